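#' Assemble a pipeline configuration
#'
#' A pipeline configuration names the five input files (counts, sample
#' metadata, target map, network edge list, pathway GMT, hallmark labels)
#' and the per-stage parameters. `read_pipeline_config()` loads the same
#' structure from YAML or JSON.
#'
#' @param counts,samples,targets,network,pathways,hallmarks Input file paths.
#' @param out_dir Output directory for stage results and the run manifest.
#' @param de Named list of [run_de()] parameters.
#' @param seeding Named list of [build_seed_set()] parameters.
#' @param propagation Named list: `r`, `tol`, `k`, `max_iter`, `strict`,
#'   `min_weight`.
#' @param enrichment Named list: `mode` (perturbation-count mode), `query`
#'   (`"vicinity"` or `"pseudo_activated"`), `min_overlap`.
#' @param hallmark Named list of [fit_logistic()] parameters.
#' @param seed Integer seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed matters when inputs are generated).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples, targets, network, pathways,
                            hallmarks, out_dir,
                            de = list(), seeding = list(),
                            propagation = list(), enrichment = list(),
                            hallmark = list(), seed = 1L) {
  structure(list(inputs = list(counts = counts, samples = samples,
                               targets = targets, network = network,
                               pathways = pathways, hallmarks = hallmarks),
                 out_dir = out_dir, de = de, seeding = seeding,
                 propagation = propagation, enrichment = enrichment,
                 hallmark = hallmark, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML (or JSON) file with the same fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, c(raw$inputs,
                             raw[intersect(names(raw),
                                           c("out_dir", "de", "seeding", "propagation",
                                             "enrichment", "hallmark", "seed"))]))
}

#' Validate a pipeline configuration
#'
#' Checks paths and parameter ranges, reporting every violation at once.
#'
#' @param cfg A `pipeline_config`.
#' @return A tibble of violations (`field`, `problem`); zero rows when valid.
#' @export
validate_config <- function(cfg) {
  v <- list()
  add <- function(field, problem) v[[length(v) + 1L]] <<- tibble(field = field, problem = problem)
  for (nm in names(cfg$inputs)) {
    p <- cfg$inputs[[nm]]
    if (is.null(p) || !is.character(p) || length(p) != 1)
      add(nm, "input path missing")
    else if (!file.exists(p))
      add(nm, paste0("file not found: ", p))
  }
  r <- cfg$propagation$r %||% 0.7
  if (!is.numeric(r) || r <= 0 || r >= 1)
    add("propagation.r", "restart_prob must be in (0,1)")
  k <- cfg$propagation$k %||% 20
  if (!is.numeric(k) || k < 1) add("propagation.k", "k must be >= 1")
  tolv <- cfg$propagation$tol %||% 1e-10
  if (!is.numeric(tolv) || tolv <= 0) add("propagation.tol", "tol must be positive")
  for (nm in c("lfc_threshold", "p_threshold"))
    if (!is.null(cfg$de[[nm]]) && cfg$de[[nm]] <= 0)
      add(paste0("de.", nm), "threshold must be positive")
  q <- cfg$enrichment$query %||% "vicinity"
  if (!q %in% c("vicinity", "pseudo_activated"))
    add("enrichment.query", "query must be 'vicinity' or 'pseudo_activated'")
  if (length(v) == 0) tibble(field = character(0), problem = character(0))
  else bind_rows(v)
}

#' Run the five-stage pipeline end to end
#'
#' Executes differential expression, seed derivation, per-seed network
#' propagation, pathway enrichment with perturbation counting, and the
#' hallmark logistic association, writing every intermediate as TSV into the
#' output directory. A JSON run manifest (config snapshot, per-stage row
#' counts and wall-clock, input checksums) is written even when a stage
#' fails, with the failing stage named.
#'
#' @param cfg A [pipeline_config()].
#' @return The run manifest, invisibly (a list; also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  problems <- validate_config(cfg)
  if (nrow(problems) > 0)
    abort(paste0("invalid pipeline config:\n",
                 paste0("  - ", problems$field, ": ", problems$problem,
                        collapse = "\n")),
          class = "evnetprop_config_error")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("evnetprop")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "inputs")],
    inputs = lapply(cfg$inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = list(), status = "running", failed_stage = NULL)
  write_manifest <- function() {
    m <- manifest
    m$config <- lapply(m$config, function(x) if (is.list(x)) x else unclass(x))
    jsonlite::write_json(m, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      manifest$stages[[name]] <<- list(error = conditionMessage(e))
      write_manifest()
      abort(paste0("pipeline failed at stage '", name, "': ",
                   conditionMessage(e)), parent = e,
            class = "evnetprop_pipeline_error")
    })
    manifest$stages[[name]] <<- c(res$info,
                                  list(seconds = round(proc.time()[["elapsed"]] - t0, 3)))
    write_manifest()
    res$value
  }

  de <- stage("expression_de", function() {
    cm <- read_count_matrix(cfg$inputs$counts, cfg$inputs$samples)
    de <- do.call(run_de, c(list(cm = cm), cfg$de))
    write_tsv_plain(de |> select("mirna_id", "log2fc", "p_value", "q_value", "call"),
                    file.path(cfg$out_dir, "de_results.tsv"))
    list(value = de,
         info = list(n_mirnas_input = nrow(cm$counts),
                     n_tested = nrow(de),
                     n_de = sum(de$call != "not_de"),
                     n_up = sum(de$call == "up"),
                     n_down = sum(de$call == "down")))
  })

  seeds <- stage("target_seeding", function() {
    targets <- read_tsv_plain(cfg$inputs$targets)
    ss <- do.call(build_seed_set, c(list(de = de, targets = targets), cfg$seeding))
    write_tsv_plain(ss, file.path(cfg$out_dir, "seed_set.tsv"))
    list(value = ss, info = list(n_seed_genes = nrow(ss)))
  })

  prop <- stage("propagation", function() {
    net <- read_network(cfg$inputs$network,
                        min_weight = cfg$propagation$min_weight %||% 0)
    pr <- propagate_all(net, seeds,
                        r = cfg$propagation$r %||% 0.7,
                        tol = cfg$propagation$tol %||% 1e-10,
                        k = cfg$propagation$k %||% 20,
                        max_iter = cfg$propagation$max_iter %||% 10000,
                        strict = isTRUE(cfg$propagation$strict))
    vic <- bind_rows(lapply(names(pr), function(s)
      pr[[s]]$vicinity |> mutate(seed = s) |>
        select("seed", "gene", "affinity", "rank")))
    write_tsv_plain(vic, file.path(cfg$out_dir, "vicinities.tsv"))
    aff <- bind_rows(lapply(names(pr), function(s)
      pr[[s]]$profile |> mutate(seed = s) |> select("seed", "gene", "affinity")))
    write_tsv_plain(aff, file.path(cfg$out_dir, "affinities.tsv"))
    list(value = list(net = net, runs = pr),
         info = list(n_network_nodes = length(network_nodes(net)),
                     n_seeds_propagated = length(pr)))
  })

  enr <- stage("enrichment", function() {
    gene_sets <- read_gmt(cfg$inputs$pathways)
    qmode <- cfg$enrichment$query %||% "vicinity"
    per_seed <- lapply(prop$runs, function(x)
      if (qmode == "vicinity") x$vicinity$gene else pseudo_activated(x$profile))
    query <- sort(unique(unlist(per_seed)))
    er <- ora(query, gene_sets, universe = network_nodes(prop$net),
              min_overlap = cfg$enrichment$min_overlap %||% 1)
    write_tsv_plain(er, file.path(cfg$out_dir, "enrichment.tsv"))
    pc <- perturbation_counts(per_seed, gene_sets,
                              mode = cfg$enrichment$mode %||% "seed_runs")
    write_tsv_plain(pc, file.path(cfg$out_dir, "perturbation_counts.tsv"))
    list(value = list(enrichment = er, counts = pc),
         info = list(n_pathways_tested = nrow(er),
                     n_enriched_fdr05 = sum(er$q_value < 0.05),
                     count_mode = attr(pc, "mode")))
  })

  fit <- stage("hallmark_link", function() {
    hl <- read_tsv_plain(cfg$inputs$hallmarks)
    fit <- do.call(hallmark_association,
                   c(list(counts = enr$counts, hallmarks = hl), cfg$hallmark))
    write_tsv_plain(tidy(fit), file.path(cfg$out_dir, "hallmark_fit.tsv"))
    write_tsv_plain(fit$data, file.path(cfg$out_dir, "hallmark_probabilities.tsv"))
    list(value = fit,
         info = list(beta1 = unname(fit$coefficients["beta1"]),
                     beta1_p = unname(fit$p_values[2]),
                     n_pathways = fit$n))
  })

  manifest$status <- "ok"
  write_manifest()
  invisible(c(manifest, list(results = list(de = de, seeds = seeds,
                                            propagation = prop$runs,
                                            enrichment = enr, fit = fit))))
}
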