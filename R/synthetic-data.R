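#' Configuration for the synthetic pipeline inputs
#'
#' Builds and validates the parameter set used by the synthetic generators.
#' The defaults emulate the study conditions the pipeline is designed for:
#' ten subjects sampled before and after an exercise bout, a few hundred
#' detectable miRNAs of which 16 respond, a modular tissue-specific gene
#' network, two partially overlapping target databases, and a pathway
#' collection whose aging-hallmark labels depend logistically on how exposed
#' each pathway is to the planted target module.
#'
#' @param n_subjects Number of paired subjects (samples = subjects x timepoints).
#' @param n_mirnas Number of miRNAs in the count table.
#' @param n_de_mirnas Number of planted differentially expressed miRNAs.
#' @param de_log2fc Planted post-vs-pre effect, in log2 units.
#' @param nb_dispersion Negative-binomial dispersion phi (variance = mu + mu^2 phi).
#' @param lib_size_range Length-2 integer vector; per-sample library sizes are
#'   drawn uniformly from this range.
#' @param subject_sd Standard deviation (log2 scale) of the subject-by-miRNA
#'   random effect shared across timepoints; this is what makes pairing informative.
#' @param n_timepoints Two (pre/post) by default; three adds a recovery timepoint.
#' @param n_genes,n_modules Stochastic-block-model network size and block count.
#' @param p_within,p_between Within/between-module edge probabilities
#'   (`p_within > p_between` so the modules are detectable).
#' @param targets_per_mirna True targets planted per DE miRNA.
#' @param db_overlap_frac Probability that a true target is reported by both
#'   target databases (1 = perfect cross-database agreement, 0 = none).
#' @param n_pathways Number of module-aligned pathway gene sets.
#' @param hallmark_beta0,hallmark_beta1 Planted logistic coefficients linking a
#'   pathway's perturbation propensity to its binary hallmark label.
#' @param seed Integer RNG seed; every generator derives an independent
#'   stream from it, so identical configs reproduce all artifacts exactly.
#'
#' @return A validated `synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1)
#' dat <- synth_all(cfg)
#' dim(dat$counts$counts)
synth_config <- function(n_subjects = 10,
                         n_mirnas = 300,
                         n_de_mirnas = 16,
                         de_log2fc = 2.0,
                         nb_dispersion = 0.1,
                         lib_size_range = c(8e5, 1.2e6),
                         subject_sd = 0.2,
                         n_timepoints = 2,
                         n_genes = 400,
                         n_modules = 8,
                         p_within = 0.15,
                         p_between = 0.005,
                         targets_per_mirna = 5,
                         db_overlap_frac = 0.8,
                         n_pathways = 100,
                         hallmark_beta0 = -1,
                         hallmark_beta1 = 0.15,
                         seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_mirnas = n_mirnas,
              n_de_mirnas = n_de_mirnas, de_log2fc = de_log2fc,
              nb_dispersion = nb_dispersion, lib_size_range = lib_size_range,
              subject_sd = subject_sd, n_timepoints = n_timepoints,
              n_genes = n_genes, n_modules = n_modules,
              p_within = p_within, p_between = p_between,
              targets_per_mirna = targets_per_mirna,
              db_overlap_frac = db_overlap_frac, n_pathways = n_pathways,
              hallmark_beta0 = hallmark_beta0, hallmark_beta1 = hallmark_beta1,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk <- function(ok, what) {
    if (!isTRUE(ok)) abort(paste0("invalid synthetic config: ", what),
                           class = "evnetprop_config_error")
  }
  chk(cfg$n_subjects >= 1, "n_subjects must be a positive integer")
  chk(cfg$n_mirnas >= 1, "n_mirnas must be a positive integer")
  chk(cfg$n_de_mirnas >= 0 && cfg$n_de_mirnas <= cfg$n_mirnas,
      "n_de_mirnas must satisfy 0 <= n_de_mirnas <= n_mirnas")
  chk(cfg$nb_dispersion > 0, "nb_dispersion must be positive")
  chk(length(cfg$lib_size_range) == 2 && all(cfg$lib_size_range > 0) &&
        cfg$lib_size_range[1] <= cfg$lib_size_range[2],
      "lib_size_range must be an increasing pair of positive sizes")
  chk(cfg$n_timepoints %in% c(2, 3), "n_timepoints must be 2 or 3")
  chk(cfg$n_genes >= 1, "n_genes must be a positive integer")
  chk(cfg$n_modules >= 1 && cfg$n_modules <= cfg$n_genes,
      "n_modules must be in [1, n_genes]")
  chk(cfg$p_within >= 0 && cfg$p_within <= 1 &&
        cfg$p_between >= 0 && cfg$p_between <= 1,
      "p_within and p_between must be probabilities in [0, 1]")
  chk(cfg$n_genes == 1 || cfg$n_modules == 1 || cfg$p_within > cfg$p_between,
      "p_within must exceed p_between (modular structure must be detectable)")
  chk(cfg$targets_per_mirna >= 1, "targets_per_mirna must be a positive integer")
  chk(cfg$db_overlap_frac >= 0 && cfg$db_overlap_frac <= 1,
      "db_overlap_frac must be a probability in [0, 1]")
  chk(cfg$n_pathways >= 1, "n_pathways must be a positive integer")
  invisible(cfg)
}

#' Generate a paired negative-binomial miRNA count table with planted DE
#'
#' Counts are drawn from a negative binomial (variance \eqn{\mu + \mu^2\phi})
#' around miRNA-specific baseline abundances, with uniform per-sample library
#' sizes and a subject-level random effect shared across timepoints. Planted
#' DE miRNAs have their mean multiplied by `2^de_log2fc` at every
#' post-baseline timepoint. DE miRNAs are drawn from the upper half of the
#' abundance distribution so the planted effect is identifiable above the
#' count noise floor.
#'
#' @param cfg A [synth_config()].
#' @return A list with `counts` (a `count_matrix`: integer miRNA x sample
#'   matrix plus a sample-metadata tibble) and `truth`
#'   (`de_mirna_ids`, `baseline_abundance`).
#' @export
generate_counts <- function(cfg) {
  validate_synth_config(cfg)
  with_stage_seed(cfg$seed, "counts", {
    mirna_ids <- sprintf("miR-%04d", seq_len(cfg$n_mirnas))
    subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
    tps <- c("pre", "post", "recovery")[seq_len(cfg$n_timepoints)]
    samples <- tidyr::expand_grid(subject_id = subjects, timepoint = tps) |>
      mutate(sample_id = paste(.data$subject_id, .data$timepoint, sep = "_")) |>
      select("sample_id", "subject_id", "timepoint")

    # relative abundances: log-normal, heavy-tailed as in small RNA-seq
    abund <- exp(stats::rnorm(cfg$n_mirnas, mean = log(50), sd = 1.5))
    names(abund) <- mirna_ids
    de_ids <- character(0)
    if (cfg$n_de_mirnas > 0) {
      eligible <- mirna_ids[abund >= stats::median(abund)]
      de_ids <- sort(sample(eligible, min(cfg$n_de_mirnas, length(eligible))))
    }
    rel <- abund / sum(abund)

    lib_sizes <- round(stats::runif(nrow(samples),
                                    cfg$lib_size_range[1], cfg$lib_size_range[2]))
    subj_eff <- matrix(stats::rnorm(cfg$n_mirnas * cfg$n_subjects,
                                    sd = cfg$subject_sd),
                       nrow = cfg$n_mirnas,
                       dimnames = list(mirna_ids, subjects))

    counts <- matrix(0L, cfg$n_mirnas, nrow(samples),
                     dimnames = list(mirna_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      shift <- rep(0, cfg$n_mirnas)
      if (samples$timepoint[j] != "pre") shift[mirna_ids %in% de_ids] <- cfg$de_log2fc
      mu <- rel * lib_sizes[j] *
        2^(subj_eff[, samples$subject_id[j]] + shift)
      counts[, j] <- stats::rnbinom(cfg$n_mirnas, mu = mu,
                                    size = 1 / cfg$nb_dispersion)
    }
    list(counts = count_matrix(counts, samples),
         truth = list(de_mirna_ids = de_ids, baseline_abundance = rel))
  })
}

#' A miRNA x sample count container
#'
#' @param counts Non-negative integer matrix with miRNA row names and sample
#'   column names.
#' @param samples Tibble with columns `sample_id`, `subject_id`, `timepoint`,
#'   one row per count column.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples) {
  samples <- as_tibble(samples)
  assert_that(!is.null(rownames(counts)) && !anyDuplicated(rownames(counts)),
              "counts must have unique miRNA row names")
  assert_that(!anyDuplicated(samples$sample_id), "duplicate sample IDs")
  assert_that(identical(colnames(counts), samples$sample_id),
              "count columns must match sample metadata order")
  assert_that(all(counts >= 0), "counts must be non-negative")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d miRNAs x %d samples (%d subjects, timepoints: %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$subject_id)),
              paste(unique(x$samples$timepoint), collapse = "/")))
  invisible(x)
}

#' Generate a modular weighted gene network (stochastic block model)
#'
#' Nodes are split into `n_modules` contiguous blocks; within-block pairs are
#' connected with probability `p_within`, between-block pairs with
#' `p_between`, and each edge gets a weight in (0, 1]. Only the largest
#' connected component is retained (with a message naming how many nodes were
#' dropped), because the random-walk operator requires a connected support.
#'
#' @param cfg A [synth_config()].
#' @return A list with `network` (a [functional_network()]) and `truth`
#'   (`module_of_gene` for retained nodes, `target_module` — the block from
#'   which true miRNA targets are later planted).
#' @export
generate_network <- function(cfg) {
  validate_synth_config(cfg)
  with_stage_seed(cfg$seed, "network", {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    module <- rep(seq_len(cfg$n_modules), length.out = cfg$n_genes)
    module <- sort(module)
    names(module) <- genes
    if (cfg$n_genes > 1) {
      pairs <- utils::combn(cfg$n_genes, 2)
      same <- module[pairs[1, ]] == module[pairs[2, ]]
      p <- ifelse(same, cfg$p_within, cfg$p_between)
      keep <- stats::runif(ncol(pairs)) < p
      if (!any(keep)) abort("network generation produced an empty graph",
                            class = "evnetprop_generation_error")
      edges <- tibble(gene_a = genes[pairs[1, keep]],
                      gene_b = genes[pairs[2, keep]],
                      weight = stats::runif(sum(keep), 0.05, 1))
    } else {
      edges <- tibble(gene_a = character(0), gene_b = character(0),
                      weight = numeric(0))
    }
    net <- functional_network(edges, nodes = genes)
    kept <- network_nodes(net)
    module_kept <- module[kept]
    # plant targets in the largest surviving block so the ground truth is
    # well-populated even if the component extraction trimmed the graph
    target_module <- as.integer(names(which.max(table(module_kept))))
    list(network = net,
         truth = list(module_of_gene = module_kept,
                      target_module = target_module))
  })
}

#' Generate two partially overlapping miRNA target databases
#'
#' Emulates cross-database target prediction: for each planted DE miRNA the
#' true targets (drawn from the planted network module) appear in both
#' databases with probability `db_overlap_frac` and in exactly one otherwise;
#' decoy targets are unique to one database. Database B carries
#' strong/weak experimental-evidence labels (true targets are always strong).
#' Non-DE miRNAs receive decoy targets only.
#'
#' @param cfg A [synth_config()].
#' @param truth Accumulated ground truth containing `de_mirna_ids`,
#'   `module_of_gene` and `target_module` (from [generate_counts()] and
#'   [generate_network()]).
#' @return A list with `targets` (tibble: `mirna_id`, `gene_id`, `database`,
#'   `evidence`) and `truth` (`true_targets`: named list, DE miRNA -> genes).
#' @export
generate_target_map <- function(cfg, truth) {
  validate_synth_config(cfg)
  assert_that(!is.null(truth$module_of_gene), "generate_network must run first")
  with_stage_seed(cfg$seed, "targets", {
    genes <- names(truth$module_of_gene)
    in_mod <- genes[truth$module_of_gene == truth$target_module]
    out_mod <- genes[truth$module_of_gene != truth$target_module]
    if (length(out_mod) == 0) out_mod <- genes
    all_mirnas <- truth$mirna_ids %||%
      sprintf("miR-%04d", seq_len(cfg$n_mirnas))
    k <- cfg$targets_per_mirna

    rows <- list()
    true_targets <- list()
    for (m in all_mirnas) {
      is_de <- m %in% truth$de_mirna_ids
      decoys <- sample(out_mod, min(2 * k, length(out_mod)))
      half <- ceiling(length(decoys) / 2)
      rows[[length(rows) + 1L]] <- tibble(
        mirna_id = m, gene_id = decoys[seq_len(half)],
        database = "db_a", evidence = sample(c("strong", "weak"), half, TRUE))
      if (length(decoys) > half) {
        rest <- decoys[(half + 1):length(decoys)]
        rows[[length(rows) + 1L]] <- tibble(
          mirna_id = m, gene_id = rest,
          database = "db_b",
          evidence = sample(c("strong", "weak"), length(rest), TRUE))
      }
      if (is_de) {
        tt <- sample(in_mod, min(k, length(in_mod)))
        true_targets[[m]] <- sort(tt)
        both <- stats::runif(length(tt)) < cfg$db_overlap_frac
        one_db <- ifelse(stats::runif(length(tt)) < 0.5, "db_a", "db_b")
        for (i in seq_along(tt)) {
          dbs <- if (both[i]) c("db_a", "db_b") else one_db[i]
          rows[[length(rows) + 1L]] <- tibble(
            mirna_id = m, gene_id = tt[i], database = dbs, evidence = "strong")
        }
      }
    }
    targets <- bind_rows(rows) |>
      distinct(.data$mirna_id, .data$gene_id, .data$database, .keep_all = TRUE) |>
      arrange(.data$mirna_id, .data$database, .data$gene_id)
    list(targets = targets, truth = list(true_targets = true_targets))
  })
}

#' Generate module-aligned pathway gene sets and hallmark labels
#'
#' Pathways are gene sets sampled within single network modules (round-robin
#' across modules, sizes 10--30). Each pathway's perturbation propensity is
#' the number of its genes falling in the planted target module; its binary
#' aging-hallmark label is drawn Bernoulli with
#' `logit p = hallmark_beta0 + hallmark_beta1 * propensity`.
#'
#' @param cfg A [synth_config()].
#' @param truth Ground truth containing `module_of_gene` and `target_module`.
#' @return A list with `gene_sets` (named list of gene vectors), `hallmarks`
#'   (tibble: `pathway`, `label`) and `truth` (`pathway_module`,
#'   `perturbation_propensity`, `planted_betas`).
#' @export
generate_pathways_and_hallmarks <- function(cfg, truth) {
  validate_synth_config(cfg)
  assert_that(!is.null(truth$module_of_gene), "generate_network must run first")
  with_stage_seed(cfg$seed, "pathways", {
    module_of_gene <- truth$module_of_gene
    mods_present <- sort(unique(module_of_gene))
    pw_names <- sprintf("PW%03d", seq_len(cfg$n_pathways))
    pw_module <- rep(mods_present, length.out = cfg$n_pathways)
    gene_sets <- vector("list", cfg$n_pathways)
    names(gene_sets) <- pw_names
    for (i in seq_len(cfg$n_pathways)) {
      pool <- names(module_of_gene)[module_of_gene == pw_module[i]]
      size <- sample(10:30, 1)
      gene_sets[[i]] <- sort(sample(pool, min(size, length(pool))))
    }
    propensity <- vapply(gene_sets, function(g)
      sum(module_of_gene[g] == truth$target_module), numeric(1))
    eta <- cfg$hallmark_beta0 + cfg$hallmark_beta1 * propensity
    labels <- stats::rbinom(cfg$n_pathways, 1, stats::plogis(eta))
    hallmarks <- tibble(pathway = pw_names, label = labels)
    list(gene_sets = gene_sets, hallmarks = hallmarks,
         truth = list(pathway_module = stats::setNames(pw_module, pw_names),
                      perturbation_propensity = propensity,
                      planted_betas = c(beta0 = cfg$hallmark_beta0,
                                        beta1 = cfg$hallmark_beta1)))
  })
}

#' Generate every pipeline input with planted ground truth
#'
#' Runs all four generators with independent seed-derived RNG streams and
#' bundles their outputs and ground truth.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_data` list: `config`, `counts` (a `count_matrix`),
#'   `network`, `targets`, `gene_sets`, `hallmarks`, `truth`.
#' @export
synth_all <- function(cfg) {
  validate_synth_config(cfg)
  cts <- generate_counts(cfg)
  truth <- cts$truth
  truth$mirna_ids <- rownames(cts$counts$counts)
  nw <- generate_network(cfg)
  truth <- c(truth, nw$truth)
  tm <- generate_target_map(cfg, truth)
  truth <- c(truth, tm$truth)
  pw <- generate_pathways_and_hallmarks(cfg, truth)
  truth <- c(truth, pw$truth)
  truth$hallmark_labels <- stats::setNames(pw$hallmarks$label, pw$hallmarks$pathway)
  structure(list(config = cfg, counts = cts$counts, network = nw$network,
                 targets = tm$targets, gene_sets = pw$gene_sets,
                 hallmarks = pw$hallmarks, truth = truth),
            class = "synth_data")
}

#' Write synthetic artifacts to plain-text files
#'
#' Counts and sample metadata as TSV, the network as a 3-column edge list,
#' target maps as TSV, pathways as GMT, hallmark labels as TSV, and the
#' ground truth as JSON.
#'
#' @param dat A `synth_data` object from [synth_all()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synth_data <- function(dat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "sample_meta.tsv"),
             network = file.path(dir, "network.tsv"),
             targets = file.path(dir, "target_map.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             hallmarks = file.path(dir, "hallmarks.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  cts <- as.data.frame(dat$counts$counts)
  cts <- cbind(mirna_id = rownames(dat$counts$counts), cts)
  write_tsv_plain(cts, paths["counts"])
  write_tsv_plain(dat$counts$samples, paths["samples"])
  write_tsv_plain(network_edges(dat$network), paths["network"])
  write_tsv_plain(dat$targets, paths["targets"])
  write_gmt(dat$gene_sets, paths["pathways"])
  write_tsv_plain(dat$hallmarks, paths["hallmarks"])
  tr <- dat$truth
  tr$module_of_gene <- as.list(tr$module_of_gene)
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a count TSV plus sample metadata TSV back into a `count_matrix`
#'
#' Accepts the layout written by [write_synth_data()] and, equivalently, any
#' plain miRNA x sample TSV whose first column holds miRNA identifiers (such
#' as a GEO supplementary count export).
#'
#' @param counts_path TSV with miRNA IDs in the first column.
#' @param samples_path TSV with columns `sample_id`, `subject_id`, `timepoint`.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  cts <- read_tsv_plain(counts_path)
  m <- as.matrix(cts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(cts[[1]])
  samples <- read_tsv_plain(samples_path)
  count_matrix(m[, samples$sample_id, drop = FALSE], samples)
}
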