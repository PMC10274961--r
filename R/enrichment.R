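#' Upper-tail hypergeometric over-representation p-value
#'
#' \eqn{P[X \ge k]} for \eqn{X \sim} Hypergeometric(population `N`, `K`
#' annotated, `n` drawn), evaluated on the log scale for numerical
#' stability. `k = 0` returns exactly 1.
#'
#' @param k Observed overlap.
#' @param K Annotated-set size.
#' @param n Query size.
#' @param N Universe size.
#' @return The one-sided over-representation p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  assert_that(all(k >= 0) && all(K <= N) && all(n <= N) &&
                all(k <= pmin(K, n)),
              "inconsistent hypergeometric arguments: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0)
    abort(sprintf("malformed GMT record at line %d (need name, description, genes)",
                  bad[1]), class = "evnetprop_parse_error")
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

#' @rdname read_gmt
#' @param sets Named list of gene-identifier vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis against a gene-set collection
#'
#' One upper-tail hypergeometric test per gene set (after restricting both
#' the query and the sets to the universe), Benjamini-Hochberg correction
#' across the tested sets, results ranked by p-value. The universe defaults
#' to the union of all set genes; in the pipeline it is the network node
#' set, since propagation can only ever visit network genes.
#'
#' @param query Character vector of query genes.
#' @param gene_sets Named list of gene sets (for example from [read_gmt()]).
#' @param universe Character vector; default union of all set genes.
#' @param min_overlap Only sets overlapping the query by at least this many
#'   genes are tested.
#' @param top_n Optionally keep only the `top_n` smallest-p rows.
#' @return An `enrichment_result` tibble: `set_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `overlap` (comma-joined genes), ranked by p.
#' @export
ora <- function(query, gene_sets, universe = NULL, min_overlap = 1,
                top_n = NULL) {
  universe <- sort(unique(universe %||% unlist(gene_sets, use.names = FALSE)))
  query0 <- unique(query)
  query <- intersect(query0, universe)
  n_out <- length(query0) - length(query)
  if (n_out > 0)
    inform(sprintf("ORA: %d query genes outside the universe dropped", n_out))
  if (length(query) == 0)
    abort("empty query after restriction to the universe",
          class = "evnetprop_empty_result")
  sets <- lapply(gene_sets, intersect, y = universe)
  res <- imap(sets, function(g, nm) {
    ov <- intersect(query, g)
    tibble(set_name = nm, k = length(ov), K = length(g),
           n = length(query), N = length(universe),
           overlap = paste(sort(ov), collapse = ","))
  }) |> bind_rows() |>
    filter(.data$k >= min_overlap, .data$K > 0)
  assert_that(nrow(res) > 0, "no gene set meets the minimum overlap")
  res <- res |>
    mutate(p_value = hypergeom_test(.data$k, .data$K, .data$n, .data$N),
           q_value = bh_adjust(.data$p_value)) |>
    arrange(.data$p_value, .data$set_name) |>
    select("set_name", "k", "K", "n", "N", "p_value", "q_value", "overlap")
  if (!is.null(top_n)) res <- slice_head(res, n = top_n)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Per-pathway perturbation counts over propagated seeds
#'
#' For each pathway, counts either the number of seed propagation runs whose
#' vicinity intersects the pathway (`mode = "seed_runs"`, default — bounded
#' by the number of seeds and directly interpretable as "how many seeds
#' perturb this pathway"), or the total number of (seed, gene) intersection
#' events (`mode = "gene_overlap"`).
#'
#' @param propagated Named list from [propagate_all()] (or a named list of
#'   gene vectors, one per seed).
#' @param gene_sets Named list of pathway gene sets.
#' @param mode `"seed_runs"` or `"gene_overlap"`.
#' @return A tibble `pathway`, `count`, with attribute `mode`.
#' @export
perturbation_counts <- function(propagated, gene_sets,
                                mode = c("seed_runs", "gene_overlap")) {
  mode <- match.arg(mode)
  vic_genes <- lapply(propagated, function(x) {
    if (is.list(x) && !is.null(x$vicinity)) x$vicinity$gene else x
  })
  counts <- vapply(gene_sets, function(pw) {
    per_seed <- vapply(vic_genes, function(v) length(intersect(v, pw)),
                       numeric(1))
    if (mode == "seed_runs") sum(per_seed > 0) else sum(per_seed)
  }, numeric(1))
  out <- tibble(pathway = names(gene_sets), count = unname(counts))
  attr(out, "mode") <- mode
  attr(out, "n_seeds") <- length(vic_genes)
  out
}
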