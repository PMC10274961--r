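#' Cross-database consistent targets of one miRNA
#'
#' Intersects the target genes reported for `mirna` by the two databases of
#' a target-map table. With `evidence_filter = "strong_only"`, the
#' experimental-evidence database (`db_b`) entry must be labelled `strong`
#' (reporter assay / western blot / qRT-PCR class evidence); the prediction
#' database (`db_a`) entries pass regardless of label. A miRNA absent from
#' either database yields the empty set, not an error.
#'
#' @param mirna A miRNA identifier.
#' @param targets Tibble with columns `mirna_id`, `gene_id`, `database`,
#'   `evidence`.
#' @param evidence_filter `"strong_only"` (default) or `"any"`.
#' @param db_a,db_b Database labels; default to the first two labels in the
#'   table (sorted), with `db_b` the evidence-bearing one.
#' @return Sorted character vector of consistently predicted target genes.
#' @export
consistent_targets <- function(mirna, targets,
                               evidence_filter = c("strong_only", "any"),
                               db_a = NULL, db_b = NULL) {
  evidence_filter <- match.arg(evidence_filter)
  dbs <- sort(unique(targets$database))
  assert_that(length(dbs) >= 2, "target map must contain two databases")
  db_a <- db_a %||% dbs[1]
  db_b <- db_b %||% dbs[2]
  rows <- targets |> filter(.data$mirna_id == mirna)
  a_genes <- rows |> filter(.data$database == db_a) |> pull("gene_id")
  b_rows <- rows |> filter(.data$database == db_b)
  if (evidence_filter == "strong_only")
    b_rows <- b_rows |> filter(.data$evidence == "strong")
  sort(intersect(a_genes, b_rows$gene_id))
}

#' Build the propagation seed gene set from DE miRNAs
#'
#' Takes the union of cross-database consistent targets over the
#' differentially expressed miRNAs (all DE calls, or up-regulated only),
#' deduplicates, and records which miRNAs support each gene. Gene symbols
#' may first be translated through an explicit mapping table (for example
#' mouse-to-human orthologs) and are upper-cased to the human convention.
#'
#' @param de A `de_result` tibble from [paired_de_test()] or [run_de()].
#' @param targets Target-map tibble (see [consistent_targets()]).
#' @param direction_filter `"all_de"` (default) or `"up_only"`.
#' @param evidence_filter Passed to [consistent_targets()].
#' @param symbol_map Optional data frame with columns `from`, `to` applied to
#'   target gene symbols before deduplication.
#' @return A `seed_set` tibble: `gene_id`, `supporting_mirnas` (comma-joined),
#'   `n_mirnas`; errors if the union is empty.
#' @export
build_seed_set <- function(de, targets,
                           direction_filter = c("all_de", "up_only"),
                           evidence_filter = c("strong_only", "any"),
                           symbol_map = NULL) {
  direction_filter <- match.arg(direction_filter)
  evidence_filter <- match.arg(evidence_filter)
  wanted <- if (direction_filter == "up_only") "up" else c("up", "down")
  de_mirnas <- de$mirna_id[de$call %in% wanted]
  translate <- function(g) {
    if (!is.null(symbol_map)) {
      hit <- match(g, symbol_map$from)
      g[!is.na(hit)] <- symbol_map$to[hit[!is.na(hit)]]
    }
    toupper(g)
  }
  support <- list()
  for (m in sort(de_mirnas)) {
    genes <- translate(consistent_targets(m, targets, evidence_filter))
    for (g in genes) support[[g]] <- c(support[[g]], m)
  }
  if (length(support) == 0)
    abort(paste0("empty seed set: no DE miRNA has a cross-database consistent ",
                 "target (", length(de_mirnas), " DE miRNAs considered)"),
          class = "evnetprop_empty_seed_error")
  out <- tibble(gene_id = sort(names(support))) |>
    mutate(supporting_mirnas = unname(collapse_ids(support[.data$gene_id])),
           n_mirnas = unname(lengths(support[.data$gene_id])))
  class(out) <- c("seed_set", class(out))
  out
}
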