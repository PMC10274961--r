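#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline geom_vline labs theme_minimal scale_color_manual coord_flip
NULL

#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  th <- attr(object, "thresholds") %||% c(lfc = 1, p = 0.05)
  ggplot(object, aes(x = .data$log2fc, y = -log10(.data$p_value),
                     color = .data$call)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = c(-th[["lfc"]], th[["lfc"]]), linetype = 2) +
    geom_hline(yintercept = -log10(th[["p"]]), linetype = 2) +
    scale_color_manual(values = c(up = "#c0392b", down = "#2980b9",
                                  not_de = "grey60")) +
    labs(x = "log2 fold change (post - pre)", y = "-log10 p",
         color = "call", title = "Paired differential expression") +
    theme_minimal()
}

#' Bar plot of the top enriched gene sets
#'
#' @param object An `enrichment_result` tibble.
#' @param top_n How many sets to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, top_n = 10, ...) {
  d <- object |> slice_head(n = top_n) |>
    mutate(set_name = factor(.data$set_name, levels = rev(.data$set_name)))
  ggplot(d, aes(x = .data$set_name, y = -log10(.data$q_value))) +
    geom_col(fill = "#34495e") +
    geom_hline(yintercept = -log10(0.05), linetype = 2, color = "#c0392b") +
    coord_flip() +
    labs(x = NULL, y = "-log10 FDR", title = "Over-represented gene sets") +
    theme_minimal()
}

#' Affinity decay plot for a propagation profile
#'
#' Ranked affinity of the non-seed genes, highlighting the top-k vicinity.
#'
#' @param object An `affinity_profile`.
#' @param k Vicinity size to highlight.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot affinity_profile
#' @export
autoplot.affinity_profile <- function(object, k = 20, ...) {
  d <- object |>
    filter(!.data$gene %in% attr(object, "seeds")) |>
    arrange(desc(.data$affinity), .data$gene) |>
    mutate(rank = row_number(), vicinity = .data$rank <= k)
  ggplot(d, aes(x = .data$rank, y = .data$affinity, color = .data$vicinity)) +
    geom_point(size = 0.8) +
    scale_color_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60")) +
    labs(x = "affinity rank", y = "RWR affinity",
         title = paste("Propagation from seed",
                       paste(attr(object, "seeds"), collapse = "+"))) +
    theme_minimal()
}

#' Fitted hallmark-probability curve
#'
#' Observed labels (jittered) against perturbation count, with the fitted
#' logistic probability of the aged-hallmark phenotype.
#'
#' @param object A `logistic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot logistic_fit
#' @export
autoplot.logistic_fit <- function(object, ...) {
  d <- tibble(count = object$x, label = object$y)
  grid <- tibble(count = seq(min(object$x), max(object$x), length.out = 200))
  grid$probability <- predict_probability(object, grid$count)
  ggplot(d, aes(x = .data$count, y = .data$label)) +
    geom_point(alpha = 0.4, position = ggplot2::position_jitter(height = 0.03)) +
    geom_line(data = grid, aes(y = .data$probability), color = "#c0392b",
              linewidth = 1) +
    labs(x = "perturbation count", y = "P(aged-hallmark phenotype)",
         title = "Hallmark association") +
    theme_minimal()
}
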