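#' Filter low-expression miRNAs (filterByExpr rule)
#'
#' Retains miRNAs whose counts-per-million exceed the CPM equivalent of
#' `min_count` (relative to the median library size) in at least the
#' smallest-group number of samples, and whose total count is at least
#' `min_total`. For groups larger than ten samples the required sample number
#' grows as `10 + (n - 10) * min_prop`, matching the published heuristic.
#' Grouping follows the `timepoint` column of the sample metadata.
#'
#' @param cm A [count_matrix()].
#' @param min_count Minimum count in the CPM-threshold part of the rule.
#' @param min_total Minimum total count across all samples.
#' @param min_prop Large-group proportion.
#' @return A filtered `count_matrix`; a message reports retained/dropped rows.
#' @export
filter_low_counts <- function(cm, min_count = 10, min_total = 15,
                              min_prop = 0.7) {
  counts <- cm$counts
  lib_size <- colSums(counts)
  group_sizes <- table(cm$samples$timepoint)
  n_small <- min(group_sizes)
  if (n_small > 10) n_small <- 10 + (n_small - 10) * min_prop
  median_lib <- stats::median(lib_size)
  cpm_cutoff <- min_count / median_lib * 1e6
  cpm <- t(t(counts) / lib_size) * 1e6
  tol <- 1e-14
  keep_cpm <- rowSums(cpm >= cpm_cutoff) >= (n_small - tol)
  keep_total <- rowSums(counts) >= (min_total - tol)
  keep <- keep_cpm & keep_total
  if (!any(keep)) abort("all miRNAs removed by the expression filter",
                        class = "evnetprop_empty_result")
  inform(sprintf("expression filter: retained %d of %d miRNAs (%d dropped)",
                 sum(keep), length(keep), sum(!keep)))
  count_matrix(counts[keep, , drop = FALSE], cm$samples)
}

# One TMM factor: weighted trimmed mean of M-values of `obs` against `ref`,
# trimming the tails of both the log-ratio (M) and log-abundance (A)
# distributions and weighting by inverse asymptotic variances.
tmm_pair <- function(obs, ref, lib_obs, lib_ref, logratio_trim, sum_trim,
                     a_cutoff) {
  logR <- log2((obs / lib_obs) / (ref / lib_ref))
  absE <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / lib_obs / obs + (lib_ref - ref) / lib_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > a_cutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Computes one scaling factor per sample against a reference sample (the one
#' whose upper-quartile CPM is closest to the mean upper-quartile), trimming
#' extreme log-ratios and log-abundances and weighting the surviving
#' M-values by inverse delta-method variances. Factors are renormalized to
#' geometric mean 1, so they encode composition bias only — sequencing depth
#' stays in the library sizes.
#'
#' @param cm A [count_matrix()].
#' @param logratio_trim,sum_trim Two-sided trim fractions for M and A values.
#' @param a_cutoff Minimum average log-abundance retained.
#' @return Named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(cm, logratio_trim = 0.3, sum_trim = 0.05,
                        a_cutoff = -1e10) {
  counts <- cm$counts
  assert_that(ncol(counts) >= 2, "TMM needs at least two samples")
  lib_size <- colSums(counts)
  assert_that(all(lib_size > 0), "sample with zero total count")
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib_size
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_pair(counts[, j], counts[, ref], lib_size[j], lib_size[ref],
             logratio_trim, sum_trim, a_cutoff), numeric(1))
  f <- f / geometric_mean(f)
  stats::setNames(f, colnames(counts))
}

#' Log2 counts-per-million with a prior count
#'
#' CPM uses effective library sizes (library size times TMM factor). The
#' prior count is scaled proportionally to each effective library size (so a
#' zero count maps to the same log-CPM in every sample) and the denominator
#' is inflated by twice the prior, keeping all outputs finite.
#'
#' @param cm A [count_matrix()].
#' @param factors Per-sample normalization factors (default: all 1).
#' @param prior_count Prior count added before the log (0 allowed only if no
#'   zeros are present).
#' @return A `normalized_expression` list: `log_cpm` matrix, `tmm_factors`,
#'   `effective_lib_sizes`, and the `samples` metadata.
#' @export
log_cpm <- function(cm, factors = NULL, prior_count = 0.5) {
  counts <- cm$counts
  factors <- factors %||% stats::setNames(rep(1, ncol(counts)), colnames(counts))
  assert_that(all(factors > 0), "normalization factors must be positive")
  eff_lib <- colSums(counts) * factors
  prior <- prior_count * eff_lib / mean(eff_lib)
  lcpm <- log2(t((t(counts) + prior) / (eff_lib + 2 * prior)) * 1e6)
  assert_that(all(is.finite(lcpm)),
              "non-finite log-CPM; use a positive prior_count with zero counts")
  structure(list(log_cpm = lcpm, tmm_factors = factors,
                 effective_lib_sizes = eff_lib, samples = cm$samples),
            class = "normalized_expression")
}

# Method-of-moments fit of the scaled-inverse-chi-squared prior for
# empirical-Bayes variance moderation: sample variances follow
# s^2 / s0^2 ~ F(df, d0) marginally, and matching the first two moments of
# s^2 gives closed-form (d0, s0^2). Returns d0 = Inf when the observed
# variance of s^2 is no larger than pure chi-squared noise.
fit_variance_prior <- function(s2, df) {
  m1 <- mean(s2)
  m2 <- stats::var(s2)
  if (!is.finite(m2) || m2 <= 0 || m1 <= 0) {
    return(list(d0 = Inf, s02 = m1))
  }
  c0 <- m2 / m1^2
  denom <- c0 * df - 2
  if (denom <= 0) return(list(d0 = Inf, s02 = m1))
  d0 <- (4 * c0 * df + 2 * df - 4) / denom
  if (d0 <= 4) d0 <- 4.001  # moment solution unstable below 4 df
  s02 <- m1 * (d0 - 2) / d0
  list(d0 = d0, s02 = s02)
}

#' Paired differential-expression test on log-CPM
#'
#' Forms per-subject post-minus-pre differences of log2 CPM and tests the
#' mean difference per miRNA. With `shrink = TRUE`, per-miRNA variances are
#' moderated by empirical-Bayes shrinkage toward a pooled
#' scaled-inverse-chi-squared prior fitted by method of moments, and the
#' moderated t uses the prior-augmented degrees of freedom; with
#' `shrink = FALSE` it is the ordinary paired t-test. Benjamini-Hochberg
#' q-values are always reported; up/down calls use the raw p-value and
#' absolute log2-fold-change thresholds.
#'
#' @param ne A `normalized_expression` from [log_cpm()].
#' @param shrink Moderate variances by empirical Bayes?
#' @param timepoints Length-2 character: reference and treatment timepoint
#'   (the contrast is `timepoints[2] - timepoints[1]`).
#' @param lfc_threshold,p_threshold Calling thresholds (defaults 1.0 and 0.05).
#' @return A `de_result` tibble: `mirna_id`, `log2fc`, `t`, `df_total`,
#'   `p_value`, `q_value`, `call`.
#' @export
paired_de_test <- function(ne, shrink = TRUE, timepoints = c("pre", "post"),
                           lfc_threshold = 1.0, p_threshold = 0.05) {
  samples <- ne$samples
  assert_that(all(timepoints %in% samples$timepoint),
              paste0("timepoints not present in sample metadata: ",
                     paste(setdiff(timepoints, samples$timepoint), collapse = ", ")))
  pre <- samples |> filter(.data$timepoint == timepoints[1]) |> arrange(.data$subject_id)
  post <- samples |> filter(.data$timepoint == timepoints[2]) |> arrange(.data$subject_id)
  assert_that(identical(pre$subject_id, post$subject_id) &&
                !anyDuplicated(pre$subject_id),
              "paired design incomplete: each subject needs exactly one sample per timepoint")
  n <- nrow(pre)
  assert_that(n >= 2, "paired test needs at least 2 subjects (no residual df)")
  d <- ne$log_cpm[, post$sample_id, drop = FALSE] -
    ne$log_cpm[, pre$sample_id, drop = FALSE]
  dbar <- rowMeans(d)
  s2 <- apply(d, 1, stats::var)
  df <- n - 1

  if (shrink) {
    prior <- fit_variance_prior(s2, df)
    if (is.infinite(prior$d0)) {
      s2_post <- rep(prior$s02, length(s2))
      df_total <- rep(Inf, length(s2))
    } else {
      s2_post <- (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
      df_total <- rep(df + prior$d0, length(s2))
    }
  } else {
    s2_post <- s2
    df_total <- rep(df, length(s2))
  }
  se <- sqrt(s2_post / n)
  tstat <- ifelse(se > 0, dbar / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df_total), 1)
  q <- bh_adjust(p)
  res <- tibble(mirna_id = rownames(ne$log_cpm), log2fc = unname(dbar),
                t = unname(tstat), df_total = unname(df_total),
                p_value = unname(p), q_value = unname(q)) |>
    mutate(call = classify_de(.data$log2fc, .data$p_value,
                              lfc_threshold, p_threshold))
  class(res) <- c("de_result", class(res))
  attr(res, "thresholds") <- c(lfc = lfc_threshold, p = p_threshold)
  res
}

#' Classify miRNAs as up/down/not differentially expressed
#'
#' `up` if `log2fc > lfc_threshold` and `p < p_threshold`; `down` if
#' `log2fc < -lfc_threshold` and `p < p_threshold`; otherwise `not_de`.
#' The fold-change rule is applied to the signed value, i.e. symmetrically
#' in absolute value.
#'
#' @param log2fc,p Numeric vectors of equal length.
#' @param lfc_threshold,p_threshold Positive thresholds.
#' @return Character vector in `{"up", "down", "not_de"}`.
#' @export
classify_de <- function(log2fc, p, lfc_threshold = 1.0, p_threshold = 0.05) {
  assert_that(lfc_threshold > 0 && p_threshold > 0, "thresholds must be positive")
  dplyr::case_when(
    log2fc > lfc_threshold & p < p_threshold ~ "up",
    log2fc < -lfc_threshold & p < p_threshold ~ "down",
    TRUE ~ "not_de")
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in \[0, 1\] (BH step-up with monotonization).
#' @export
bh_adjust <- function(p) {
  assert_that(all(is.finite(p)) && all(p >= 0) && all(p <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the full filtering / normalization / paired DE chain
#'
#' Convenience wrapper: [filter_low_counts()], [tmm_factors()], [log_cpm()],
#' [paired_de_test()].
#'
#' @inheritParams filter_low_counts
#' @inheritParams paired_de_test
#' @param prior_count Prior count for the log-CPM transform.
#' @return A `de_result` tibble (see [paired_de_test()]).
#' @export
run_de <- function(cm, min_count = 10, min_total = 15, min_prop = 0.7,
                   prior_count = 0.5, shrink = TRUE,
                   timepoints = c("pre", "post"),
                   lfc_threshold = 1.0, p_threshold = 0.05) {
  cm <- filter_low_counts(cm, min_count, min_total, min_prop)
  f <- tmm_factors(cm)
  ne <- log_cpm(cm, f, prior_count)
  paired_de_test(ne, shrink = shrink, timepoints = timepoints,
                 lfc_threshold = lfc_threshold, p_threshold = p_threshold)
}
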