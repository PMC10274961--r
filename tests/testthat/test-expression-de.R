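test_that("expression filter implements the published rule", {
  withr::local_seed(1)
  # 500 miRNAs, 100 of them all-low, 10+10 paired samples
  hi <- matrix(rpois(400 * 20, 120), 400, 20)
  lo <- matrix(rpois(100 * 20, 0.3), 100, 20)
  counts <- rbind(hi, lo)
  rownames(counts) <- sprintf("m%03d", 1:500)
  colnames(counts) <- sprintf("s%02d", 1:20)
  cm <- toy_counts(counts, 10)
  expect_message(kept <- filter_low_counts(cm), "retained 400 of 500")
  expect_equal(nrow(kept$counts), 400)
  expect_identical(rownames(kept$counts), rownames(counts)[1:400])

  # agrees with the reference implementation
  skip_if_not_installed("edgeR")
  keep_ref <- edgeR::filterByExpr(counts, group = cm$samples$timepoint)
  expect_identical(rownames(kept$counts), names(which(keep_ref)))
})

test_that("expression filter drops zero rows, keeps saturated input, is idempotent", {
  withr::local_seed(2)
  counts <- matrix(rpois(40 * 6, 200), 40, 6,
                   dimnames = list(sprintf("m%02d", 1:40), sprintf("s%d", 1:6)))
  counts[1, ] <- 0
  cm <- toy_counts(counts, 3)
  f1 <- suppressMessages(filter_low_counts(cm))
  expect_false("m01" %in% rownames(f1$counts))
  expect_equal(nrow(f1$counts), 39)  # all others far above threshold
  f2 <- suppressMessages(filter_low_counts(f1))
  expect_identical(f1$counts, f2$counts)
  cm_zero <- toy_counts(matrix(0L, 3, 4, dimnames = list(letters[1:3],
                                                         sprintf("s%d", 1:4))), 2)
  expect_error(filter_low_counts(cm_zero), class = "evnetprop_empty_result")
})

test_that("TMM factors are 1 for identical or depth-scaled libraries", {
  withr::local_seed(3)
  base <- rpois(200, 100) + 1
  cm <- toy_counts(cbind(s1 = base, s2 = base))
  expect_equal(unname(tmm_factors(cm)), c(1, 1))
  cm2 <- toy_counts(cbind(s1 = base, s2 = 2L * base))
  expect_equal(unname(tmm_factors(cm2)), c(1, 1))
})

test_that("TMM corrects composition bias and matches the reference implementation", {
  withr::local_seed(4)
  a <- rpois(400, 150) + 1
  b <- a
  b[1:200] <- 4L * b[1:200]  # half the miRNAs 4x up in sample B
  cm <- toy_counts(cbind(sA = a, sB = b))
  f <- tmm_factors(cm)
  expect_gt(f[["sB"]], 1)
  expect_lt(f[["sA"]], 1)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-8)

  skip_if_not_installed("edgeR")
  ref <- edgeR::calcNormFactors(cbind(sA = a, sB = b), method = "TMM")
  expect_equal(unname(f), unname(ref), tolerance = 1e-6)

  # and on a larger multi-sample matrix
  m <- matrix(rnbinom(300 * 8, mu = 80, size = 5), 300, 8,
              dimnames = list(NULL, sprintf("s%d", 1:8)))
  m[1:50, 1:2] <- m[1:50, 1:2] * 5L
  rownames(m) <- sprintf("m%03d", 1:300)
  f2 <- tmm_factors(toy_counts(m, 4))
  ref2 <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(f2), unname(ref2), tolerance = 1e-6)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-8)
})

test_that("log-CPM matches its arithmetic definition and is depth-invariant", {
  counts <- matrix(c(100, 1000, 999900 - 1000,
                     100, 1000, 999900 - 1000), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cm <- toy_counts(counts, 1)
  ne <- log_cpm(cm, prior_count = 0)
  expect_equal(ne$log_cpm["a", "s1"], log2(100), tolerance = 1e-12)

  cm2 <- toy_counts(cbind(s1 = counts[, 1], s2 = 2 * counts[, 1]), 1)
  ne2 <- log_cpm(cm2, prior_count = 0)
  expect_equal(ne2$log_cpm[, "s1"], ne2$log_cpm[, "s2"], tolerance = 1e-12)

  # prior keeps zeros finite and preserves monotonicity in the count
  counts3 <- matrix(c(0, 5, 50, 0, 5, 50), 3, 2,
                    dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ne3 <- log_cpm(toy_counts(counts3, 1), prior_count = 0.5)
  expect_true(all(is.finite(ne3$log_cpm)))
  expect_true(all(diff(ne3$log_cpm[, "s1"]) > 0))

  skip_if_not_installed("edgeR")
  withr::local_seed(5)
  m <- matrix(rpois(100 * 4, 40), 100, 4,
              dimnames = list(sprintf("m%03d", 1:100), sprintf("s%d", 1:4)))
  ref <- edgeR::cpm(m, log = TRUE, prior.count = 0.5)
  expect_equal(log_cpm(toy_counts(m, 2), prior_count = 0.5)$log_cpm, ref,
               tolerance = 1e-10)
})

test_that("unmoderated paired test reproduces the textbook paired t exactly", {
  withr::local_seed(6)
  n <- 8
  lc <- matrix(rnorm(3 * 2 * n, mean = 8), 3, 2 * n)
  rownames(lc) <- c("m1", "m2", "m3")
  colnames(lc) <- as.vector(rbind(sprintf("S%02d_pre", 1:n), sprintf("S%02d_post", 1:n)))
  lc[2, seq(2, 2 * n, 2)] <- lc[2, seq(2, 2 * n, 2)] + 2
  samples <- tibble::tibble(sample_id = colnames(lc),
                            subject_id = rep(sprintf("S%02d", 1:n), each = 2),
                            timepoint = rep(c("pre", "post"), n))
  ne <- structure(list(log_cpm = lc, tmm_factors = rep(1, 2 * n),
                       effective_lib_sizes = rep(1e6, 2 * n), samples = samples),
                  class = "normalized_expression")
  de <- paired_de_test(ne, shrink = FALSE)
  for (i in 1:3) {
    d <- lc[i, seq(2, 2 * n, 2)] - lc[i, seq(1, 2 * n, 2)]
    tt <- t.test(d)
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-10)
    expect_equal(de$log2fc[i], unname(tt$estimate), tolerance = 1e-12)
  }
  expect_equal(de$call[2], "up")
})

test_that("a miRNA identical pre/post in every subject is flat and not DE", {
  lc <- rbind(m1 = rep(c(5, 5), 4), m2 = rep(c(4, 7), 4))
  colnames(lc) <- as.vector(rbind(sprintf("S%d_pre", 1:4), sprintf("S%d_post", 1:4)))
  samples <- tibble::tibble(sample_id = colnames(lc),
                            subject_id = rep(sprintf("S%d", 1:4), each = 2),
                            timepoint = rep(c("pre", "post"), 4))
  ne <- structure(list(log_cpm = lc, samples = samples),
                  class = "normalized_expression")
  de <- paired_de_test(ne, shrink = FALSE)
  expect_equal(de$log2fc[de$mirna_id == "m1"], 0)
  expect_equal(de$p_value[de$mirna_id == "m1"], 1)
  expect_equal(de$call[de$mirna_id == "m1"], "not_de")
})

test_that("moderated test shrinks variances and broadly agrees with limma", {
  skip_if_not_installed("limma")
  cfg <- synth_config(n_mirnas = 150, n_de_mirnas = 10, seed = 31)
  g <- generate_counts(cfg)
  cm <- suppressMessages(filter_low_counts(g$counts))
  ne <- log_cpm(cm, tmm_factors(cm))
  de <- paired_de_test(ne, shrink = TRUE)

  meta <- ne$samples
  pre <- meta$sample_id[meta$timepoint == "pre"][order(meta$subject_id[meta$timepoint == "pre"])]
  post <- meta$sample_id[meta$timepoint == "post"][order(meta$subject_id[meta$timepoint == "post"])]
  d <- ne$log_cpm[, post] - ne$log_cpm[, pre]
  fit <- limma::eBayes(limma::lmFit(d, matrix(1, ncol(d), 1)))
  expect_equal(de$log2fc, unname(fit$coefficients[, 1]), tolerance = 1e-10)
  # same DE calls at the published thresholds for the vast majority of miRNAs
  call_limma <- classify_de(fit$coefficients[, 1], fit$p.value[, 1])
  expect_gt(mean(de$call == call_limma), 0.95)
})

test_that("type-I error on null data is near nominal without shrinkage", {
  ps <- unlist(lapply(1:3, function(s) {
    g <- generate_counts(synth_config(n_mirnas = 250, n_de_mirnas = 0, seed = 100 + s))
    cm <- suppressMessages(filter_low_counts(g$counts))
    ne <- log_cpm(cm, tmm_factors(cm))
    paired_de_test(ne, shrink = FALSE)$p_value
  }))
  frac <- mean(ps < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(ps)) + 0.01)
})

test_that("planted effects are recovered with high sensitivity", {
  hits <- vapply(1:10, function(s) {
    cfg <- synth_config(n_subjects = 10, n_mirnas = 150, n_de_mirnas = 8,
                        de_log2fc = 2, nb_dispersion = 0.1, seed = 200 + s)
    dat <- generate_counts(cfg)
    de <- suppressMessages(run_de(dat$counts))
    mean(dat$truth$de_mirna_ids %in% de$mirna_id[de$call == "up"])
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("DE classification applies the thresholds symmetrically", {
  expect_equal(classify_de(1.5, 0.01), "up")
  expect_equal(classify_de(0.5, 0.001), "not_de")
  expect_equal(classify_de(-1.2, 0.03), "down")
  expect_equal(classify_de(1.5, 0.2), "not_de")
  # pure function: permuting rows permutes calls identically
  lfc <- c(2, -3, 0.2, 1.1, -1.01)
  p <- c(0.001, 0.04, 0.01, 0.049, 0.02)
  perm <- c(3, 1, 5, 2, 4)
  expect_identical(classify_de(lfc, p)[perm], classify_de(lfc[perm], p[perm]))
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::local_seed(8)
  p <- runif(50)^2
  expect_equal(bh_adjust(p), bh_direct_oracle(p), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.1, 1.2)), "p-values")
})
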