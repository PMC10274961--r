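logistic_loglik <- function(beta, x, y) {
  eta <- beta[1] + beta[2] * x
  sum(y * eta - log1p(exp(eta)))
}

#' Logistic regression of hallmark labels on perturbation counts
#'
#' Fits `logit P(label = 1) = beta0 + beta1 * count` by maximum likelihood
#' using iteratively reweighted least squares (Newton-Raphson on the
#' Bernoulli log-likelihood with logit link), with step-halving so the
#' log-likelihood never decreases, and Wald standard errors from the inverse
#' observed information. Complete or quasi-complete separation is detected
#' (diverging coefficients with fitted probabilities collapsing to 0/1) and
#' raised as an explicit error rather than returned as huge coefficients.
#'
#' @param data Data frame with one row per pathway.
#' @param x,y Column names (strings or bare names) holding the perturbation
#'   count and the binary hallmark label; defaults `count` and `label`.
#' @param standardize Center/scale the predictor before fitting (coefficients
#'   are reported on the original scale).
#' @param tol Convergence tolerance on the coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @return A `logistic_fit` object: coefficients, standard errors,
#'   covariance, fitted probabilities, log-likelihood, convergence info.
#' @export
#' @examples
#' d <- data.frame(count = 0:19, label = rbinom(20, 1, plogis(-1 + 0.2 * (0:19))))
#' fit <- fit_logistic(d)
#' tidy(fit)
fit_logistic <- function(data, x = "count", y = "label", standardize = FALSE,
                         tol = 1e-8, max_iter = 100) {
  x <- rlang::as_name(rlang::enquo(x))
  y <- rlang::as_name(rlang::enquo(y))
  xv <- as.numeric(data[[x]])
  yv <- as.numeric(data[[y]])
  assert_that(all(yv %in% c(0, 1)), "labels must be binary 0/1")
  assert_that(length(unique(yv)) == 2,
              "single-class outcome: both hallmark classes are required")
  assert_that(all(is.finite(xv)), "predictor must be finite")
  ctr <- 0; scl <- 1
  if (standardize) {
    ctr <- mean(xv); scl <- stats::sd(xv)
    assert_that(scl > 0, "constant predictor cannot be standardized")
    xv <- (xv - ctr) / scl
  }
  X <- cbind(1, xv)
  beta <- c(stats::qlogis(mean(yv)), 0)
  ll <- logistic_loglik(beta, xv, yv)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- stats::plogis(X %*% beta)
    w <- as.numeric(mu * (1 - mu))
    info <- crossprod(X, X * w)
    score <- crossprod(X, yv - as.numeric(mu))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step))
      abort("singular information matrix in IRLS (separation or constant predictor)",
            class = "evnetprop_separation_error")
    # step-halving: never accept a likelihood decrease
    lam <- 1
    repeat {
      cand <- beta + lam * as.numeric(step)
      ll_new <- logistic_loglik(cand, xv, yv)
      if (ll_new >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- as.numeric(stats::plogis(X %*% beta))
  # separation: monotone likelihood pushes |beta| out while every fitted
  # probability collapses onto its observed label
  eps <- 1e-6
  separated <- max(abs(beta)) > 15 &&
    all(abs(yv - mu) < 1e-3 | mu < eps | mu > 1 - eps) &&
    all((yv == 1) == (mu > 0.5))
  if (separated || (!converged && max(abs(beta)) > 15))
    abort("complete separation detected: the perturbation counts perfectly split the hallmark labels",
          class = "evnetprop_separation_error")
  if (!converged)
    warn(sprintf("IRLS did not reach tolerance in %d iterations", max_iter))
  w <- mu * (1 - mu)
  vc <- solve(crossprod(X, X * w))
  # back-transform to the original predictor scale
  if (standardize) {
    Tm <- matrix(c(1, 0, -ctr / scl, 1 / scl), 2, 2)
    beta <- as.numeric(Tm %*% beta)
    vc <- Tm %*% vc %*% t(Tm)
  }
  se <- sqrt(diag(vc))
  zstat <- beta / se
  structure(list(
    coefficients = stats::setNames(beta, c("beta0", "beta1")),
    std_errors = stats::setNames(se, c("beta0", "beta1")),
    vcov = vc, fitted = mu, x = as.numeric(data[[x]]), y = yv,
    log_lik = ll, converged = converged, n_iterations = it,
    n = length(yv), x_name = x, y_name = y,
    p_values = 2 * stats::pnorm(-abs(zstat))),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, logLik = %.3f (%s in %d IRLS iterations)\n",
              x$n, x$log_lik,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  print(tidy(x))
  invisible(x)
}

#' Predicted probability of the aged-hallmark phenotype
#'
#' `plogis(beta0 + beta1 * x)`, elementwise.
#'
#' @param fit A `logistic_fit`.
#' @param x Perturbation counts (default: the training values).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(fit, x = NULL) {
  assert_that(fit$converged, "fit did not converge; refusing to predict")
  x <- x %||% fit$x
  stats::plogis(fit$coefficients[["beta0"]] + fit$coefficients[["beta1"]] * x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the logistic hallmark fit
#'
#' @param x A `logistic_fit`.
#' @param conf_level Wald confidence level.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `conf_low`, `conf_high`.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std_error = unname(x$std_errors),
         statistic = unname(x$coefficients / x$std_errors),
         p_value = unname(x$p_values),
         conf_low = unname(x$coefficients - z * x$std_errors),
         conf_high = unname(x$coefficients + z * x$std_errors))
}

#' @rdname tidy.logistic_fit
#' @return `glance()`: a one-row tibble with `n`, `log_lik`, `aic`,
#'   `converged`, `n_iterations`.
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(n = x$n, log_lik = x$log_lik, aic = -2 * x$log_lik + 4,
         converged = x$converged, n_iterations = x$n_iterations)
}

#' Relate perturbation counts to hallmark labels
#'
#' Joins a perturbation-count table with a hallmark-label table by pathway
#' and fits the logistic model. Warns when fewer than 30 pathways are
#' available (logistic fits on very few pathways are unstable).
#'
#' @param counts Tibble `pathway`, `count` (from [perturbation_counts()]).
#' @param hallmarks Tibble `pathway`, `label` (binary).
#' @param ... Passed to [fit_logistic()].
#' @return A `logistic_fit` with an extra `data` element (the joined table
#'   augmented with `probability`, the fitted aged-phenotype probability).
#' @export
hallmark_association <- function(counts, hallmarks, ...) {
  d <- inner_join(as_tibble(counts), as_tibble(hallmarks), by = "pathway")
  assert_that(nrow(d) > 0, "no pathway names shared between counts and hallmark labels")
  if (nrow(d) < 30)
    warn(sprintf("only %d pathways available; logistic estimates will be unstable",
                 nrow(d)))
  fit <- fit_logistic(d, x = "count", y = "label", ...)
  fit$data <- d |> mutate(probability = predict_probability(fit, d$count))
  fit
}
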