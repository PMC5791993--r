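#' Tidy a fitted model
#'
#' One row per parameter in the broom convention, grouped by model
#' component: `"measurement"` (loadings, thresholds), `"concomitant"`
#' (slopes), `"structural"` (fixed effects, latent effects, threshold) and
#' `"variance"` (`sigma_u2`). Standard errors are cluster-robust sandwich
#' SEs by default; `std.error.naive` carries the inverse-information SEs.
#' Parameters held fixed during estimation get `NA` standard errors.
#'
#' @param x An `hlc_fit` object.
#' @param conf.int Add normal-approximation confidence bounds.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble: `component`, `term`, `estimate`, `std.error`,
#'   `std.error.naive`, `statistic`, `p.value` (and optionally `conf.low`,
#'   `conf.high`).
#' @method tidy hlc_fit
#' @export
tidy.hlc_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  p <- x$params
  K <- length(p$loadings); L <- length(p$slopes); P <- length(p$beta)
  term <- c(par_labels(p)[seq_len(2 * K + L + P)],
            "gamma_linear", "gamma_quadratic", "tau", "sigma_u2")
  component <- c(rep("measurement", 2 * K), rep("concomitant", L),
                 rep("structural", P + 3), "variance")
  estimate <- c(p$loadings, p$thresholds, p$slopes, p$beta,
                p$gamma_linear, p$gamma_quadratic, p$tau, p$sigma_u2)
  se <- se_naive <- rep(NA_real_, length(term))
  if (!is.null(x$vcov_robust)) {
    idx <- match(x$free_labels, term)
    se[idx] <- sqrt(pmax(diag(x$vcov_robust), 0))
    se_naive[idx] <- sqrt(pmax(diag(x$vcov_naive), 0))
  }
  out <- tibble::tibble(
    component = component, term = term, estimate = estimate,
    std.error = se, std.error.naive = se_naive,
    statistic = estimate / se,
    p.value = 2 * pnorm(-abs(estimate / se))
  )
  if (conf.int) {
    zq <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - zq * out$std.error
    out$conf.high <- out$estimate + zq * out$std.error
  }
  out
}

#' Model-level summary of a fit
#'
#' @param x An `hlc_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `nobs`, `n_clusters`, `n_items`,
#'   `df`, `icc`, `sigma_u2`, `converged`, `n_iter`, `gradient_norm`.
#' @export
glance.hlc_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, nobs = x$n, n_clusters = x$n_clusters,
    n_items = length(x$params$loadings),
    df = length(x$free_idx), icc = x$icc, sigma_u2 = x$params$sigma_u2,
    converged = x$converged, n_iter = x$n_iter,
    gradient_norm = x$gradient_norm
  )
}
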