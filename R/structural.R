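#' Structural linear predictor
#'
#' Latent-response linear predictor of the probit choice model:
#' `x' beta + gamma_linear * z + gamma_quadratic * z^2 + u - tau`. A success
#' is observed when the latent response exceeds the threshold `tau`, which
#' replaces the intercept; subtracting `tau` here means the success
#' probability is simply the standard normal CDF of the returned value.
#'
#' @param x Numeric vector of fixed-effect covariates (length must match
#'   `params$beta`).
#' @param z Latent living-conditions score.
#' @param u Cluster random-intercept value.
#' @param params An `hlc_params` object (structural block used).
#' @return The linear predictor, a real number.
#' @export
linear_predictor <- function(x, z, u, params) {
  stopifnot(inherits(params, "hlc_params"))
  x <- as.numeric(x)
  if (length(x) != length(params$beta)) {
    abort(sprintf("`x` has length %d but `beta` has length %d.",
                  length(x), length(params$beta)))
  }
  sum(x * params$beta) + params$gamma_linear * z +
    params$gamma_quadratic * z^2 + u - params$tau
}

#' Conditional choice probability
#'
#' Probability of a success given covariates, the latent score and the
#' cluster random intercept, under standard normal errors:
#' `pnorm(linear_predictor(...))`.
#'
#' @inheritParams linear_predictor
#' @return A probability strictly inside (0, 1).
#' @export
choice_prob <- function(x, z, u, params) {
  p <- pnorm(linear_predictor(x, z, u, params))
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Marginal choice probability (closed form)
#'
#' Success probability with the latent score and random intercept integrated
#' out, valid only when the quadratic latent effect is zero: with
#' `z ~ N(mu, 1)` and `u ~ N(0, sigma_u2)`,
#' `P(y = 1 | x) = pnorm((x'beta + gamma_linear * mu - tau) /
#' sqrt(1 + gamma_linear^2 + sigma_u2))`.
#'
#' Serves as an independent closed-form check of the quadrature integration.
#'
#' @inheritParams linear_predictor
#' @param latent_mean Mean of the latent score distribution (`theta' w`).
#' @param sigma_u2 Random-intercept variance; defaults to the value in
#'   `params`.
#' @return A probability.
#' @export
marginal_choice_prob <- function(x, params, latent_mean = 0,
                                 sigma_u2 = params$sigma_u2) {
  stopifnot(inherits(params, "hlc_params"))
  if (params$gamma_quadratic != 0) {
    abort(paste0("closed-form marginal probability requires gamma_quadratic ",
                 "= 0; use the quadrature path (hlc_loglik) instead."))
  }
  x <- as.numeric(x)
  if (length(x) != length(params$beta)) {
    abort(sprintf("`x` has length %d but `beta` has length %d.",
                  length(x), length(params$beta)))
  }
  num <- sum(x * params$beta) + params$gamma_linear * latent_mean - params$tau
  pnorm(num / sqrt(1 + params$gamma_linear^2 + sigma_u2))
}

#' Intraclass correlation of the latent response
#'
#' Share of latent-response variance attributable to clusters under the
#' probit model: `sigma_u2 / (1 + sigma_u2)`, the residual variance being
#' fixed at 1 for identification.
#'
#' @param sigma_u2 Random-intercept variance(s), non-negative.
#' @return Value(s) in `[0, 1)`.
#' @examples
#' icc(0.230)
#' @export
icc <- function(sigma_u2) {
  if (any(!is.finite(sigma_u2)) || any(sigma_u2 < 0)) {
    abort("`sigma_u2` must be finite and non-negative.")
  }
  sigma_u2 / (1 + sigma_u2)
}

#' Person-level conditional density
#'
#' Joint probability of one person's observed data given the latent score
#' `z` and cluster intercept `u`: the product of the item response
#' probabilities (items are conditionally independent given `z`) and the
#' outcome probability. Missing items and a missing outcome contribute a
#' factor of 1.
#'
#' @param z,u Latent score and cluster intercept (finite scalars).
#' @param params An `hlc_params` object.
#' @param y Outcome in `{0, 1}` or `NA` (missing).
#' @param x Fixed-effect covariate vector (needed when `y` is observed and
#'   `beta` is non-empty).
#' @param items Integer vector of item responses in `{0, 1}`, `NA` allowed;
#'   length must match the measurement block.
#' @param item_link Item link, `"probit"` (default) or `"logit"`.
#' @return A non-negative density value.
#' @export
person_conditional_density <- function(z, u, params, y = NA,
                                       x = numeric(0), items = NULL,
                                       item_link = c("probit", "logit")) {
  stopifnot(inherits(params, "hlc_params"))
  item_link <- match.arg(item_link)
  if (!is.finite(z) || !is.finite(u)) abort("`z` and `u` must be finite.")
  K <- length(params$loadings)
  if (is.null(items)) items <- rep(NA_integer_, K)
  if (length(items) != K) {
    abort(sprintf("`items` has length %d but the model has %d item(s).",
                  length(items), K))
  }
  dens <- 1
  for (k in seq_len(K)) {
    if (is.na(items[k])) next
    pk <- item_response_prob(z, params$loadings[k], params$thresholds[k],
                             link = item_link)
    dens <- dens * if (items[k] == 1) pk else 1 - pk
  }
  if (!is.na(y)) {
    py <- choice_prob(x, z, u, params)
    dens <- dens * if (y == 1) py else 1 - py
  }
  dens
}
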