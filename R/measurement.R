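#' Item response probability
#'
#' Probability that a binary asset/dwelling item is endorsed ("owned") at a
#' given level of the latent living-conditions score, under the
#' factor-analytic item parameterization `P(v = 1 | z) = F(loading * z -
#' threshold)` with a probit (normal-ogive, default) or logistic link.
#'
#' @param z Latent score value(s).
#' @param loading Item loading (discrimination).
#' @param threshold Item threshold, on the link scale.
#' @param link Item link function, `"probit"` (default) or `"logit"`.
#' @return Probabilities strictly inside (0, 1), vectorized over the inputs.
#' @examples
#' item_response_prob(0, loading = 1.457, threshold = -0.658)
#' @export
item_response_prob <- function(z, loading, threshold,
                               link = c("probit", "logit")) {
  link <- match.arg(link)
  if (!all(is.finite(z), is.finite(loading), is.finite(threshold))) {
    abort("`z`, `loading` and `threshold` must all be finite.")
  }
  eta <- loading * z - threshold
  p <- if (link == "probit") pnorm(eta) else stats::plogis(eta)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Item difficulty
#'
#' The difficulty of an item is the ratio threshold / loading: the latent
#' level at which the endorsement probability is exactly one half. In the
#' living-conditions context it measures how rare an asset is — high
#' difficulty means only well-off households own it; a negative difficulty
#' means the item is common already at the average latent level.
#'
#' @param loading Item loading(s); must be non-zero.
#' @param threshold Item threshold(s).
#' @return `threshold / loading`, vectorized.
#' @examples
#' item_difficulty(1.457, -0.658)  # electrification-type item: common
#' item_difficulty(1.015, 3.208)   # car-type item: rare
#' @export
item_difficulty <- function(loading, threshold) {
  if (any(loading == 0)) {
    abort("item difficulty is undefined for a zero loading (threshold/loading).")
  }
  threshold / loading
}

#' Item discrimination
#'
#' The discrimination of an item equals its loading: its capability to
#' differentiate households along the latent living-conditions scale.
#'
#' @param loading Item loading(s).
#' @return The loading, unchanged.
#' @export
item_discrimination <- function(loading) {
  loading
}

#' Marginal item prevalence
#'
#' Population endorsement probability of an item when the latent score is
#' integrated over a normal distribution: for a probit item link this has the
#' closed form `pnorm((loading * mean - threshold) / sqrt(1 + loading^2 *
#' sd^2))`. The sample analogue is the observed item prevalence ("aggregate"
#' column of an item-parameter table).
#'
#' @param loading,threshold Item parameters.
#' @param latent_mean,latent_sd Moments of the latent score distribution;
#'   `latent_sd` must be non-negative.
#' @param link Only `"probit"` has a closed form; `"logit"` raises an error
#'   (use the quadrature path instead).
#' @return Marginal probability, vectorized.
#' @examples
#' marginal_item_prevalence(1.457, -0.658)  # ~0.68 at a N(0,1) latent score
#' @export
marginal_item_prevalence <- function(loading, threshold,
                                     latent_mean = 0, latent_sd = 1,
                                     link = c("probit", "logit")) {
  link <- match.arg(link)
  if (link == "logit") {
    abort("no closed form for the logit item link; integrate item_response_prob by quadrature.")
  }
  if (any(latent_sd < 0)) abort("`latent_sd` must be non-negative.")
  pnorm((loading * latent_mean - threshold) / sqrt(1 + loading^2 * latent_sd^2))
}

#' Item parameter table
#'
#' Tidies the measurement block of a parameter set or fitted model into the
#' conventional item-response layout: one row per item with loading,
#' threshold, difficulty and discrimination, plus the model-implied marginal
#' prevalence at the given latent moments.
#'
#' @param x An `hlc_params` or `hlc_fit` object.
#' @param latent_mean,latent_sd Latent moments for the implied prevalence
#'   column.
#' @return A tibble with one row per item.
#' @export
item_parameter_table <- function(x, latent_mean = 0, latent_sd = 1) {
  p <- if (inherits(x, "hlc_fit")) x$params else x
  if (!inherits(p, "hlc_params")) abort("`x` must be an hlc_params or hlc_fit object.")
  tibble::tibble(
    item = p$item_names %||% character(0),
    loading = p$loadings,
    threshold = p$thresholds,
    difficulty = if (length(p$loadings)) item_difficulty(p$loadings, p$thresholds) else numeric(0),
    discrimination = item_discrimination(p$loadings),
    implied_prevalence = if (length(p$loadings)) {
      marginal_item_prevalence(p$loadings, p$thresholds, latent_mean, latent_sd)
    } else numeric(0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
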