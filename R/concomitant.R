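#' Concomitant latent mean
#'
#' Expected value of the latent living-conditions score given concomitant
#' (contextual) covariates: `theta' w`, with no intercept so the model stays
#' identified and each slope is the departure from the reference category.
#' The latent variance is fixed at 1, so slopes are in latent SD units. With
#' no concomitant covariates the latent score is standard normal for everyone.
#'
#' @param w Numeric vector of concomitant covariate values (length L), or a
#'   matrix with L columns for several observations.
#' @param slopes Numeric vector of concomitant slopes, length L, or an
#'   `hlc_params` object whose `slopes` element is used.
#' @return The latent mean(s) `theta' w`; 0 when L = 0.
#' @examples
#' latent_mean(1, slopes = 1.437)  # urban household
#' latent_mean(0, slopes = 1.437)  # rural reference
#' @export
latent_mean <- function(w, slopes) {
  if (inherits(slopes, "hlc_params")) slopes <- slopes$slopes
  slopes <- as.numeric(slopes)
  if (length(slopes) == 0) {
    n <- if (is.matrix(w)) nrow(w) else 1L
    return(rep(0, n))
  }
  if (is.matrix(w)) {
    if (ncol(w) != length(slopes)) {
      abort(sprintf("`w` has %d column(s) but %d slope(s) were given.",
                    ncol(w), length(slopes)))
    }
    return(drop(w %*% slopes))
  }
  if (length(w) != length(slopes)) {
    abort(sprintf("`w` has length %d but %d slope(s) were given.",
                  length(w), length(slopes)))
  }
  sum(w * slopes)
}
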