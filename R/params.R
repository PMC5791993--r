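#' Model parameter container
#'
#' Bundles the three parameter blocks of the joint model: the measurement
#' block (per-item loadings and thresholds of the normal-ogive IRT model),
#' the concomitant block (slopes of the latent mean on contextual covariates),
#' and the structural block (fixed effects, linear and quadratic latent
#' effects, outcome threshold, random-intercept variance).
#'
#' Identification follows the usual conventions for this model class: the
#' latent variable has unit variance and zero concomitant intercept, the
#' outcome residual is standard normal, and the threshold `tau` replaces the
#' outcome intercept.
#'
#' @param loadings Numeric vector of item loadings (discriminations), length K.
#' @param thresholds Numeric vector of item thresholds, length K, probit scale.
#' @param item_names Optional character vector of item labels.
#' @param slopes Numeric vector of concomitant slopes (latent SD units).
#' @param concomitant_names Optional labels for the concomitant covariates.
#' @param beta Numeric vector of structural fixed effects (probit scale).
#' @param beta_names Optional labels for the fixed effects.
#' @param gamma_linear,gamma_quadratic Linear and quadratic effects of the
#'   latent score on the outcome latent response.
#' @param tau Outcome threshold (replaces the intercept).
#' @param sigma_u2 Cluster random-intercept variance, must be `>= 0`.
#'
#' @return An object of class `hlc_params`.
#' @examples
#' hlc_params(loadings = c(1.4, 1.0), thresholds = c(-0.5, 2.0),
#'            slopes = 1.4, gamma_linear = 0.2, tau = 0.5, sigma_u2 = 0.23)
#' @export
hlc_params <- function(loadings = numeric(0), thresholds = numeric(0),
                       item_names = NULL,
                       slopes = numeric(0), concomitant_names = NULL,
                       beta = numeric(0), beta_names = NULL,
                       gamma_linear = 0, gamma_quadratic = 0,
                       tau = 0, sigma_u2 = 0) {
  loadings <- as.numeric(loadings)
  thresholds <- as.numeric(thresholds)
  if (length(loadings) != length(thresholds)) {
    abort("`loadings` and `thresholds` must have the same length.")
  }
  slopes <- as.numeric(slopes)
  beta <- as.numeric(beta)
  vals <- c(loadings, thresholds, slopes, beta,
            gamma_linear, gamma_quadratic, tau, sigma_u2)
  if (!all(is.finite(vals))) abort("all parameters must be finite.")
  if (sigma_u2 < 0) abort("`sigma_u2` must be non-negative.")
  K <- length(loadings)
  if (is.null(item_names) && K > 0) item_names <- paste0("item_", seq_len(K))
  if (is.null(concomitant_names) && length(slopes) > 0) {
    concomitant_names <- paste0("w_", seq_along(slopes))
  }
  if (is.null(beta_names) && length(beta) > 0) {
    beta_names <- paste0("x_", seq_along(beta))
  }
  structure(
    list(loadings = loadings, thresholds = thresholds,
         item_names = item_names,
         slopes = slopes, concomitant_names = concomitant_names,
         beta = beta, beta_names = beta_names,
         gamma_linear = as.numeric(gamma_linear),
         gamma_quadratic = as.numeric(gamma_quadratic),
         tau = as.numeric(tau), sigma_u2 = as.numeric(sigma_u2)),
    class = "hlc_params"
  )
}

#' @export
print.hlc_params <- function(x, ...) {
  cat("<hlc_params>\n")
  K <- length(x$loadings)
  cat("  measurement: ", K, " item(s)\n", sep = "")
  if (K > 0) {
    tab <- item_parameter_table(x)
    print(as.data.frame(tab), digits = 4, row.names = FALSE)
  }
  if (length(x$slopes) > 0) {
    cat("  concomitant slopes: ",
        paste0(x$concomitant_names, " = ", format(x$slopes, digits = 4),
               collapse = ", "), "\n", sep = "")
  }
  if (length(x$beta) > 0) {
    cat("  fixed effects: ",
        paste0(x$beta_names, " = ", format(x$beta, digits = 4),
               collapse = ", "), "\n", sep = "")
  }
  cat("  gamma_linear = ", format(x$gamma_linear, digits = 4),
      ", gamma_quadratic = ", format(x$gamma_quadratic, digits = 4),
      ", tau = ", format(x$tau, digits = 4),
      ", sigma_u2 = ", format(x$sigma_u2, digits = 4), "\n", sep = "")
  invisible(x)
}

# natural-scale packing order used throughout:
# lambda(K), kappa(K), theta(L), beta(P), gamma1, gamma2, tau, sigma_u (SD!)
pack_params <- function(p) {
  c(p$loadings, p$thresholds, p$slopes, p$beta,
    p$gamma_linear, p$gamma_quadratic, p$tau, sqrt(p$sigma_u2))
}

unpack_params <- function(vec, template) {
  K <- length(template$loadings)
  L <- length(template$slopes)
  P <- length(template$beta)
  i <- 0
  take <- function(m) {
    out <- vec[seq_len(m) + i]
    i <<- i + m
    out
  }
  hlc_params(
    loadings = take(K), thresholds = take(K), item_names = template$item_names,
    slopes = take(L), concomitant_names = template$concomitant_names,
    beta = take(P), beta_names = template$beta_names,
    gamma_linear = take(1), gamma_quadratic = take(1), tau = take(1),
    sigma_u2 = take(1)^2
  )
}

par_labels <- function(p) {
  items <- p$item_names %||% character(0)
  c(if (length(items)) paste0("loading[", items, "]"),
    if (length(items)) paste0("threshold[", items, "]"),
    if (length(p$slopes)) paste0("slope[", p$concomitant_names, "]"),
    if (length(p$beta)) p$beta_names,
    "gamma_linear", "gamma_quadratic", "tau", "sigma_u")
}

#' Gauss-Hermite quadrature specification
#'
#' Node counts for the nested numerical integration of the latent score
#' (inner, per person) and the cluster random intercept (outer, per cluster).
#' Nodes are standardized to the respective priors: the latent score has unit
#' prior variance around its concomitant mean, the random intercept has
#' standard deviation `sigma_u`. Odd node counts include the prior mode.
#'
#' @param n_z Number of quadrature nodes for the latent score (`>= 3`).
#' @param n_u Number of quadrature nodes for the random intercept (`>= 3`).
#' @return An object of class `quad_spec` with nodes and weights attached.
#' @examples
#' quad_spec(15, 9)
#' @export
quad_spec <- function(n_z = 15, n_u = 15) {
  n_z <- as.integer(n_z); n_u <- as.integer(n_u)
  if (n_z < 3 || n_u < 3) abort("quadrature node counts must be >= 3.")
  gz <- pracma::gaussHermite(n_z)
  gu <- pracma::gaussHermite(n_u)
  structure(list(n_z = n_z, n_u = n_u,
                 zx = gz$x, zw = gz$w, ux = gu$x, uw = gu$w),
            class = "quad_spec")
}

#' @export
print.quad_spec <- function(x, ...) {
  cat("<quad_spec> n_z =", x$n_z, ", n_u =", x$n_u, "\n")
  invisible(x)
}
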