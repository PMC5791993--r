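# Internal: turn a person-level data frame plus column mappings into the
# matrix bundle the C++ kernel consumes. Rows are reordered so clusters are
# contiguous; `order` maps back to the input row order.
prepare_choice_data <- function(data, outcome = NULL, items = character(0),
                                fixed_effects = character(0),
                                concomitants = character(0),
                                cluster, weights = NULL,
                                quadratic_terms = character(0),
                                centering = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) abort("`data` has no rows.")
  needed <- c(outcome, items, fixed_effects, concomitants, cluster, weights)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found in `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }

  ord <- order(match(data[[cluster]], unique(data[[cluster]])))
  data <- data[ord, , drop = FALSE]
  cl <- data[[cluster]]
  n <- nrow(data)

  check_binary <- function(v, what) {
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad) > 0) {
      abort(sprintf("%s must be 0/1 (or NA); offending row(s): %s",
                    what, paste(head(bad, 10), collapse = ", ")))
    }
    out <- as.integer(v)
    out[is.na(out)] <- -1L
    out
  }

  y <- if (!is.null(outcome)) check_binary(data[[outcome]], paste0("outcome `", outcome, "`"))
       else rep(-1L, n)

  V <- if (length(items) > 0) {
    vapply(items, function(cn) check_binary(data[[cn]], paste0("item `", cn, "`")),
           integer(n))
  } else matrix(0L, n, 0)
  if (!is.matrix(V)) V <- matrix(V, nrow = n)

  # quadratic continuous terms are formed inside the model: each listed
  # column is centered (default: its sample mean) and both the centered
  # column and its square enter the design
  centers <- list()
  x_cols <- list()
  x_names <- character(0)
  for (cn in fixed_effects) {
    xv <- as.numeric(data[[cn]])
    if (anyNA(xv)) abort(sprintf("fixed-effect column `%s` contains NA.", cn))
    if (cn %in% quadratic_terms) {
      ctr <- if (!is.null(centering) && !is.null(centering[[cn]])) centering[[cn]] else mean(xv)
      centers[[cn]] <- ctr
      xc <- xv - ctr
      x_cols <- c(x_cols, list(xc, xc^2))
      x_names <- c(x_names, cn, paste0(cn, "^2"))
    } else {
      x_cols <- c(x_cols, list(xv))
      x_names <- c(x_names, cn)
    }
  }
  X <- if (length(x_cols) > 0) do.call(cbind, x_cols) else matrix(0, n, 0)
  colnames(X) <- x_names

  W <- if (length(concomitants) > 0) {
    as.matrix(vapply(concomitants, function(cn) {
      wv <- as.numeric(data[[cn]])
      if (anyNA(wv)) abort(sprintf("concomitant column `%s` contains NA.", cn))
      wv
    }, numeric(n)))
  } else matrix(0, n, 0)
  if (!is.matrix(W)) W <- matrix(W, nrow = n)

  wt <- if (!is.null(weights)) as.numeric(data[[weights]]) else rep(1, n)
  bad_w <- which(!is.finite(wt) | wt <= 0)
  if (length(bad_w) > 0) {
    abort(sprintf("weights must be strictly positive; offending row(s): %s",
                  paste(head(bad_w, 10), collapse = ", ")))
  }

  starts <- which(!duplicated(cl))
  ends <- c(starts[-1] - 1L, n)

  list(y = y, X = X, V = V, W = W, wt = wt,
       cl_start = as.integer(starts - 1L), cl_end = as.integer(ends - 1L),
       cluster_ids = cl[starts], cluster = cl, order = ord, n = n,
       n_clusters = length(starts),
       item_names = items, x_names = x_names, w_names = concomitants,
       centers = centers, data = data)
}

# weights normalized to sum to the sample size (frequency-style convention)
normalize_weights <- function(wt) {
  wt * length(wt) / sum(wt)
}

call_kernel <- function(prep, params, quad, item_link = "probit",
                        wt = prep$wt, want_grad = FALSE, want_scores = FALSE,
                        want_post = FALSE) {
  joint_loglik_cpp(
    params$loadings, params$thresholds, params$slopes, params$beta,
    params$gamma_linear, params$gamma_quadratic, params$tau,
    sqrt(params$sigma_u2),
    prep$y, prep$X, prep$V, prep$W, wt,
    prep$cl_start, prep$cl_end,
    quad$zx, quad$zw, quad$ux, quad$uw,
    if (item_link == "logit") 1L else 0L,
    want_grad, want_scores, want_post
  )
}

#' Marginal log-(pseudo)likelihood of the joint model
#'
#' Evaluates the survey-weighted marginal log-likelihood of the joint
#' measurement + concomitant + structural model at fixed parameter values,
#' integrating the latent score (per person) and the cluster random
#' intercept (per cluster) by nested Gauss-Hermite quadrature. Weights are
#' used exactly as supplied (no normalization), entering as frequency-style
#' exponents on person contributions inside each cluster integral.
#'
#' @param data Person-level data frame.
#' @param params An `hlc_params` object.
#' @param outcome,items,fixed_effects,concomitants,cluster,weights Column
#'   names in `data`; `outcome` and `weights` may be `NULL`.
#' @param quad A [quad_spec()].
#' @param item_link Item link function.
#' @param by_cluster If `TRUE`, return the vector of per-cluster
#'   log-likelihood contributions (in cluster order of first appearance)
#'   instead of their sum.
#' @return The total log-likelihood (default) or a named vector of cluster
#'   contributions.
#' @export
hlc_loglik <- function(data, params, outcome = NULL, items = character(0),
                       fixed_effects = character(0),
                       concomitants = character(0), cluster,
                       weights = NULL, quad = quad_spec(),
                       item_link = c("probit", "logit"),
                       by_cluster = FALSE) {
  item_link <- match.arg(item_link)
  stopifnot(inherits(params, "hlc_params"))
  if (nrow(data) == 0) {
    return(if (by_cluster) setNames(numeric(0), character(0)) else 0)
  }
  prep <- prepare_choice_data(data, outcome = outcome, items = items,
                              fixed_effects = fixed_effects,
                              concomitants = concomitants, cluster = cluster,
                              weights = weights)
  if (ncol(prep$V) != length(params$loadings)) {
    abort("number of item columns does not match the measurement block of `params`.")
  }
  if (ncol(prep$X) != length(params$beta)) {
    abort("number of fixed-effect columns does not match `beta`.")
  }
  if (ncol(prep$W) != length(params$slopes)) {
    abort("number of concomitant columns does not match `slopes`.")
  }
  if (!by_cluster) {
    return(call_kernel(prep, params, quad, item_link)$loglik)
  }
  vapply(seq_len(prep$n_clusters), function(j) {
    sub <- prep
    sub$cl_start <- prep$cl_start[j]
    sub$cl_end <- prep$cl_end[j]
    call_kernel(sub, params, quad, item_link)$loglik
  }, numeric(1)) |> setNames(as.character(prep$cluster_ids))
}
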