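#' Control settings for model fitting
#'
#' @param gtol Convergence tolerance on the scaled gradient norm
#'   `max(abs(gradient)) / max(1, abs(loglik))`; the fit is flagged converged
#'   when the optimizer succeeds and this norm is below `gtol`.
#' @param max_iter Maximum optimizer iterations; `0` returns the starting
#'   values unoptimized with `converged = FALSE`.
#' @param sigma_u2 `NULL` to estimate the random-intercept variance, or a
#'   fixed non-negative value (e.g. `0` for a single-level model).
#' @param sigma_u2_start Starting value when `sigma_u2` is estimated.
#' @param degenerate_items What to do with items observed as all-0 or all-1:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @param se `"robust"` (sandwich + naive SEs, default) or `"none"` to skip
#'   the variance computation.
#' @param hessian_step Relative step for the finite-difference Hessian of the
#'   analytic gradient.
#' @param polish Follow the quasi-Newton stage with a tight gradient-polishing
#'   stage (default `TRUE`); `FALSE` trades a looser optimum for speed, useful
#'   in large simulation studies that only need the likelihood value.
#' @param normalize_weights Normalize weights to sum to the sample size
#'   before estimation (default `TRUE`).
#' @param centering Optional named list of centering constants for
#'   `quadratic_terms` columns; default is each column's sample mean.
#' @return A list of class `hlc_control`.
#' @export
hlc_control <- function(gtol = 1e-6, max_iter = 500, sigma_u2 = NULL,
                        sigma_u2_start = 0.1,
                        degenerate_items = c("drop", "error"),
                        se = c("robust", "none"), hessian_step = 1e-4,
                        normalize_weights = TRUE, centering = NULL,
                        polish = TRUE) {
  if (!is.null(sigma_u2) && (!is.finite(sigma_u2) || sigma_u2 < 0)) {
    abort("fixed `sigma_u2` must be non-negative.")
  }
  structure(list(gtol = gtol, max_iter = max_iter, sigma_u2 = sigma_u2,
                 sigma_u2_start = sigma_u2_start,
                 degenerate_items = match.arg(degenerate_items),
                 se = match.arg(se), hessian_step = hessian_step,
                 normalize_weights = normalize_weights,
                 centering = centering, polish = polish),
            class = "hlc_control")
}

# starting values: per-item univariate probit on a first-principal-component
# proxy score; outcome block from a plain probit including the proxy (and its
# square) as a stand-in for the latent score; concomitant slopes start at 0
make_start <- function(prep, wtn, latent_effect, sigma_u2_start, sigma_fixed) {
  K <- ncol(prep$V); P <- ncol(prep$X); L <- ncol(prep$W)
  loadings <- rep(1, K); thresholds <- rep(0, K)
  proxy <- NULL
  if (K > 0) {
    Vimp <- matrix(as.numeric(prep$V), nrow = prep$n)
    Vimp[Vimp < 0] <- NA
    cm <- colMeans(Vimp, na.rm = TRUE)
    for (k in seq_len(K)) Vimp[is.na(Vimp[, k]), k] <- cm[k]
    sds <- apply(Vimp, 2, stats::sd)
    keepv <- sds > 0
    proxy <- if (any(keepv)) {
      pc <- try(prcomp(Vimp[, keepv, drop = FALSE], center = TRUE,
                       scale. = TRUE)$x[, 1], silent = TRUE)
      if (inherits(pc, "try-error")) rowMeans(Vimp) else pc
    } else rep(0, prep$n)
    if (stats::sd(proxy) > 0) proxy <- as.numeric(scale(proxy))
    if (sum(proxy * (Vimp[, 1] - cm[1])) < 0) proxy <- -proxy
    for (k in seq_len(K)) {
      vk <- prep$V[, k]
      obs <- vk >= 0
      co <- try(suppressWarnings(
        coef(glm(vk[obs] ~ proxy[obs], family = binomial("probit")))),
        silent = TRUE)
      if (!inherits(co, "try-error") && all(is.finite(co))) {
        loadings[k] <- max(min(co[2], 5), -5)
        thresholds[k] <- max(min(-co[1], 5), -5)
      } else {
        pk <- mean(vk[obs])
        thresholds[k] <- -qnorm(min(max(pk, 0.01), 0.99))
      }
    }
  }
  beta <- rep(0, P); tau <- 0; g1 <- 0; g2 <- 0
  if (any(prep$y >= 0)) {
    obs <- prep$y >= 0
    df <- if (P > 0) as.data.frame(prep$X[obs, , drop = FALSE]) else
      data.frame(row.names = seq_len(sum(obs)))
    names(df) <- if (P > 0) paste0("x", seq_len(P)) else character(0)
    df$.y <- prep$y[obs]
    if (!is.null(proxy) && latent_effect != "none") {
      df$.pz <- proxy[obs]
      if (latent_effect == "quadratic") df$.pz2 <- proxy[obs]^2
    }
    form <- if (ncol(df) > 1) ".y ~ ." else ".y ~ 1"
    co <- try(suppressWarnings(
      coef(glm(stats::as.formula(form), data = df,
               family = binomial("probit"), weights = wtn[obs]))),
      silent = TRUE)
    if (!inherits(co, "try-error") && all(is.finite(co))) {
      tau <- -co[["(Intercept)"]]
      if (P > 0) beta <- unname(co[paste0("x", seq_len(P))])
      if (".pz" %in% names(co)) g1 <- co[[".pz"]]
      if (".pz2" %in% names(co)) g2 <- co[[".pz2"]]
    }
  }
  hlc_params(loadings = loadings, thresholds = thresholds,
             item_names = prep$item_names,
             slopes = rep(0, L), concomitant_names = prep$w_names,
             beta = beta, beta_names = prep$x_names,
             gamma_linear = if (latent_effect == "none") 0 else g1,
             gamma_quadratic = if (latent_effect == "quadratic") g2 else 0,
             tau = tau,
             sigma_u2 = if (sigma_fixed) 0 else sigma_u2_start)
}

pinv_sym <- function(A, tol = 1e-10) {
  s <- svd((A + t(A)) / 2)
  pos <- s$d > tol * max(s$d, 0)
  if (!all(pos)) warn("information matrix is singular; using a pseudo-inverse.")
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit the multilevel probit model with a latent covariate
#'
#' Single-step survey-weighted marginal maximum (pseudo-)likelihood
#' estimation of the joint model: normal-ogive measurement of the latent
#' living-conditions score from binary items, concomitant regression of its
#' mean, and a probit outcome model with linear + quadratic latent effects
#' and cluster random intercepts. Integration uses nested Gauss-Hermite
#' quadrature standardized to the latent priors; optimization is
#' quasi-Newton with analytic gradients on an unconstrained scale (the
#' random-intercept SD enters as its logarithm). Standard errors are
#' cluster-robust (sandwich, with the B matrix built from PSU-level weighted
#' scores) alongside naive inverse-information SEs.
#'
#' The latent sign is identified by requiring the first item's loading to be
#' positive; if the optimizer lands on the mirrored solution, all loadings,
#' concomitant slopes and the linear latent effect are flipped jointly (the
#' likelihood is invariant).
#'
#' @param data Person-level data frame.
#' @param outcome Name of the binary outcome column (`NA` allowed; persons
#'   with missing outcome contribute measurement information only).
#' @param items Character vector of binary item columns (`NA` allowed,
#'   treated as missing at random given the latent score).
#' @param fixed_effects Character vector of fixed-effect covariate columns.
#' @param concomitants Character vector of concomitant covariate columns
#'   (shift the latent mean).
#' @param cluster Name of the cluster (PSU) id column.
#' @param weights Optional name of the sampling-weight column (positive).
#' @param latent_effect `"quadratic"` (linear + quadratic latent effect,
#'   default), `"linear"`, or `"none"` (latent effect excluded from the
#'   outcome model).
#' @param quadratic_terms Fixed-effect columns whose effect is quadratic;
#'   each is centered and its square added to the design inside the model.
#' @param item_link Item link function, `"probit"` (default) or `"logit"`.
#' @param quad A [quad_spec()].
#' @param start Optional `hlc_params` starting values.
#' @param control An [hlc_control()] list.
#' @return An object of class `hlc_fit`; see [tidy.hlc_fit()],
#'   [glance.hlc_fit()], [eb_scores()], [cluster_effects()],
#'   [lr_test_latent()].
#' @export
fit_hlc_probit <- function(data, outcome, items = character(0),
                           fixed_effects = character(0),
                           concomitants = character(0), cluster,
                           weights = NULL,
                           latent_effect = c("quadratic", "linear", "none"),
                           quadratic_terms = character(0),
                           item_link = c("probit", "logit"),
                           quad = quad_spec(), start = NULL,
                           control = hlc_control()) {
  latent_effect <- match.arg(latent_effect)
  item_link <- match.arg(item_link)
  if (length(items) == 0 && latent_effect != "none") {
    abort("with no items the latent effect is not identified; use latent_effect = \"none\".")
  }
  prep <- prepare_choice_data(data, outcome = outcome, items = items,
                              fixed_effects = fixed_effects,
                              concomitants = concomitants, cluster = cluster,
                              weights = weights,
                              quadratic_terms = quadratic_terms,
                              centering = control$centering)

  # degenerate items: all observed responses identical
  if (ncol(prep$V) > 0) {
    degen <- vapply(seq_len(ncol(prep$V)), function(k) {
      vk <- prep$V[, k][prep$V[, k] >= 0]
      length(vk) == 0 || all(vk == vk[1])
    }, logical(1))
    if (any(degen)) {
      bad <- prep$item_names[degen]
      if (control$degenerate_items == "error") {
        abort(paste0("degenerate item(s) (all 0 or all 1): ",
                     paste(bad, collapse = ", ")))
      }
      warn(paste0("dropping degenerate item(s) (all 0 or all 1): ",
                  paste(bad, collapse = ", ")))
      prep$V <- prep$V[, !degen, drop = FALSE]
      prep$item_names <- prep$item_names[!degen]
      items <- prep$item_names
      if (ncol(prep$V) == 0 && latent_effect != "none") {
        abort("all items were degenerate; cannot identify the latent effect.")
      }
    }
  }

  wtn <- if (control$normalize_weights) normalize_weights(prep$wt) else prep$wt
  sigma_fixed <- !is.null(control$sigma_u2)

  if (is.null(start)) {
    start <- make_start(prep, wtn, latent_effect, control$sigma_u2_start,
                        sigma_fixed && control$sigma_u2 == 0)
  }
  if (sigma_fixed) start$sigma_u2 <- control$sigma_u2
  if (latent_effect == "none") start$gamma_linear <- 0
  if (latent_effect != "quadratic") start$gamma_quadratic <- 0

  K <- ncol(prep$V); L <- ncol(prep$W); P <- ncol(prep$X)
  npar <- 2 * K + L + P + 4
  i_g1 <- 2 * K + L + P + 1
  i_g2 <- i_g1 + 1
  i_tau <- i_g1 + 2
  i_sig <- i_g1 + 3
  free <- rep(TRUE, npar)
  free[i_g1] <- latent_effect != "none"
  free[i_g2] <- latent_effect == "quadratic"
  free[i_sig] <- !sigma_fixed
  free_idx <- which(free)
  sig_free_pos <- match(i_sig, free_idx)

  nat0 <- pack_params(start)

  to_nat <- function(par_opt) {
    nat <- nat0
    nat[free_idx] <- par_opt
    if (!is.na(sig_free_pos)) nat[i_sig] <- exp(par_opt[sig_free_pos])
    nat
  }
  from_nat <- function(nat) {
    p <- nat[free_idx]
    if (!is.na(sig_free_pos)) p[sig_free_pos] <- log(max(nat[i_sig], 1e-8))
    p
  }
  eval_kernel <- function(par_opt, want_grad = FALSE, want_scores = FALSE) {
    pars <- unpack_params(to_nat(par_opt), start)
    call_kernel(prep, pars, quad, item_link, wt = wtn,
                want_grad = want_grad, want_scores = want_scores)
  }
  fn <- function(par_opt) -eval_kernel(par_opt)$loglik
  grad_opt <- function(par_opt) {
    res <- eval_kernel(par_opt, want_grad = TRUE)
    g <- res$gradient[free_idx]
    if (!is.na(sig_free_pos)) {
      g[sig_free_pos] <- g[sig_free_pos] * exp(par_opt[sig_free_pos])
    }
    g
  }
  gr <- function(par_opt) -grad_opt(par_opt)

  par0 <- from_nat(nat0)
  lower <- rep(-Inf, length(par0))
  upper <- rep(Inf, length(par0))
  if (!is.na(sig_free_pos)) {
    lower[sig_free_pos] <- log(1e-4)
    upper[sig_free_pos] <- log(50)
  }

  if (control$max_iter <= 0) {
    opt <- list(par = par0, objective = fn(par0), convergence = 1L,
                iterations = 0L, message = "max_iter = 0: not optimized")
  } else {
    # L-BFGS-B covers the distance cheaply; nlminb polishes the gradient
    o1 <- tryCatch(
      stats::optim(par0, fn, gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = control$max_iter, factr = 1e7)),
      error = function(e) list(par = par0, value = fn(par0),
                               counts = c(0L, 0L))
    )
    if (isTRUE(control$polish)) {
      opt <- nlminb(o1$par, fn, gr, lower = lower, upper = upper,
                    control = list(iter.max = control$max_iter,
                                   eval.max = 4 * control$max_iter,
                                   rel.tol = 1e-10))
      if (!is.finite(opt$objective) || opt$objective > o1$value) {
        opt$par <- o1$par
        opt$objective <- o1$value
      }
    } else {
      opt <- list(par = o1$par, objective = o1$value,
                  convergence = if (o1$convergence %||% 0L) 1L else 0L,
                  iterations = 0L)
    }
    opt$iterations <- (opt$iterations %||% 0L) + unname(o1$counts[1])
  }

  par_hat <- opt$par
  ll <- -opt$objective
  g_hat <- grad_opt(par_hat)
  gnorm <- max(abs(g_hat)) / max(1, abs(ll))
  converged <- control$max_iter > 0 && is.finite(ll) && gnorm < control$gtol
  params <- unpack_params(to_nat(par_hat), start)

  # sign identification: first loading positive
  if (K > 0 && params$loadings[1] < 0) {
    params$loadings <- -params$loadings
    params$slopes <- -params$slopes
    params$gamma_linear <- -params$gamma_linear
    nat0 <- pack_params(params)
    par_hat <- from_nat(nat0)
  }

  labels_nat <- par_labels(params)
  labels_free <- labels_nat[free_idx]
  labels_free[labels_free == "sigma_u"] <- "sigma_u2"

  vcov_rob <- vcov_naive <- NULL
  if (control$se == "robust" && control$max_iter > 0) {
    res <- eval_kernel(par_hat, want_grad = TRUE, want_scores = TRUE)
    S <- res$scores[, free_idx, drop = FALSE]
    if (!is.na(sig_free_pos)) {
      S[, sig_free_pos] <- S[, sig_free_pos] * exp(par_hat[sig_free_pos])
    }
    B <- crossprod(S)
    h <- control$hessian_step * (1 + abs(par_hat))
    q <- length(par_hat)
    A <- matrix(0, q, q)
    for (i in seq_len(q)) {
      e <- rep(0, q); e[i] <- h[i]
      A[, i] <- (grad_opt(par_hat + e) - grad_opt(par_hat - e)) / (2 * h[i])
    }
    A <- -(A + t(A)) / 2 # observed information of the weighted loglik
    Ainv <- tryCatch(solve(A), error = function(e) pinv_sym(A))
    vcov_rob <- Ainv %*% B %*% Ainv
    vcov_naive <- Ainv
    # delta method from optimizer scale (log sigma_u) to sigma_u2
    if (!is.na(sig_free_pos)) {
      J <- rep(1, q)
      J[sig_free_pos] <- 2 * params$sigma_u2 # d sigma_u2 / d log sigma_u
      vcov_rob <- vcov_rob * tcrossprod(J)
      vcov_naive <- vcov_naive * tcrossprod(J)
    }
    dimnames(vcov_rob) <- dimnames(vcov_naive) <- list(labels_free, labels_free)
  }

  structure(
    list(params = params, loglik = ll, icc = icc(params$sigma_u2),
         converged = converged, n_iter = opt$iterations %||% NA_integer_,
         gradient_norm = gnorm,
         vcov_robust = vcov_rob, vcov_naive = vcov_naive,
         free_labels = labels_free, free_idx = free_idx,
         latent_effect = latent_effect, item_link = item_link,
         quad = quad, control = control, prep = prep, wtn = wtn,
         n = prep$n, n_clusters = prep$n_clusters,
         columns = list(outcome = outcome, items = items,
                        fixed_effects = fixed_effects,
                        concomitants = concomitants, cluster = cluster,
                        weights = weights,
                        quadratic_terms = quadratic_terms),
         optim_message = opt$message %||% ""),
    class = "hlc_fit"
  )
}

#' @export
print.hlc_fit <- function(x, ...) {
  cat("<hlc_fit> multilevel probit with latent living-conditions covariate\n")
  cat(sprintf("  n = %d persons in %d clusters; log-(pseudo)likelihood = %.3f\n",
              x$n, x$n_clusters, x$loglik))
  cat(sprintf("  sigma_u2 = %.4f (ICC = %.4f); converged: %s (grad norm %.2e)\n",
              x$params$sigma_u2, x$icc, x$converged, x$gradient_norm))
  cat(sprintf("  latent effect: %s (gamma_linear = %.4f, gamma_quadratic = %.4f)\n",
              x$latent_effect, x$params$gamma_linear, x$params$gamma_quadratic))
  invisible(x)
}

#' @export
logLik.hlc_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$free_idx), class = "logLik")
}

#' @rdname fit_hlc_probit
#' @param object An `hlc_fit` object.
#' @param type `"robust"` (sandwich) or `"naive"` (inverse information).
#' @param ... Unused.
#' @export
vcov.hlc_fit <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  v <- if (type == "robust") object$vcov_robust else object$vcov_naive
  if (is.null(v)) abort("standard errors were not computed for this fit.")
  v
}

#' Likelihood-ratio test of the joint latent effect
#'
#' Tests `H0: gamma_linear = gamma_quadratic = 0` — i.e. that the latent
#' living-conditions score has no effect on the outcome — by refitting the
#' model with the latent effect excluded (the measurement and concomitant
#' blocks are re-estimated under the null) and comparing twice the
#' log-likelihood difference to a chi-square distribution. Under weighted
#' pseudo-likelihood the statistic is reported unadjusted; with informative
#' weights it is approximate.
#'
#' @param fit A converged `hlc_fit` with `latent_effect` `"quadratic"` or
#'   `"linear"`.
#' @return A one-row tibble: `statistic`, `df`, `p.value`,
#'   `loglik_full`, `loglik_restricted`.
#' @export
lr_test_latent <- function(fit) {
  stopifnot(inherits(fit, "hlc_fit"))
  if (fit$latent_effect == "none") {
    abort("`fit` already excludes the latent effect; fit the full model first.")
  }
  df <- if (fit$latent_effect == "quadratic") 2L else 1L
  start0 <- fit$params
  start0$gamma_linear <- 0
  start0$gamma_quadratic <- 0
  ctl <- fit$control
  ctl$se <- "none"
  refit <- function(le, start, quiet_degen = TRUE) {
    fit_hlc_probit(fit$prep$data, outcome = fit$columns$outcome,
                   items = fit$columns$items,
                   fixed_effects = fit$columns$fixed_effects,
                   concomitants = fit$columns$concomitants,
                   cluster = fit$columns$cluster,
                   weights = fit$columns$weights,
                   latent_effect = le,
                   quadratic_terms = fit$columns$quadratic_terms,
                   item_link = fit$item_link, quad = fit$quad,
                   start = start, control = ctl)
  }
  restricted <- refit("none", start0)
  stat <- 2 * (fit$loglik - restricted$loglik)
  tol <- 1e-6 * max(1, abs(fit$loglik))
  loglik_full <- fit$loglik
  if (stat < -tol) {
    # restricted beat the full model: polish the full fit from there
    start_full <- restricted$params
    full2 <- refit(fit$latent_effect, start_full)
    loglik_full <- max(loglik_full, full2$loglik)
    stat <- 2 * (loglik_full - restricted$loglik)
    if (stat < -tol) {
      abort("negative LR statistic persists after refitting; check convergence.")
    }
  }
  stat <- max(stat, 0)
  tibble::tibble(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 loglik_full = loglik_full,
                 loglik_restricted = restricted$loglik)
}
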