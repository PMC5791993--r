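#' Empirical-Bayes living-conditions scores
#'
#' Posterior mean and SD of the latent living-conditions score for each
#' person, given their observed items and concomitant covariates, computed
#' by Gauss-Hermite quadrature against the `N(theta'w, 1)` prior. By default
#' the outcome is excluded from the conditioning set, so the scores form a
#' standalone wealth index with no feedback from the dependent variable;
#' `include_outcome = TRUE` additionally conditions on the person's own
#' outcome, integrating the cluster intercept over its `N(0, sigma_u2)`
#' prior.
#'
#' With no items observed (and the outcome excluded) the prior is returned:
#' posterior mean `theta'w`, posterior SD 1.
#'
#' @param x An `hlc_fit` object, or a data frame (in which case `params` and
#'   the column mappings must be supplied).
#' @param newdata Optional data frame to score instead of the training data
#'   (for `hlc_fit` input).
#' @param include_outcome Condition on the outcome as well (default `FALSE`).
#' @param n_nodes Quadrature nodes for the posterior integrals.
#' @param ... Passed to methods.
#' @return A tibble in the input row order: `post_mean`, `post_sd`, plus the
#'   cluster id column when available.
#' @export
eb_scores <- function(x, ...) UseMethod("eb_scores")

#' @rdname eb_scores
#' @param params An `hlc_params` object (data-frame method).
#' @param items,concomitants,outcome,fixed_effects,cluster Column names
#'   (data-frame method); `cluster` is only required when no other grouping
#'   is available and may be omitted by passing a constant column.
#' @param item_link Item link function.
#' @export
eb_scores.data.frame <- function(x, params, items = character(0),
                                 concomitants = character(0),
                                 outcome = NULL, fixed_effects = character(0),
                                 cluster = NULL, include_outcome = FALSE,
                                 n_nodes = 41, item_link = "probit", ...) {
  stopifnot(inherits(params, "hlc_params"))
  df <- as.data.frame(x)
  n <- nrow(df)
  if (is.null(cluster)) {
    df$.cl <- seq_len(n)
    cluster <- ".cl"
  }
  prep <- prepare_choice_data(df, outcome = if (include_outcome) outcome else NULL,
                              items = items, fixed_effects = fixed_effects,
                              concomitants = concomitants, cluster = cluster)
  post <- posterior_z_moments(prep, params, include_outcome = include_outcome,
                              n_nodes = n_nodes, item_link = item_link)
  out <- tibble::tibble(post_mean = post$mean, post_sd = post$sd)
  out[[cluster]] <- prep$cluster
  # back to input row order
  out[order(prep$order), , drop = FALSE]
}

#' @rdname eb_scores
#' @export
eb_scores.hlc_fit <- function(x, newdata = NULL, include_outcome = FALSE,
                              n_nodes = 41, ...) {
  df <- if (is.null(newdata)) x$prep$data else newdata
  eb_scores.data.frame(df, params = x$params, items = x$columns$items,
                       concomitants = x$columns$concomitants,
                       outcome = x$columns$outcome,
                       fixed_effects = x$columns$fixed_effects,
                       cluster = x$columns$cluster,
                       include_outcome = include_outcome,
                       n_nodes = n_nodes, item_link = x$item_link)
}

# posterior moments of z per person by prior-standardized GH quadrature;
# optionally conditions on the person's own outcome, integrating u over its
# prior with a second GH rule
posterior_z_moments <- function(prep, params, include_outcome = FALSE,
                                n_nodes = 41, item_link = "probit") {
  n <- prep$n
  K <- length(params$loadings)
  gh <- pracma::gaussHermite(n_nodes)
  mu <- if (ncol(prep$W) > 0) drop(prep$W %*% params$slopes) else rep(0, n)
  zmat <- outer(mu, sqrt(2) * gh$x, "+") # n x T
  la <- log(gh$w) - 0.5 * log(pi)
  logm <- matrix(0, n, n_nodes)
  for (k in seq_len(K)) {
    vk <- prep$V[, k]
    obs <- vk >= 0
    if (!any(obs)) next
    alpha <- params$loadings[k] * zmat[obs, , drop = FALSE] - params$thresholds[k]
    lp1 <- if (item_link == "probit") pnorm(alpha, log.p = TRUE) else
      -log1p(exp(-alpha))
    lp0 <- if (item_link == "probit") pnorm(-alpha, log.p = TRUE) else
      -log1p(exp(alpha))
    logm[obs, ] <- logm[obs, ] + ifelse(vk[obs] == 1, 1, 0) * lp1 +
      ifelse(vk[obs] == 0, 1, 0) * lp0
  }
  logpost <- sweep(logm, 2, la, "+")
  if (include_outcome && any(prep$y >= 0)) {
    sigu <- sqrt(params$sigma_u2)
    S <- if (sigu > 0) n_nodes else 1L
    uu <- if (sigu > 0) sqrt(2) * sigu * gh$x else 0
    lb <- if (sigu > 0) log(gh$w) - 0.5 * log(pi) else 0
    base <- (if (ncol(prep$X) > 0) drop(prep$X %*% params$beta) else rep(0, n)) -
      params$tau
    qz <- params$gamma_linear * zmat + params$gamma_quadratic * zmat^2
    obs <- prep$y >= 0
    # log integral over u of outcome prob, per (person, z-node)
    acc <- matrix(-Inf, sum(obs), n_nodes)
    eta_base <- base[obs] + qz[obs, , drop = FALSE]
    sgn <- ifelse(prep$y[obs] == 1, 1, -1)
    for (s in seq_len(S)) {
      lp <- pnorm(sgn * (eta_base + uu[s]), log.p = TRUE) + lb[min(s, length(lb))]
      acc <- pmax(acc, lp) + log1p(exp(pmin(acc, lp) - pmax(acc, lp)))
    }
    logpost[obs, ] <- logpost[obs, ] + acc
  }
  m <- apply(logpost, 1, max)
  wgt <- exp(logpost - m)
  norm <- rowSums(wgt)
  pm <- rowSums(wgt * zmat) / norm
  pv <- rowSums(wgt * zmat^2) / norm - pm^2
  list(mean = pm, sd = sqrt(pmax(pv, 0)))
}

#' Posterior cluster random effects
#'
#' Shrinkage (posterior-mean) estimates of the cluster random intercepts
#' given each cluster's full data, computed inside the same nested
#' quadrature as the likelihood. Exactly zero when `sigma_u2 = 0`.
#'
#' @param x An `hlc_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per cluster: cluster id, `post_mean`,
#'   `post_sd`.
#' @export
cluster_effects <- function(x, ...) {
  stopifnot(inherits(x, "hlc_fit"))
  res <- call_kernel(x$prep, x$params, x$quad, x$item_link, wt = x$wtn,
                     want_post = TRUE)
  tibble::tibble(cluster = x$prep$cluster_ids,
                 post_mean = res$post_u_mean,
                 post_sd = res$post_u_sd)
}

#' Weighted aggregation of scores by group
#'
#' Aggregates person-level scores into a group table (e.g. households into
#' states): weighted mean, weighted SD and a dense ranking by mean, rank 1
#' being the highest mean. Empty groups are dropped with a warning.
#'
#' @param data A data frame of person-level records.
#' @param score Column with the score to aggregate (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @param weights Optional weight column (tidy-eval); equal weights when
#'   omitted.
#' @return A tibble: `group`, `n`, `mean_score`, `sd_score`, `rank`.
#' @export
aggregate_scores <- function(data, score, group, weights = NULL) {
  score <- rlang::enquo(score)
  group <- rlang::enquo(group)
  weights <- rlang::enquo(weights)
  df <- tibble::as_tibble(data)
  df <- dplyr::mutate(
    df,
    .s = !!score,
    .w = if (rlang::quo_is_null(weights)) 1 else !!weights,
    .g = !!group
  )
  if (any(!is.finite(df$.w)) || any(df$.w <= 0)) {
    abort("weights must be strictly positive.")
  }
  drop_na <- is.na(df$.s) | is.na(df$.g)
  if (any(drop_na)) {
    warn(sprintf("dropping %d row(s) with missing score or group.", sum(drop_na)))
    df <- df[!drop_na, , drop = FALSE]
  }
  if (nrow(df) == 0) abort("no rows left to aggregate.")
  out <- df |>
    dplyr::group_by(.data$.g) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_score = sum(.data$.w * .data$.s) / sum(.data$.w),
      sd_score = sqrt(sum(.data$.w * (.data$.s - mean_score)^2) / sum(.data$.w)),
      .groups = "drop"
    ) |>
    dplyr::rename(group = ".g") |>
    dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(.data$mean_score))) |>
    dplyr::arrange(.data$rank)
  out
}

#' External validation of aggregated scores
#'
#' Compares group-level mean scores with an external aggregate indicator
#' (e.g. state-level net domestic product per capita): Pearson correlation
#' on the paired values and Spearman rank correlation on their orderings
#' (average ranks for ties). Groups present in only one of the two tables
#' are listed and excluded with a warning.
#'
#' @param group_table A data frame with one row per group (e.g. from
#'   [aggregate_scores()]).
#' @param indicator_table A data frame with one row per group holding the
#'   external indicator.
#' @param by Name of the group label column, present in both tables.
#' @param score Name of the score column in `group_table`.
#' @param indicator Name of the indicator column in `indicator_table`.
#' @return An object of class `hlc_validation`: a list with `pearson`,
#'   `spearman`, the paired `table`, and any `excluded` labels.
#' @examples
#' tab <- state_validation_table()
#' external_validation(tab, tab, by = "state",
#'                     score = "hlc_mean", indicator = "nsdp_pc")
#' @export
external_validation <- function(group_table, indicator_table, by = "group",
                                score = "mean_score", indicator = "indicator") {
  gt <- tibble::as_tibble(group_table)
  it <- tibble::as_tibble(indicator_table)
  for (nm in c(by, score)) if (!nm %in% names(gt)) {
    abort(sprintf("column `%s` not found in `group_table`.", nm))
  }
  for (nm in c(by, indicator)) if (!nm %in% names(it)) {
    abort(sprintf("column `%s` not found in `indicator_table`.", nm))
  }
  excluded <- c(setdiff(gt[[by]], it[[by]]), setdiff(it[[by]], gt[[by]]))
  if (length(excluded) > 0) {
    warn(paste0("unmatched group label(s) excluded: ",
                paste(excluded, collapse = ", ")))
  }
  merged <- dplyr::inner_join(
    tibble::tibble(label = gt[[by]], score = gt[[score]]),
    tibble::tibble(label = it[[by]], indicator = it[[indicator]]),
    by = "label"
  )
  if (nrow(merged) < 3) abort("need at least 3 matched groups for validation.")
  structure(
    list(pearson = cor(merged$score, merged$indicator),
         spearman = cor(merged$score, merged$indicator, method = "spearman"),
         n_groups = nrow(merged), table = merged, excluded = excluded,
         score = score, indicator = indicator, by = by),
    class = "hlc_validation"
  )
}

#' @export
print.hlc_validation <- function(x, ...) {
  cat("<hlc_validation>", x$n_groups, "matched groups\n")
  cat(sprintf("  Pearson r     = %.3f\n", x$pearson))
  cat(sprintf("  Spearman rho  = %.3f\n", x$spearman))
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Packaged state-level validation fixture
#'
#' State-level table for the external-validation workflow: net state
#' domestic product per capita (thousand Indian rupees, 2005/06 constant
#' prices) alongside the weighted mean living-conditions score, both with
#' their rankings, for 29 Indian states. Shipped with the package so the
#' validation math is runnable without any data download.
#'
#' @return A tibble with columns `state`, `abbrev`, `nsdp_pc`, `nsdp_rank`,
#'   `hlc_mean`, `hlc_rank`, `hlc_sd`.
#' @export
state_validation_table <- function() {
  path <- system.file("extdata", "state_validation.csv", package = "hlcprobit")
  # na = "" : the abbreviation of Nagaland is the literal string "NA"
  readr::read_csv(path, show_col_types = FALSE, na = "")
}
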