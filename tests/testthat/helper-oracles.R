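# Independent oracles built from first principles (base R only), used to
# check the quadrature kernel. They share no code with the package's
# integration path.

# density of one person's data at fixed (z, u), from scratch
oracle_person_density <- function(z, u, y, x, items, params) {
  d <- 1
  for (k in seq_along(params$loadings)) {
    if (is.na(items[k])) next
    pk <- pnorm(params$loadings[k] * z - params$thresholds[k])
    d <- d * if (items[k] == 1) pk else 1 - pk
  }
  if (!is.na(y)) {
    eta <- sum(x * params$beta) + params$gamma_linear * z +
      params$gamma_quadratic * z^2 + u - params$tau
    py <- pnorm(eta)
    d <- d * if (y == 1) py else 1 - py
  }
  d
}

# cluster marginal log-likelihood by dense 2-D trapezoid integration on a
# [-lim, lim] grid for u and per-person z grids around the latent mean
oracle_cluster_loglik <- function(cluster_df, params, weights = NULL,
                                  lim = 8, n_grid = 1601) {
  n <- nrow(cluster_df)
  if (is.null(weights)) weights <- rep(1, n)
  ug <- seq(-lim, lim, length.out = n_grid)
  du <- ug[2] - ug[1]
  sigu <- sqrt(params$sigma_u2)
  zg <- seq(-lim, lim, length.out = n_grid)
  dz <- zg[2] - zg[1]
  item_cols <- grep("^item_", names(cluster_df), value = TRUE)
  # per person: f_i(u) = int phi(z; mu_i, 1) * density(z, u) dz on the grid
  log_fi_of_u <- matrix(NA_real_, n, n_grid)
  for (i in seq_len(n)) {
    row <- cluster_df[i, ]
    mu_i <- sum(as.numeric(row[["urban"]]) * params$slopes)
    zs <- mu_i + zg
    mz <- dnorm(zs, mu_i, 1) # prior times measurement product, over z
    items <- as.integer(row[item_cols])
    for (k in seq_along(params$loadings)) {
      if (is.na(items[k])) next
      pk <- pnorm(params$loadings[k] * zs - params$thresholds[k])
      mz <- mz * if (items[k] == 1) pk else 1 - pk
    }
    x <- c(row[["x_bin"]], row[["x_cont"]])
    y <- row[["y"]]
    if (is.na(y)) {
      P <- matrix(1, n_grid, n_grid)
    } else {
      eta0 <- sum(x * params$beta) + params$gamma_linear * zs +
        params$gamma_quadratic * zs^2 - params$tau
      P <- pnorm(outer(eta0, ug, "+")) # z in rows, u in columns
      if (y == 0) P <- 1 - P
    }
    integrand <- mz * P
    log_fi_of_u[i, ] <- log(
      dz * (colSums(integrand) - 0.5 * (integrand[1, ] + integrand[n_grid, ]))
    )
  }
  if (sigu == 0) {
    # u degenerate at 0: pick the grid point at u = 0 (grid is symmetric)
    s0 <- which.min(abs(ug))
    return(sum(weights * log_fi_of_u[, s0]))
  }
  log_prior_u <- dnorm(ug, 0, sigu, log = TRUE)
  log_integrand <- log_prior_u + colSums(weights * log_fi_of_u)
  m <- max(log_integrand)
  vals <- exp(log_integrand - m)
  m + log(du * (sum(vals) - 0.5 * (vals[1] + vals[n_grid])))
}

# marginal P(y = 1 | x) by dense nested integration over z and u
oracle_marginal_choice_prob <- function(x, params, latent_mean, sigma_u2,
                                        lim = 8, n_grid = 2001) {
  zg <- seq(latent_mean - lim, latent_mean + lim, length.out = n_grid)
  dzv <- zg[2] - zg[1]
  inner <- function(u) {
    eta <- sum(x * params$beta) + params$gamma_linear * zg +
      params$gamma_quadratic * zg^2 + u - params$tau
    f <- dnorm(zg, latent_mean, 1) * pnorm(eta)
    dzv * (sum(f) - 0.5 * (f[1] + f[n_grid]))
  }
  if (sigma_u2 == 0) return(inner(0))
  sigu <- sqrt(sigma_u2)
  ug <- seq(-lim * sigu, lim * sigu, length.out = n_grid)
  duv <- ug[2] - ug[1]
  g <- vapply(ug, function(u) dnorm(u, 0, sigu) * inner(u), numeric(1))
  duv * (sum(g) - 0.5 * (g[1] + g[n_grid]))
}

# posterior mean/sd of z given items only, by dense grid
oracle_posterior_z <- function(items, mu, params, lim = 10, n_grid = 4001) {
  zg <- seq(mu - lim, mu + lim, length.out = n_grid)
  dens <- dnorm(zg, mu, 1)
  for (k in seq_along(params$loadings)) {
    if (is.na(items[k])) next
    pk <- pnorm(params$loadings[k] * zg - params$thresholds[k])
    dens <- dens * if (items[k] == 1) pk else 1 - pk
  }
  w <- dens / sum(dens)
  m <- sum(w * zg)
  list(mean = m, sd = sqrt(sum(w * (zg - m)^2)))
}

# small deterministic toy dataset builder (two clusters)
toy_two_clusters <- function(params, seed = 42) {
  set.seed(seed)
  K <- length(params$loadings)
  df <- tibble::tibble(
    cluster = c(1, 1, 2, 2),
    urban = c(0, 1, 1, 0),
    x_bin = c(0, 1, 1, 0),
    x_cont = c(-0.5, 0.3, 1.1, -1.2),
    y = c(0L, 1L, 1L, 0L),
    weight = c(0.8, 1.2, 1.1, 0.9)
  )
  V <- matrix(rbinom(4 * K, 1, 0.5), 4, K)
  colnames(V) <- paste0("item_", seq_len(K))
  dplyr::bind_cols(df, tibble::as_tibble(V))
}
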