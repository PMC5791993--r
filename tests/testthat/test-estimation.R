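toy_params <- hlc_params(
  loadings = c(1.3, 0.9, 1.6, 1.1), thresholds = c(-0.4, 0.8, 1.9, 0.2),
  slopes = 1.2, beta = c(0.4, 0.2), gamma_linear = 0.3,
  gamma_quadratic = -0.05, tau = 0.3, sigma_u2 = 0.4
)

loglik_toy <- function(df, params, quad, weights = "weight") {
  hlc_loglik(df, params, outcome = "y", items = grep("^item_", names(df), value = TRUE),
             fixed_effects = c("x_bin", "x_cont"), concomitants = "urban",
             cluster = "cluster", weights = weights, quad = quad,
             by_cluster = TRUE)
}

test_that("quadrature cluster log-likelihood matches the dense-grid oracle", {
  df <- toy_two_clusters(toy_params, seed = 5)
  q <- quad_spec(61, 61)
  ll <- loglik_toy(df, toy_params, q)
  for (j in 1:2) {
    cl <- df[df$cluster == j, ]
    oracle <- oracle_cluster_loglik(cl, toy_params, weights = cl$weight)
    expect_equal(ll[[j]], oracle, tolerance = 1e-6)
  }
  # missing outcome and missing items are handled as absent factors
  df2 <- df
  df2$y[2] <- NA
  df2$item_2[3] <- NA
  ll2 <- loglik_toy(df2, toy_params, q)
  for (j in 1:2) {
    cl <- df2[df2$cluster == j, ]
    oracle <- oracle_cluster_loglik(cl, toy_params, weights = cl$weight)
    expect_equal(ll2[[j]], oracle, tolerance = 1e-6)
  }
})

test_that("total log-likelihood sums clusters and is order invariant", {
  sim <- simulate_hlc_data(sim_config(n_clusters = 12, cluster_size = 6),
                           seed = 31)
  q <- quad_spec(11, 7)
  args <- list(sim$data, sim$params, outcome = "y",
               items = sim$config$item_names,
               fixed_effects = c("x_bin", "x_cont"), concomitants = "urban",
               cluster = "cluster", weights = "weight", quad = q)
  total <- do.call(hlc_loglik, args)
  per_cl <- do.call(hlc_loglik, c(args, by_cluster = TRUE))
  expect_equal(total, sum(per_cl))
  # permuting rows (and hence cluster order) leaves the value unchanged
  set.seed(8)
  args_perm <- args
  args_perm[[1]] <- sim$data[sample(nrow(sim$data)), ]
  expect_equal(do.call(hlc_loglik, args_perm), total, tolerance = 1e-10)
  # single person, no items, beta = 0, tau = 0, sigma_u2 = 0 -> w * log(0.5)
  df1 <- tibble::tibble(cluster = 1, y = 1, w = 2.5)
  p0 <- hlc_params()
  expect_equal(
    hlc_loglik(df1, p0, outcome = "y", cluster = "cluster", weights = "w",
               quad = q),
    2.5 * log(0.5)
  )
  # empty data contributes nothing
  expect_equal(
    hlc_loglik(df1[0, ], p0, outcome = "y", cluster = "cluster", quad = q), 0
  )
})

test_that("analytic gradient matches central finite differences", {
  sim <- simulate_hlc_data(sim_config(n_clusters = 6, cluster_size = 5,
                                      missing_rate = 0.1), seed = 77)
  prep <- hlcprobit:::prepare_choice_data(
    sim$data, outcome = "y", items = sim$config$item_names,
    fixed_effects = c("x_bin", "x_cont"), concomitants = "urban",
    cluster = "cluster", weights = "weight"
  )
  q <- quad_spec(9, 7)
  nat <- hlcprobit:::pack_params(sim$params)
  f <- function(v) {
    hlcprobit:::call_kernel(prep, hlcprobit:::unpack_params(v, sim$params), q)$loglik
  }
  g_an <- hlcprobit:::call_kernel(prep, sim$params, q, want_grad = TRUE)$gradient
  h <- 1e-5
  g_num <- vapply(seq_along(nat), function(i) {
    e <- rep(0, length(nat)); e[i] <- h
    (f(nat + e) - f(nat - e)) / (2 * h)
  }, numeric(1))
  expect_equal(as.numeric(g_an), g_num, tolerance = 1e-5)
  # per-cluster scores sum to the total gradient
  sc <- hlcprobit:::call_kernel(prep, sim$params, q, want_scores = TRUE)$scores
  expect_equal(colSums(sc), as.numeric(g_an), tolerance = 1e-10)
})

test_that("quadrature is converged at the default node counts", {
  sim <- simulate_hlc_data(sim_config(n_clusters = 25, cluster_size = 8),
                           seed = 13)
  args <- list(sim$data, sim$params, outcome = "y",
               items = sim$config$item_names,
               fixed_effects = c("x_bin", "x_cont"), concomitants = "urban",
               cluster = "cluster", weights = "weight")
  ll21 <- do.call(hlc_loglik, c(args, list(quad = quad_spec(21, 21))))
  ll41 <- do.call(hlc_loglik, c(args, list(quad = quad_spec(41, 41))))
  expect_equal(ll21, ll41, tolerance = 1e-4)
})

test_that("refitting from the solution is a fixed point", {
  sim <- simulate_hlc_data(sim_config(n_clusters = 40, cluster_size = 6),
                           seed = 17)
  q <- quad_spec(9, 7)
  ctl <- hlc_control(se = "none")
  fit1 <- fit_sim(sim, quad = q, control = ctl)
  fit2 <- fit_sim(sim, quad = q, start = fit1$params, control = ctl)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-8)
})

test_that("unoptimized and degenerate-item paths behave as documented", {
  sim <- simulate_hlc_data(sim_config(n_clusters = 15, cluster_size = 5),
                           seed = 23)
  f0 <- fit_sim(sim, quad = quad_spec(7, 5),
                control = hlc_control(max_iter = 0, se = "none"))
  expect_false(f0$converged)
  # an all-ones item is dropped with a warning
  dat <- sim$data
  dat$item_1 <- 1L
  expect_warning(
    fd <- fit_hlc_probit(dat, outcome = "y",
                         items = paste0("item_", 1:4),
                         fixed_effects = c("x_bin", "x_cont"),
                         concomitants = "urban", cluster = "cluster",
                         quad = quad_spec(7, 5),
                         control = hlc_control(se = "none", max_iter = 50)),
    "degenerate"
  )
  expect_equal(length(fd$params$loadings), 3L)
  expect_error(
    suppressWarnings(fit_hlc_probit(dat, outcome = "y",
                   items = paste0("item_", 1:4),
                   fixed_effects = c("x_bin", "x_cont"),
                   concomitants = "urban", cluster = "cluster",
                   control = hlc_control(degenerate_items = "error"))),
    "degenerate"
  )
})

test_that("estimates are invariant to splitting clusters into half-weight copies", {
  sim <- simulate_hlc_data(
    sim_config(n_clusters = 40, cluster_size = 10,
               loadings = c(1.457, 0.995, 1.309, 1.125, 1.734, 1.476),
               thresholds = c(-0.658, 1.744, 0.747, 0.581, 2.042, 0.664)),
    seed = 41
  )
  q <- quad_spec(9, 5)
  ctl <- hlc_control(se = "none")
  fit1 <- fit_sim(sim, quad = q, control = ctl)
  dup2 <- sim$data
  dup2$cluster <- dup2$cluster + 1000
  both <- dplyr::bind_rows(sim$data, dup2)
  both$weight <- both$weight / 2
  fit2 <- fit_hlc_probit(both, outcome = "y", items = paste0("item_", 1:6),
                         fixed_effects = c("x_bin", "x_cont"),
                         concomitants = "urban", cluster = "cluster",
                         weights = "weight", quad = q, control = ctl)
  expect_equal(fit2$params$loadings, fit1$params$loadings, tolerance = 1e-3)
  expect_equal(fit2$params$gamma_linear, fit1$params$gamma_linear,
               tolerance = 1e-3)
  expect_equal(fit2$params$sigma_u2, fit1$params$sigma_u2, tolerance = 1e-3)
  # each cluster appears twice, so the pseudo-loglik doubles
  expect_equal(fit2$loglik, 2 * fit1$loglik, tolerance = 1e-6)
})

test_that("clustered sandwich matches a hand computation on a threshold-only probit", {
  set.seed(55)
  n_cl <- 60
  df <- tibble::tibble(
    cluster = rep(seq_len(n_cl), each = 4),
    u_cl = rep(rnorm(n_cl, 0, 0.5), each = 4)
  )
  df$y <- as.integer(rnorm(nrow(df)) + df$u_cl > 0.3)
  fit <- fit_hlc_probit(df, outcome = "y", cluster = "cluster",
                        latent_effect = "none",
                        control = hlc_control(sigma_u2 = 0),
                        quad = quad_spec(7, 5))
  tau_hat <- fit$params$tau
  # textbook clustered sandwich for the probit threshold model by hand
  eta <- -tau_hat
  p <- pnorm(eta)
  score_i <- ifelse(df$y == 1, -dnorm(eta) / p, dnorm(eta) / (1 - p))
  info_i <- dnorm(eta)^2 * (1 / p + 1 / (1 - p)) # same for every person
  A <- nrow(df) * info_i
  Sj <- tapply(score_i, df$cluster, sum)
  B <- sum(Sj^2)
  se_hand <- sqrt(B / A^2)
  se_pkg <- sqrt(diag(vcov(fit)))[["tau"]]
  expect_equal(se_pkg, se_hand, tolerance = 1e-3)
  # naive SE matches the unclustered information
  expect_equal(sqrt(diag(vcov(fit, type = "naive")))[["tau"]],
               sqrt(1 / A), tolerance = 1e-3)
})

test_that("robust and naive SEs agree under a correctly specified independent model", {
  set.seed(66)
  n <- 4000
  df <- tibble::tibble(cluster = seq_len(n), x = rnorm(n))
  df$y <- as.integer(0.5 * df$x - 0.2 + rnorm(n) > 0)
  fit <- fit_hlc_probit(df, outcome = "y", fixed_effects = "x",
                        cluster = "cluster", latent_effect = "none",
                        control = hlc_control(sigma_u2 = 0),
                        quad = quad_spec(5, 5))
  td <- tidy(fit)
  est <- td[td$term %in% c("x", "tau"), ]
  ratio <- est$std.error / est$std.error.naive
  expect_true(all(ratio > 0.8 & ratio < 1.2))
})

test_that("likelihood-ratio test behaves at its boundaries and detects strong effects", {
  sim <- simulate_hlc_data(
    sim_config(n_clusters = 60, cluster_size = 8, gamma_linear = 0.8,
               gamma_quadratic = 0, weight_scheme = "equal"),
    seed = 91
  )
  fit <- fit_sim(sim, quad = quad_spec(9, 5), control = hlc_control(se = "none"))
  lt <- lr_test_latent(fit)
  expect_equal(lt$df, 2L)
  expect_gte(lt$statistic, 0)
  expect_lt(lt$p.value, 1e-6)
  expect_error(lr_test_latent(
    fit_sim(sim, quad = quad_spec(7, 5), latent_effect = "none",
            control = hlc_control(se = "none"))
  ), "full model")
})

test_that("the logistic item link is available throughout and matches direct computation", {
  p <- hlc_params(loadings = c(1.2, 0.8), thresholds = c(0.4, -0.3))
  expect_equal(item_response_prob(0.5, 1.2, 0.4, link = "logit"),
               plogis(1.2 * 0.5 - 0.4))
  # single person, two items, no outcome: dense-grid integral under the
  # logistic item response function
  df <- tibble::tibble(cluster = 1, item_1 = 1L, item_2 = 0L)
  ll <- hlc_loglik(df, p, items = c("item_1", "item_2"), cluster = "cluster",
                   quad = quad_spec(41, 5), item_link = "logit")
  zg <- seq(-10, 10, by = 0.005)
  f <- dnorm(zg) * plogis(1.2 * zg - 0.4) * (1 - plogis(0.8 * zg + 0.3))
  oracle <- log((zg[2] - zg[1]) * (sum(f) - 0.5 * (f[1] + f[length(f)])))
  expect_equal(ll, oracle, tolerance = 1e-8)
  expect_equal(
    person_conditional_density(0.7, 0, p, items = c(1L, 0L),
                               item_link = "logit"),
    plogis(1.2 * 0.7 - 0.4) * (1 - plogis(0.8 * 0.7 + 0.3))
  )
})
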