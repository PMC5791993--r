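score_params <- hlc_params(
  loadings = c(1.4, 1.0, 1.8), thresholds = c(-0.3, 0.9, 2.1),
  slopes = 1.437, beta = c(0.3, 0.15), gamma_linear = 0.2,
  gamma_quadratic = -0.006, tau = 0, sigma_u2 = 0.23
)

test_that("empirical-Bayes scores reduce to the prior with no items", {
  df <- tibble::tibble(cluster = 1:2, urban = c(0, 1),
                       item_1 = NA, item_2 = NA, item_3 = NA)
  sc <- eb_scores(df, params = score_params, items = paste0("item_", 1:3),
                  concomitants = "urban", cluster = "cluster")
  expect_equal(sc$post_mean, c(0, 1.437), tolerance = 1e-8)
  expect_equal(sc$post_sd, c(1, 1), tolerance = 1e-8)
})

test_that("empirical-Bayes scores match the dense-grid posterior", {
  pat <- list(c(1L, NA, NA), c(1L, 1L, 1L), c(0L, 0L, 0L), c(1L, 0L, NA))
  df <- tibble::tibble(cluster = seq_along(pat),
                       urban = c(0, 1, 0, 1))
  for (k in 1:3) df[[paste0("item_", k)]] <- vapply(pat, `[`, integer(1), k)
  sc <- eb_scores(df, params = score_params, items = paste0("item_", 1:3),
                  concomitants = "urban", cluster = "cluster", n_nodes = 61)
  for (i in seq_along(pat)) {
    mu <- df$urban[i] * 1.437
    o <- oracle_posterior_z(pat[[i]], mu, score_params)
    expect_equal(sc$post_mean[i], o$mean, tolerance = 1e-6)
    expect_equal(sc$post_sd[i], o$sd, tolerance = 1e-6)
  }
  # information from any observed item shrinks the posterior below the prior
  expect_true(all(sc$post_sd < 1))
  # uniformly positive items push the mean above the concomitant prior mean
  expect_gt(sc$post_mean[2], 1.437)
  expect_lt(sc$post_mean[3], 0)
})

test_that("conditioning on the outcome moves scores in the outcome direction", {
  df <- tibble::tibble(cluster = 1:2, urban = 0, x_bin = 0, x_cont = 0,
                       y = c(1L, 0L), item_1 = 1L, item_2 = 0L, item_3 = NA)
  base <- eb_scores(df, params = score_params, items = paste0("item_", 1:3),
                    concomitants = "urban", cluster = "cluster")
  with_y <- eb_scores(df, params = score_params, items = paste0("item_", 1:3),
                      concomitants = "urban", outcome = "y",
                      fixed_effects = c("x_bin", "x_cont"),
                      cluster = "cluster", include_outcome = TRUE)
  # same items, positive gamma: y = 1 raises the score, y = 0 lowers it
  expect_gt(with_y$post_mean[1], base$post_mean[1])
  expect_lt(with_y$post_mean[2], base$post_mean[2])
})

test_that("cluster random-effect posteriors shrink and vanish with sigma_u2 = 0", {
  sim <- simulate_hlc_data(sim_config(n_clusters = 40, cluster_size = 8),
                           seed = 3)
  fit <- fit_sim(sim, quad = quad_spec(9, 7), control = hlc_control(se = "none"))
  ce <- cluster_effects(fit)
  expect_equal(nrow(ce), 40)
  expect_true(all(is.finite(ce$post_mean)))
  # posterior means center near zero across clusters
  expect_lt(abs(mean(ce$post_mean)), 0.15)
  # correlated with the generating random effects
  u_true <- sim$truth$u[!duplicated(sim$truth$cluster)]
  expect_gt(cor(ce$post_mean, u_true), 0.3)
  # degenerate variance: all posteriors are exactly zero
  fit0 <- fit_sim(sim, quad = quad_spec(9, 5),
                  control = hlc_control(sigma_u2 = 0, se = "none"))
  ce0 <- cluster_effects(fit0)
  expect_true(all(ce0$post_mean == 0))
  # monotonicity: an all-success cluster sits above an all-failure cluster
  df <- tibble::tibble(cluster = rep(1:2, each = 12),
                       y = rep(c(1L, 0L), each = 12))
  fitc <- fit_hlc_probit(df, outcome = "y", cluster = "cluster",
                         latent_effect = "none", quad = quad_spec(5, 21),
                         control = hlc_control(se = "none"))
  cec <- cluster_effects(fitc)
  expect_gt(cec$post_mean[1], 0)
  expect_lt(cec$post_mean[2], 0)
})

test_that("group aggregation reproduces hand-computed weighted summaries", {
  df <- tibble::tibble(
    g = c("a", "a", "a", "b", "b"),
    s = c(1, 2, 4, 0, 1),
    w = c(1, 2, 1, 3, 1)
  )
  tab <- aggregate_scores(df, s, g, weights = w)
  m_a <- (1 * 1 + 2 * 2 + 1 * 4) / 4
  m_b <- (3 * 0 + 1 * 1) / 4
  expect_equal(tab$mean_score[tab$group == "a"], m_a)
  expect_equal(tab$mean_score[tab$group == "b"], m_b)
  sd_a <- sqrt((1 * (1 - m_a)^2 + 2 * (2 - m_a)^2 + 1 * (4 - m_a)^2) / 4)
  expect_equal(tab$sd_score[tab$group == "a"], sd_a)
  expect_equal(tab$rank, c(1L, 2L)) # a has the higher mean
  # equal weights reduce to the plain mean, one group gets rank 1
  tab1 <- aggregate_scores(df[df$g == "a", ], s, g)
  expect_equal(tab1$mean_score, mean(c(1, 2, 4)))
  expect_equal(tab1$rank, 1L)
  # invariant to rescaling all weights
  df2 <- df; df2$w <- df2$w * 7.3
  expect_equal(aggregate_scores(df2, s, g, weights = w)$mean_score,
               tab$mean_score)
})

test_that("external validation computes both correlations and handles mismatches", {
  tab <- state_validation_table()
  expect_equal(nrow(tab), 29)
  # a score validated against itself is perfectly correlated
  self <- external_validation(tab, tab, by = "state", score = "hlc_mean",
                              indicator = "hlc_mean")
  expect_equal(self$pearson, 1)
  expect_equal(self$spearman, 1)
  # Pearson is invariant to affine transforms, Spearman to monotone ones
  tr <- tab
  tr$nsdp_affine <- 2.5 * tr$nsdp_pc + 10
  tr$nsdp_mono <- exp(tr$nsdp_pc / 30)
  v0 <- external_validation(tab, tab, by = "state", score = "hlc_mean",
                            indicator = "nsdp_pc")
  va <- external_validation(tab, tr, by = "state", score = "hlc_mean",
                            indicator = "nsdp_affine")
  vm <- external_validation(tab, tr, by = "state", score = "hlc_mean",
                            indicator = "nsdp_mono")
  expect_equal(va$pearson, v0$pearson)
  expect_equal(vm$spearman, v0$spearman)
  # unmatched labels are excluded with a warning
  short <- tab[1:20, ]
  expect_warning(
    vs <- external_validation(tab, short, by = "state", score = "hlc_mean",
                              indicator = "nsdp_pc"),
    "unmatched"
  )
  expect_equal(vs$n_groups, 20)
  expect_error(external_validation(tab[1:2, ], tab[1:2, ], by = "state",
                                   score = "hlc_mean", indicator = "nsdp_pc"),
               "3 matched")
})
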