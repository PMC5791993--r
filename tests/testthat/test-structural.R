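p_tab3 <- hlc_params(
  loadings = 1.457, thresholds = -0.658,
  slopes = 1.437, gamma_linear = 0.202, gamma_quadratic = -0.006,
  tau = 3.476, sigma_u2 = 0.230
)

test_that("linear predictor assembles fixed, latent, quadratic and cluster terms", {
  p0 <- hlc_params(gamma_linear = 0.202, gamma_quadratic = -0.006)
  expect_equal(linear_predictor(numeric(0), 0, 0, hlc_params()), 0)
  expect_equal(linear_predictor(numeric(0), 1, 0, p0), 0.196)
  p1 <- hlc_params(beta = 2, tau = 0.5)
  expect_equal(linear_predictor(1, 0, -1, p1), 0.5)
  expect_error(linear_predictor(c(1, 2), 0, 0, p1), "length")
})

test_that("choice probability is the probit of the linear predictor", {
  p0 <- hlc_params()
  expect_equal(choice_prob(numeric(0), 0, 0, p0), 0.5)
  p_thr <- hlc_params(tau = 3.476)
  expect_equal(choice_prob(numeric(0), 0, 0, p_thr), pnorm(-3.476))
  expect_equal(pnorm(-3.476), 2.55e-4, tolerance = 2e-3)
  # limit behaviour
  expect_equal(choice_prob(numeric(0), 0, 50, p0), 1 - .Machine$double.eps)
  # monotone in u and in x'beta
  pb <- hlc_params(beta = 1)
  u_grid <- seq(-2, 2, by = 0.5)
  probs_u <- vapply(u_grid, function(u) choice_prob(0, 0, u, pb), numeric(1))
  expect_true(all(diff(probs_u) > 0))
  x_grid <- seq(-2, 2, by = 0.5)
  probs_x <- vapply(x_grid, function(x) choice_prob(x, 0, 0, pb), numeric(1))
  expect_true(all(diff(probs_x) > 0))
})

test_that("closed-form marginal choice probability integrates both latent terms", {
  p <- hlc_params(beta = 0, gamma_linear = 1, tau = 0)
  expect_equal(marginal_choice_prob(0, p, latent_mean = 0, sigma_u2 = 0), 0.5)
  # degenerate case: no latent effect, no cluster variance
  pd <- hlc_params(beta = 0.7, gamma_linear = 0, tau = 0.2)
  expect_equal(marginal_choice_prob(1, pd, latent_mean = 3, sigma_u2 = 0),
               choice_prob(1, 0, 0, pd))
  pq <- hlc_params(gamma_linear = 0.2, gamma_quadratic = -0.01)
  expect_error(marginal_choice_prob(numeric(0), pq), "gamma_quadratic")
  # dense-grid oracle agreement over random draws
  set.seed(21)
  for (i in 1:10) {
    pr <- hlc_params(beta = runif(1, -1, 1), gamma_linear = runif(1, -1, 1),
                     tau = runif(1, -1, 1), sigma_u2 = runif(1, 0, 1))
    mu <- runif(1, -1.5, 1.5)
    x <- runif(1, -1, 1)
    expect_equal(
      marginal_choice_prob(x, pr, latent_mean = mu),
      oracle_marginal_choice_prob(x, pr, mu, pr$sigma_u2),
      tolerance = 1e-6
    )
  }
})

test_that("intraclass correlation follows sigma_u2 / (1 + sigma_u2)", {
  expect_equal(icc(0), 0)
  expect_equal(icc(1), 0.5)
  expect_equal(icc(0.230), 0.230 / 1.230)
  s <- seq(0, 5, by = 0.25)
  expect_true(all(diff(icc(s)) > 0))
  expect_true(all(icc(s) >= 0 & icc(s) < 1))
  expect_error(icc(-0.1), "non-negative")
})

test_that("person conditional density factorizes items and outcome", {
  # all items missing: returns the outcome probability alone
  expect_equal(
    person_conditional_density(0.3, 0.1, p_tab3, y = 1, x = numeric(0),
                               items = NA),
    choice_prob(numeric(0), 0.3, 0.1, p_tab3)
  )
  # single observed item, no outcome: equals the item response probability
  expect_equal(
    person_conditional_density(0.5, 0, p_tab3, y = NA, items = 1L),
    item_response_prob(0.5, 1.457, -0.658)
  )
  # two items plus outcome: hand product of three factors
  p2 <- hlc_params(loadings = c(1.2, 0.8), thresholds = c(0.3, -0.4),
                   beta = 0.5, gamma_linear = 0.25, tau = 0.1,
                   sigma_u2 = 0.2)
  z <- 0.7; u <- -0.2
  hand <- item_response_prob(z, 1.2, 0.3) *
    (1 - item_response_prob(z, 0.8, -0.4)) *
    (1 - choice_prob(1, z, u, p2))
  expect_equal(
    person_conditional_density(z, u, p2, y = 0, x = 1, items = c(1L, 0L)),
    hand
  )
  expect_error(person_conditional_density(Inf, 0, p2), "finite")
  expect_error(person_conditional_density(0, 0, p2, items = 1L), "length")
})
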