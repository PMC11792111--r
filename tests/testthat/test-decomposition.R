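test_that("expected response is the exact probability-weighted sum", {
  f <- hill_curve(1, 0, 1, 2)
  pm <- dose_distribution(1.3, 1)
  expect_equal(expected_response(f, pm), as.numeric(predict(f, 1.3)))

  lin <- linear_curve(0.5, -0.2)
  d <- dose_distribution(c(0.4, 1.1, 2.7), c(0.2, 0.5, 0.3))
  expect_equal(expected_response(lin, d),
               as.numeric(predict(lin, mean(d))))  # linearity

  d2 <- dose_distribution(c(0.5, 1.5), c(0.5, 0.5))
  oh <- oracle_hill(1, 0, 1, 2)
  expect_equal(expected_response(f, d2), 0.5 * oh(0.5) + 0.5 * oh(1.5))
})

test_that("Jensen effect: zero at a point mass, sign follows local convexity", {
  f <- hill_curve(1, 0, 1, 2)
  expect_equal(jensen_effect(f, dose_distribution(0.8, 1)), 0)

  # small two-point perturbations: sign of E[f] - f(E) matches curvature
  for (mu in c(0.2, 0.5, 2, 4)) {
    d <- dose_distribution(c(mu - 0.01, mu + 0.01), c(0.5, 0.5))
    expect_equal(sign(jensen_effect(f, d)), sign(curvature(f, mu)))
  }
  # concave region: average response to varying doses is below the response
  # to the average dose
  dconc <- dose_distribution(c(0.3, 0.9), c(0.5, 0.5))
  expect_lt(jensen_effect(f, dconc), 0)
})

test_that("decompose_effects matches the brute-force oracle on random supports", {
  set.seed(42)
  for (i in 1:40) {
    pars <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, 0.3, 3),
              runif(1, 0.5, 3))
    curve <- hill_curve(pars[1], pars[2], pars[3], pars[4])
    k_o <- sample(2:5, 1); k_r <- sample(2:5, 1)
    xo <- dose_distribution(sort(runif(k_o, 0.01, 5)), runif(k_o))
    xr <- dose_distribution(sort(runif(k_r, 0.01, 5)), runif(k_r))
    got <- decompose_effects(curve, xo, xr)
    want <- oracle_decompose(oracle_hill(pars[1], pars[2], pars[3], pars[4]),
                             xo$support, xo$probs, xr$support, xr$probs)
    for (q in c("jr", "s", "js", "t_hat"))
      expect_equal(got[[q]], want[[q]], tolerance = 1e-12)
    # additivity against the direct form E[f(Xo)] - f(E[Xr])
    expect_lt(abs(got$t_hat - (expected_response(curve, xo) -
                                 as.numeric(predict(curve, mean(xr))))), 1e-10)
  }
})

test_that("degenerate geometries: linear curves and absent selectivity", {
  lin <- linear_curve(2, -0.7)
  xo <- observed_distribution(1.89, 0.61, c(0.3, 0.1))
  xr <- reference_distribution(1.89, 0.61)
  parts <- decompose_effects(lin, xo, xr)
  expect_identical(parts$jr, 0)
  expect_lt(abs(parts$js), 1e-15)  # zero up to one ulp of the curve evaluations
  expect_equal(parts$s, -0.7 * (mean(xo) - mean(xr)))

  f <- hill_curve(1, 0, 1, 2)
  same <- decompose_effects(f, xr, xr)
  expect_identical(same$s, 0)
  expect_identical(same$js, 0)
  expect_equal(same$t_hat, same$jr)
})

test_that("small-variance limit: Jr approaches (delta^2/2) f''(mu)", {
  for (pars in list(c(1, 0, 1, 2), c(0.04, 0.01, 2, 2), c(-0.6, -2.9, 2, 2))) {
    curve <- hill_curve(pars[1], pars[2], pars[3], pars[4])
    for (mu in c(0.66, 1.89)) {
      delta <- 1e-3 * mu
      jr <- decompose_effects(curve,
                              reference_distribution(mu, delta),
                              reference_distribution(mu, delta))$jr
      expect_equal(jr / (delta^2 / 2), curvature(curve, mu), tolerance = 0.01)
    }
  }
})

test_that("Jr is positive for any two-point diet inside a convex region", {
  curve <- hill_curve(1, 0, 1, 3)   # convex beyond the inflection
  x_infl <- 1 * ((3 - 1) / (3 + 1))^(1 / 3)
  lo <- x_infl * 1.05
  set.seed(8)
  for (i in 1:20) {
    mu <- runif(1, lo + 0.5, 5)
    delta <- runif(1, 0.01, min(mu - lo, 2))
    expect_gt(decompose_effects(curve,
                                reference_distribution(mu, delta),
                                reference_distribution(mu, delta))$jr, 0)
  }
})

test_that("observed total effect: toy arithmetic, links, and bootstrap", {
  # constant arm mean 0.10, variable arm mean 0.05, known pooled link SD
  const <- c(0.08, 0.10, 0.12); vari <- c(0.03, 0.05, 0.07)
  eff <- observed_total_effect(toy_cages(const, vari), "rgr", "high",
                               n_draws = 50, seed = 1)
  expect_equal(eff$estimate_link, -0.05)
  pooled <- sqrt(((2) * var(const) + (2) * var(vari)) / 4)
  expect_equal(eff$sd_link, pooled)
  expect_equal(eff$estimate, -0.05 / pooled)

  # identical arms: exactly zero
  same <- observed_total_effect(toy_cages(c(0.1, 0.2), c(0.1, 0.2)), "rgr",
                                "high", n_draws = 10, seed = 1)
  expect_equal(same$estimate_link, 0)

  # herbivory is contrasted on the shrunk logit scale
  cg <- toy_cages(c(0.30, 0.34), c(0.20, 0.24), response = "herbivory")
  effh <- observed_total_effect(cg, "herbivory", "high", n_draws = 10,
                                seed = 1)
  y <- adjusted_logit(c(0.30, 0.34, 0.20, 0.24), 4)
  expect_equal(effh$estimate_link, mean(y[3:4]) - mean(y[1:2]))

  a <- observed_total_effect(toy_cages(const, vari), "rgr", "high",
                             n_draws = 100, seed = 9)
  b <- observed_total_effect(toy_cages(const, vari), "rgr", "high",
                             n_draws = 100, seed = 9)
  expect_identical(a$draws_link, b$draws_link)

  missing_arm <- toy_cages(const, vari)
  missing_arm$variation_treatment <- "constant"
  expect_error(observed_total_effect(missing_arm, "rgr", "high"), "arm")
})

test_that("monte-carlo cross: full Cartesian product and per-draw identities", {
  set.seed(2)
  d <- rep(exp(seq(log(0.031), log(16.1), length.out = 10)), 6)
  y <- predict(hill_curve(0.04, 0.01, 2, 2), d) + rnorm(length(d), 0, 0.02)
  fit <- fit_dose_response(d, y)
  cd <- sample_curve_draws(fit, 20, seed = 1)
  pref <- matrix(abs(rnorm(30, c(0.2, 0.1), 0.02)), ncol = 2, byrow = TRUE)
  t_obs <- observed_total_effect(
    toy_cages(rnorm(10, 0.03, 0.01), rnorm(10, 0.025, 0.01)), "rgr", "high",
    n_draws = 37, seed = 2)

  res <- monte_carlo_decompose(cd, pref, mu = 1.89, delta = 0.61,
                               t_obs = t_obs)
  expect_equal(nrow(res$draws), 20 * 15)
  expect_true(all(abs(res$draws$t_hat -
                        (res$draws$jr + res$draws$s + res$draws$js)) < 1e-10))
  expect_true(all(abs(res$draws$eps -
                        (res$draws$t_obs - res$draws$t_hat)) < 1e-10))
  # To bootstrap draws are recycled across the cross
  expect_equal(res$draws$t_obs, rep_len(t_obs$draws_link, 300))

  # single-draw cross: summaries equal the one simulation, intervals collapse
  res1 <- monte_carlo_decompose(list(hill_curve(1, 0, 1, 2)),
                                matrix(c(0.2, 0.1), 1), mu = 1, delta = 0.5)
  expect_equal(nrow(res1$draws), 1)
  expect_equal(res1$summary$mean, res1$summary$lower)
  expect_equal(res1$summary$mean, res1$summary$upper)

  # identical draws: zero interval width
  cd0 <- cd; cd0$coefs <- cd$coefs[rep(1, 10), ]
  res0 <- monte_carlo_decompose(cd0, matrix(c(0.2, 0.1), 10, 2,
                                            byrow = TRUE),
                                mu = 1.89, delta = 0.61)
  width <- res0$summary$upper - res0$summary$lower
  expect_true(all(abs(width) < 1e-12))

  expect_error(monte_carlo_decompose(cd, pref[0, ], 1.89, 0.61), "non-empty")
  expect_error(monte_carlo_decompose(cd, pref, 20, 0.61), "outside")
})

test_that("standardization rescales everything and round-trips", {
  res <- monte_carlo_decompose(list(hill_curve(1, 0, 1, 2)),
                               matrix(c(0.2, 0.1, 0.25, 0.12), 2,
                                      byrow = TRUE),
                               mu = 1, delta = 0.5)
  s2 <- standardize_effects(res, 2)
  expect_equal(s2$draws$jr, res$draws$jr / 2)
  expect_equal(s2$summary$mean, res$summary$mean / 2)
  expect_true(all(abs(s2$draws$t_hat -
                        (s2$draws$jr + s2$draws$s + s2$draws$js)) < 1e-12))
  back <- standardize_effects(s2, 1 / 2)
  expect_equal(back$draws, res$draws, tolerance = 1e-12)
  expect_identical(standardize_effects(res, 1)$draws, res$draws)
  expect_error(standardize_effects(res, 0), "positive")
})

test_that("mechanism shares sum to 100% per draw and match the oracle", {
  # single known draw: shares (80, 15, 5)
  one <- monte_carlo_decompose(list(linear_curve(0, 1)),
                               matrix(c(0.5, 0.5), 1), mu = 1, delta = 0.5)
  one$draws <- data.frame(jr = 0.8, s = 0.15, js = 0.05, t_hat = 1.0)
  sh <- mechanism_shares(one)
  expect_equal(sh$summary$mean, c(80, 15, 5))

  # linear curve with selectivity: s is the whole predicted effect
  lin <- monte_carlo_decompose(list(linear_curve(0, -0.3)),
                               matrix(c(0.2, 0.1), 1), mu = 1, delta = 0.5)
  expect_equal(mechanism_shares(lin)$summary$mean, c(0, 100, 0))

  # toy Hill configuration against the brute-force oracle
  f <- hill_curve(1, 0, 1, 2)
  res <- monte_carlo_decompose(list(f), matrix(c(0.7, 0.3), 1),
                               mu = 1, delta = 0.5)
  or <- oracle_decompose(oracle_hill(1, 0, 1, 2), c(0.5, 1.5), c(0.7, 0.3),
                         c(0.5, 1.5), c(0.5, 0.5))
  expect_equal(unname(unlist(mechanism_shares(res)$summary$mean)),
               100 * c(or$jr, or$s, or$js) / or$t_hat, tolerance = 1e-10)
  expect_true(all(abs(rowSums(mechanism_shares(res)$draws) - 100) < 1e-9))

  # near-zero predicted totals are excluded and counted
  flat <- monte_carlo_decompose(list(linear_curve(1, 0)),
                                matrix(c(0.2, 0.1), 1), mu = 1, delta = 0.5)
  expect_error(mechanism_shares(flat), "below tolerance")
})

test_that("doubling Monte-Carlo draws moves summary means by less than
          twice the Monte-Carlo standard error", {
  set.seed(3)
  d <- rep(exp(seq(log(0.031), log(16.1), length.out = 10)), 6)
  y <- predict(hill_curve(0.04, 0.01, 2, 2), d) + rnorm(length(d), 0, 0.02)
  fit <- fit_dose_response(d, y)
  pref_fun <- function(n, seed) {
    set.seed(seed)
    matrix(abs(rnorm(2 * n, c(0.2, 0.1), 0.02)), ncol = 2, byrow = TRUE)
  }
  r1 <- monte_carlo_decompose(sample_curve_draws(fit, 100, seed = 1),
                              pref_fun(100, 1), 1.89, 0.61)
  r2 <- monte_carlo_decompose(sample_curve_draws(fit, 200, seed = 2),
                              pref_fun(200, 2), 1.89, 0.61)
  for (q in c("jr", "s", "js", "t_hat")) {
    m1 <- r1$summary$mean[r1$summary$quantity == q]
    m2 <- r2$summary$mean[r2$summary$quantity == q]
    # conservative MC SE: draws are dependent across the cross, so scale by
    # the smaller marginal count rather than the number of cross rows
    se <- sd(r1$draws[[q]]) / sqrt(100)
    expect_lt(abs(m1 - m2), 2 * se + 1e-12)
  }
})
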