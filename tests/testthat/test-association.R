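# Deviation-behavior association: correlations, Bayesian LM, Savage-Dickey.

test_that("correlation matrix matches the direct formula and marks stars", {
  set.seed(1)
  n <- 200
  X <- matrix(rnorm(n * 5), n)
  colnames(X) <- paste0("d", 1:5)
  cm <- correlation_matrix(X)
  expect_equal(diag(cm$r), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  # direct covariance-formula oracle on every pair
  for (i in 1:4) for (j in (i + 1):5) {
    r_direct <- mean((X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j]))) /
      (sqrt(mean((X[, i] - mean(X[, i]))^2)) * sqrt(mean((X[, j] - mean(X[, j]))^2)))
    expect_equal(cm$r[i, j], r_direct, tolerance = 1e-12)
    # p-value from the two-sided t-test oracle
    expect_equal(cm$p[i, j], cor.test(X[, i], X[, j])$p.value, tolerance = 1e-9)
  }
  # perfectly anti-correlated pair
  cm2 <- correlation_matrix(cbind(a = X[, 1], b = -X[, 1] * 2 + 3))
  expect_equal(cm2$r["a", "b"], -1)
  expect_equal(cm2$stars["a", "b"], "***")
  expect_error(correlation_matrix(cbind(X[, 1], rep(1, n))), "constant")
  expect_error(correlation_matrix(X[1:2, ]), "3 rows")
})

test_that("standardization centers, scales, and ignores affine shifts", {
  set.seed(2)
  x <- rnorm(50, 10, 3)
  s <- standardize_predictors(x = x)$x
  expect_lt(abs(mean(s)), 1e-12)
  expect_equal(sd(s), 1)
  s2 <- standardize_predictors(x = 5 * x + 7)$x
  expect_equal(s, s2)
  expect_error(standardize_predictors(x = rep(1, 10)), "constant")
})

test_that("with no data the posterior equals the prior and BF01 is 1", {
  m <- fit_bayesian_lm(numeric(0), numeric(0), numeric(0), numeric(0),
                       prior_sd = 0.8)
  expect_equal(m$b_mean, 0)
  expect_equal(m$b_sd, 0.8)
  expect_equal(savage_dickey_bf(m), 1)
  q <- posterior_quantiles(m)
  expect_equal(unname(q), qnorm(c(0.025, 0.975), 0, 0.8))
})

test_that("the posterior concentrates on a strong true coefficient", {
  d <- make_assoc_data(1000, b_dom = 0.5, seed = 3)
  m <- fit_bayesian_lm(d$z, d$age_std, d$sex, d$dom_std)
  expect_lt(abs(m$b_mean - 0.5), 0.05)
  bf <- savage_dickey_bf(m)
  expect_lt(bf, 0.01)
  expect_equal(classify_bf(bf), "extreme (alternative)")
})

test_that("analytic and sampling posteriors agree", {
  d <- make_assoc_data(500, b_dom = 0.08, seed = 4)
  m <- fit_bayesian_lm(d$z, d$age_std, d$sex, d$dom_std)
  draws <- sample_posterior(m, draws = 20000, seed = 11)[, "domain"]
  expect_lt(abs(mean(draws) - m$b_mean) / abs(m$b_mean), 0.02)
  expect_lt(abs(sd(draws) - m$b_sd) / m$b_sd, 0.05)
  bf_a <- savage_dickey_bf(m)
  bf_s <- savage_dickey_bf(m, "sampling", draws = 50000, seed = 12)
  expect_lt(abs(bf_s - bf_a) / bf_a, 0.05)
  expect_error(savage_dickey_bf(m, "sampling", draws = 100), "1000")
})

test_that("the analytic posterior matches the known-noise conjugate oracle", {
  # z = b*dom + e with sigma known to the oracle: the conjugate posterior
  # for the coefficients is N(V X'z / sigma^2, V), V = (X'X/sigma^2 + S^-1)^-1.
  # The sigma-marginalized posterior agrees tightly on mean/SD; its density
  # at zero (hence BF01) also reflects the sampling fluctuation of the
  # residual scale, so that comparison gets a wider band.
  set.seed(5)
  n <- 1500; sigma <- 0.9; b_true <- 0.04
  dom <- standardize_predictors(x = rnorm(n))$x
  age <- standardize_predictors(x = rnorm(n))$x
  sex <- rbinom(n, 1, 0.5)
  z <- b_true * dom + sigma * rnorm(n)
  m <- fit_bayesian_lm(z, age, sex, dom, prior_sd = 1)
  X <- cbind(1, age, sex, dom)
  V <- solve(crossprod(X) / sigma^2 + diag(c(0.01, 0.01, 0.01, 1)))
  mb <- drop(V %*% crossprod(X, z)) / sigma^2
  bf_oracle <- dnorm(0, mb[4], sqrt(V[4, 4])) / dnorm(0, 0, 1)
  expect_lt(abs(m$b_mean - mb[4]), 0.02 * max(abs(mb[4]), 0.05))
  expect_lt(abs(m$b_sd - sqrt(V[4, 4])) / sqrt(V[4, 4]), 0.02)
  expect_lt(abs(savage_dickey_bf(m) - bf_oracle) / bf_oracle, 0.10)
})

test_that("evidence bands partition the positive axis as published", {
  probes <- list(
    list(0.005, "extreme (alternative)"),
    list(0.05, "strong (alternative)"),
    list(0.2, "moderate (alternative)"),
    list(0.5, "anecdotal (alternative)"),
    list(1, "evidence in either direction"),
    list(2, "anecdotal (null)"),
    list(5, "moderate (null)"),
    list(15, "strong (null)"),
    list(50, "very strong (null)"),
    list(200, "extreme (null)"))
  for (p in probes) expect_equal(classify_bf(p[[1]]), p[[2]])
  # boundary conventions: [lower, upper) on the alternative side,
  # (lower, upper] on the null side
  expect_equal(classify_bf(0.3), "anecdotal (alternative)")
  expect_equal(classify_bf(0.1), "moderate (alternative)")
  expect_equal(classify_bf(0.01), "very strong (alternative)")
  expect_equal(classify_bf(3), "anecdotal (null)")
  expect_equal(classify_bf(100), "very strong (null)")
  expect_error(classify_bf(0), "positive")
  expect_error(classify_bf(-2), "positive")
  # every positive BF maps to exactly one label
  set.seed(6)
  for (bf in exp(runif(50, -8, 8))) expect_length(classify_bf(bf), 1L)
})

test_that("rank-deficient predictors and misaligned inputs are rejected", {
  d <- make_assoc_data(100, b_dom = 0, seed = 7)
  expect_error(fit_bayesian_lm(d$z, d$dom_std, d$sex, d$dom_std),
               "rank-deficient")
  expect_error(fit_bayesian_lm(d$z, d$age_std[1:50], d$sex, d$dom_std),
               "lengths differ")
  expect_error(fit_bayesian_lm(d$z, d$age_std, d$sex, d$dom_std,
                               prior_sd = Inf), "proper prior")
})

test_that("the association grid has full cardinality and is order-invariant", {
  set.seed(8)
  n <- 300
  co <- generate_cohort(n, seed = 31)
  lat <- attr(co, "latents")
  devs <- data.frame(subject_id = co$subject_id,
                     FA_dev = lat$deviations[, "FA"] + rnorm(n, 0, 0.3),
                     CT_dev = lat$deviations[, "CT"] + rnorm(n, 0, 0.3))
  grid <- run_association_grid(devs, lat$domains, lat$general,
                               cog_dev = lat$deviations[, "COG"],
                               age = co$age, sex = co$sex)
  expect_equal(nrow(grid), 2 * 9)
  expect_setequal(unique(grid$feature), c("FA_dev", "CT_dev"))
  expect_true(all(grid$BF01 > 0))
  expect_true(all(grid$label == vapply(grid$BF01, classify_bf, "")))

  # consistent permutation of subjects leaves the results unchanged
  p <- sample.int(n)
  grid_p <- run_association_grid(devs[p, ], lat$domains[p, ], lat$general[p],
                                 cog_dev = lat$deviations[p, "COG"],
                                 age = co$age[p], sex = co$sex[p])
  expect_equal(grid, grid_p, tolerance = 1e-12)
})
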