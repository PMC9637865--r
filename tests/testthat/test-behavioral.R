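# Behavioral decomposition: cognitive general factor and ICA domains.

test_that("rank-1 battery yields a perfect first component", {
  set.seed(1)
  v <- rnorm(100)
  tests <- matrix(v, 100, 14)
  colnames(tests) <- sprintf("cog_%02d", 1:14)
  cf <- cognitive_general_factor(tests)
  expect_equal(cf$variance_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(cf$scores, v)), 1, tolerance = 1e-12)
  expect_equal(mean(cf$scores), 0, tolerance = 1e-12)
  expect_equal(sd(cf$scores), 1, tolerance = 1e-12)
})

test_that("the general factor recovers a simulated one-factor battery", {
  set.seed(2)
  n <- 2000
  f <- rnorm(n)
  lam <- 0.7
  tests <- lam * matrix(f, n, 14) + sqrt(1 - lam^2) * matrix(rnorm(n * 14), n)
  cf <- cognitive_general_factor(tests)
  expect_gt(abs(cor(cf$scores, f)), 0.95)
  # sign convention: mean loading positive
  expect_gt(mean(cf$loadings), 0)
})

test_that("sign convention is invariant to global negation of the battery", {
  set.seed(3)
  n <- 300
  f <- rnorm(n)
  tests <- 0.7 * matrix(f, n, 14) + 0.7 * matrix(rnorm(n * 14), n)
  cf_pos <- cognitive_general_factor(tests)
  cf_neg <- cognitive_general_factor(-tests)
  expect_gt(mean(cf_pos$loadings), 0)
  expect_gt(mean(cf_neg$loadings), 0)
  expect_equal(abs(cor(cf_pos$scores, cf_neg$scores)), 1, tolerance = 1e-10)
})

test_that("PC1 scores are an orthogonal projection of the standardized tests", {
  set.seed(4)
  n <- 400
  tests <- 0.6 * matrix(rnorm(n), n, 14) + matrix(rnorm(n * 14), n)
  cf <- cognitive_general_factor(tests)
  Xs <- scale(tests)
  fitted <- outer(cf$scores, rep(1, 14))
  for (j in 1:14) {
    resid <- residuals(lm(Xs[, j] ~ cf$scores))
    expect_lt(abs(cor(resid, cf$scores)), 1e-10)
  }
})

test_that("degenerate batteries are rejected", {
  expect_error(cognitive_general_factor(matrix(1, 50, 14)), "constant")
  m <- matrix(rnorm(10 * 14), 10)
  expect_error(cognitive_general_factor(m), "more subjects")
  m2 <- matrix(rnorm(50 * 14), 50); m2[3, 4] <- NA
  expect_error(cognitive_general_factor(m2), "missing")
})

test_that("ICA separates mixed Laplacian sources up to sign and permutation", {
  set.seed(5)
  n <- 5000
  S <- matrix(rexp(n * 4) * sign(runif(n * 4) - 0.5), n)
  A <- matrix(rnorm(16), 4)
  X <- S %*% t(A)
  ic <- ica_domains(X, n_components = 4, n_runs = 10, seed = 9)
  expect_gt(matched_abs_cor(ic$weights, S), 0.95)
  expect_true(all(ic$stability > 0.8))
})

test_that("pure Gaussian data gives unstable components and a warning", {
  set.seed(6)
  X <- matrix(rnorm(1000 * 20), 1000)
  expect_warning(ic <- ica_domains(X, n_components = 4, n_runs = 10, seed = 3),
                 "stability")
  expect_lt(min(ic$stability), 0.5)
})

test_that("ICA is deterministic under a fixed seed", {
  set.seed(7)
  co <- generate_cohort(400, seed = 15)
  items <- co[, sprintf("psy_%03d", 1:129)]
  d1 <- suppressWarnings(ica_domains(items, n_runs = 5, seed = 2))
  d2 <- suppressWarnings(ica_domains(items, n_runs = 5, seed = 2))
  expect_identical(d1$weights, d2$weights)
  expect_identical(d1$stability, d2$stability)
})

test_that("domain weights recover the generating latents from items", {
  co <- generate_cohort(2000, seed = 23)
  lat <- attr(co, "latents")
  dom <- suppressWarnings(
    ica_domains(co[, sprintf("psy_%03d", 1:129)], seed = 5))
  cc <- abs(cor(dom$weights, lat$domains))
  expect_true(all(apply(cc, 2, max) > 0.8))
  # orientation: higher weight = more symptoms (positive top-loading sum)
  for (j in 1:7) {
    top <- order(abs(dom$mixing[, j]), decreasing = TRUE)[1:10]
    expect_gt(sum(dom$mixing[top, j]), 0)
  }
})

test_that("general psychopathology is the row mean and is linear", {
  w <- matrix(1:7, 1)
  expect_equal(general_psychopathology(w), 4)
  expect_equal(general_psychopathology(matrix(0, 3, 7)), rep(0, 3))
  set.seed(8)
  W <- matrix(rnorm(35), 5, 7)
  expect_equal(general_psychopathology(3 * W), 3 * general_psychopathology(W))
  expect_equal(general_psychopathology(W), rowMeans(W))
  expect_error(general_psychopathology(W[, 1:6]), "7")
})
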