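# Synthetic cohort generator: trajectories, latent structure, determinism.

test_that("trajectory evaluation is deterministic and respects its contract", {
  flat <- trajectory_spec("X", baseline = 0.5)
  expect_equal(trajectory_value(flat, c(8, 15, 22), 0), rep(0.5, 3))

  off <- trajectory_spec("X", baseline = 0.5, sex_offset = 0.1)
  ages <- c(9, 12.5, 20)
  expect_equal(trajectory_value(off, ages, 1) - trajectory_value(off, ages, 0),
               rep(0.1, 3))

  expect_error(trajectory_value(flat, 23, 0), "outside")
  expect_error(trajectory_value(flat, 7.5, 0), "outside")

  # FA-like monotone-saturating coefficients are non-decreasing over the range
  fa <- default_trajectories()$FA
  grid <- trajectory_value(fa, seq(8, 22, by = 0.05), 0)
  expect_true(all(diff(grid) >= 0))
})

test_that("generation is byte-identical under a fixed seed", {
  co1 <- generate_cohort(100, seed = 7)
  co2 <- generate_cohort(100, seed = 7)
  expect_identical(co1, co2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(co1, f1); write_cohort(co2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(co1, generate_cohort(100, seed = 8)))
})

test_that("noiseless zero-deviation subjects lie exactly on their trajectory", {
  tr <- default_trajectories()
  tr <- lapply(tr, function(s) { s$noise_sd <- 0; s })
  ds <- default_deviation_structure()
  ds$scale[] <- 0
  co <- generate_cohort(50, trajectories = tr, dev_structure = ds, seed = 3)
  for (f in c("FA", "MD", "CT", "SA"))
    expect_equal(co[[f]], trajectory_value(tr[[f]], co$age, co$sex),
                 tolerance = 1e-12)
})

test_that("latent deviations carry the target correlation structure", {
  ds <- default_deviation_structure()
  co <- generate_cohort(5000, seed = 11)
  dev <- attr(co, "latents")$deviations
  R_emp <- cor(dev)
  expect_lt(abs(R_emp["FA", "RD"] - (-0.88)), 0.03)
  expect_lt(norm(R_emp - ds$target_correlation, "F"), 0.05)
})

test_that("with no injected effects, domains and deviations are uncorrelated", {
  n <- 2000
  co <- generate_cohort(n, effects = list(), seed = 13)
  lat <- attr(co, "latents")
  cc <- cor(lat$domains, lat$deviations)
  # each of the 49 null correlations sits within its ~2-sigma sampling band;
  # the max over all pairs gets the multiplicity-adjusted bound
  expect_gte(mean(abs(cc) < 2 / sqrt(n)), 0.90)
  expect_lt(max(abs(cc)), 3.5 / sqrt(n))
})

test_that("injected effects shift the targeted deviation by the stated beta", {
  n <- 4000
  eff <- list(effect_spec("FA", 4L, -0.3))
  co <- generate_cohort(n, effects = eff, seed = 17)
  lat <- attr(co, "latents")
  slope <- coef(lm(lat$deviations[, "FA"] ~ lat$domains[, 4]))[2]
  expect_lt(abs(slope - (-0.3)), 3 / sqrt(n))
  # untouched features stay unassociated
  expect_lt(abs(cor(lat$deviations[, "CT"], lat$domains[, 4])), 2.5 / sqrt(n))
})

test_that("item scores retain the generating latent structure", {
  n <- 2000
  co <- generate_cohort(n, seed = 19)
  lat <- attr(co, "latents")
  im <- default_item_model()
  items <- as.matrix(co[, rownames(im$loadings)])
  # naive re-estimated factor score: mean of each domain's item block
  for (j in 1:7) {
    block <- rownames(im$loadings)[im$loadings[, j] > 0]
    score <- rowMeans(items[, block])
    expect_gt(abs(cor(score, lat$domains[, j])), 0.8)
  }
})

test_that("generator rejects inconsistent specifications", {
  expect_error(generate_cohort(5, seed = 1), "at least 10")
  expect_error(generate_cohort(100), "seed")
  bad_R <- matrix(0.99, 3, 3); diag(bad_R) <- 1; bad_R[1, 2] <- bad_R[2, 1] <- -0.99
  expect_error(deviation_structure(c("a", "b", "c"), bad_R, rep(1, 3)),
               "positive semi-definite")
  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(deviation_structure(c("a", "b", "c"), asym, rep(1, 3)),
               "symmetric")
  expect_error(generate_cohort(50, effects = list(effect_spec("nope", 1L, 0.1)),
                               seed = 1),
               "not a modeled feature")
  expect_error(effect_spec("FA", 9L, 0.1), "1..7")
})
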