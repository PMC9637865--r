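# Shared test helpers: independent oracles and small fixture builders.

# Dense multivariate-normal log-density of y under N(0, Phi Phi'/alpha + I/beta)
# — the marginal likelihood of the BLR model, computed the brute-force way.
dense_blr_evidence <- function(Phi, y, alpha, beta) {
  n <- length(y)
  C <- Phi %*% t(Phi) / alpha + diag(n) / beta
  cC <- chol(C)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(cC))) +
            sum(backsolve(cC, y, transpose = TRUE)^2))
}

# All permutations of a vector (for source/component matching at small k).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# Best mean matched |corr| between recovered (columns of W) and true
# (columns of S) signals over all column permutations.
matched_abs_cor <- function(W, S) {
  cc <- abs(stats::cor(W, S))
  k <- ncol(S)
  max(vapply(all_perms(seq_len(k)),
             function(p) mean(cc[cbind(p, seq_len(k))]), numeric(1)))
}

# Small regression fixture for the normative model: data generated exactly
# under the BLR assumptions (smooth age trend + sex offset + Gaussian noise).
make_blr_cohort <- function(n, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  ages <- runif(n, 8, 22)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.4 + 0.02 * (ages - 15) - 0.0008 * (ages - 15)^2 + 0.01 * sex +
    rnorm(n, 0, noise_sd)
  data.frame(subject_id = sprintf("S%05d", seq_len(n)),
             age = ages, sex = sex, FA = y, stringsAsFactors = FALSE)
}

# Regression-level association fixture: z generated under the association
# model with a known standardized domain coefficient. seed = NULL draws from
# the current RNG stream (for replicate loops seeded once).
make_assoc_data <- function(n, b_dom, b_age = 0.1, b_sex = 0.1, sd_resid = 0.95,
                            seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  age <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  dom <- rnorm(n)
  sp <- standardize_predictors(age = age, dom = dom)
  z <- b_dom * sp$dom + b_age * sp$age + b_sex * sex + rnorm(n, 0, sd_resid)
  list(z = z, age_std = sp$age, sex = sex, dom_std = sp$dom)
}
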