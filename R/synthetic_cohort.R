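# ---------------------------------------------------------------------------
# Synthetic cohort generator
#
# Emulates the statistical structure the downstream analysis assumes:
#  * smooth nonlinear age trajectories per global brain feature plus a sex
#    offset, with additive measurement noise;
#  * a latent per-subject deviation vector (one element per feature,
#    cognition included) with a configurable cross-feature correlation
#    structure;
#  * seven latent psychopathology domains expressed through 129 four-level
#    ordinal questionnaire items (thresholded latent-Gaussian item model);
#  * a 14-test cognitive battery loading on a single latent cognition score;
#  * injectable linear deviation-domain effects of known standardized size,
#    so every downstream stage has a recoverable ground truth.
# ---------------------------------------------------------------------------

#' Trajectory specification for one feature
#'
#' Defines the population mean of a feature as a low-order polynomial in
#' centered/scaled age plus a sex offset. Age is mapped to
#' `t = (age - mid) / half` where `mid`/`half` are the midpoint and
#' half-width of `age_range`, so coefficients are on a comparable scale
#' across features.
#'
#' @param feature_name Label of the feature (e.g. `"FA"`).
#' @param baseline Feature value at the age midpoint for sex code 0
#'   (feature units).
#' @param age_coefficients Numeric vector `c(b1, b2, ...)` of polynomial
#'   coefficients on the scaled age `t` (feature units); may be `numeric(0)`
#'   for a flat trajectory.
#' @param sex_offset Additive offset for sex code 1 (feature units).
#' @param noise_sd Measurement noise SD (feature units), must be >= 0.
#' @param age_range Ages (years) over which the trajectory is defined.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(feature_name, baseline, age_coefficients = numeric(0),
                            sex_offset = 0, noise_sd = 0, age_range = c(8, 22)) {
  stopifnot(is.character(feature_name), length(feature_name) == 1L,
            is.numeric(baseline), length(baseline) == 1L, is.finite(baseline),
            is.numeric(age_coefficients), all(is.finite(age_coefficients)),
            is.numeric(sex_offset), is.finite(sex_offset),
            is.numeric(noise_sd), length(noise_sd) == 1L, is.finite(noise_sd),
            noise_sd >= 0,
            length(age_range) == 2L, age_range[1] < age_range[2])
  structure(list(feature_name = feature_name, baseline = baseline,
                 age_coefficients = as.numeric(age_coefficients),
                 sex_offset = sex_offset, noise_sd = noise_sd,
                 age_range = as.numeric(age_range)),
            class = "trajectory_spec")
}

#' Evaluate a trajectory at given ages
#'
#' @param spec A [trajectory_spec()].
#' @param age Ages in years, all within `spec$age_range`.
#' @param sex Sex codes in \{0, 1\} (recycled against `age`).
#' @return Feature values (deterministic; no noise).
#' @export
trajectory_value <- function(spec, age, sex) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (any(!is.finite(age)))
    stop("non-finite age")
  if (any(age < spec$age_range[1] - 1e-9 | age > spec$age_range[2] + 1e-9))
    stop(sprintf("age outside configured range [%g, %g]",
                 spec$age_range[1], spec$age_range[2]))
  if (any(!sex %in% c(0, 1))) stop("sex codes must be 0 or 1")
  mid <- mean(spec$age_range)
  half <- diff(spec$age_range) / 2
  t <- (age - mid) / half
  val <- rep(spec$baseline, length(t))
  for (j in seq_along(spec$age_coefficients))
    val <- val + spec$age_coefficients[j] * t^j
  val + spec$sex_offset * sex
}

#' Default feature trajectory library
#'
#' Monotone-saturating increase for FA, monotone-saturating decline for the
#' diffusivities (MD, RD, L1), near-linear decline for cortical thickness,
#' an inverted-U peaking in late childhood for total surface area, and a
#' strong saturating increase for latent cognition — the qualitative shapes
#' reported for these features across ages 8-22. Units: FA unitless; MD/RD/L1
#' in 10^-3 mm^2/s; CT in mm; SA in 10^5 mm^2; COG in latent SD units.
#'
#' @param age_range Ages (years) the trajectories cover.
#' @return Named list of [trajectory_spec()] objects
#'   (`FA, MD, RD, L1, CT, SA, COG`).
#' @export
default_trajectories <- function(age_range = c(8, 22)) {
  tj <- function(...) trajectory_spec(..., age_range = age_range)
  list(
    FA  = tj("FA",  baseline = 0.455, age_coefficients = c(0.020, -0.008),
             sex_offset = 0.005,  noise_sd = 0.008),
    MD  = tj("MD",  baseline = 0.800, age_coefficients = c(-0.030, 0.012),
             sex_offset = -0.005, noise_sd = 0.012),
    RD  = tj("RD",  baseline = 0.550, age_coefficients = c(-0.035, 0.014),
             sex_offset = -0.005, noise_sd = 0.015),
    L1  = tj("L1",  baseline = 1.300, age_coefficients = c(-0.020, 0.008),
             sex_offset = 0,      noise_sd = 0.015),
    CT  = tj("CT",  baseline = 2.950, age_coefficients = c(-0.090, 0.010),
             sex_offset = -0.020, noise_sd = 0.040),
    SA  = tj("SA",  baseline = 1.750, age_coefficients = c(-0.040, -0.035),
             sex_offset = 0.120,  noise_sd = 0.050),
    COG = tj("COG", baseline = 0.000, age_coefficients = c(0.800, -0.250),
             sex_offset = 0,      noise_sd = 0.100)
  )
}

#' Latent deviation correlation structure
#'
#' @param feature_names Ordered feature labels (6 brain features + cognition).
#' @param target_correlation Symmetric correlation matrix with unit diagonal;
#'   must be positive semi-definite.
#' @param scale Per-feature deviation SD in feature units (same order).
#' @return An object of class `deviation_structure`.
#' @export
deviation_structure <- function(feature_names, target_correlation, scale) {
  k <- length(feature_names)
  target_correlation <- as.matrix(target_correlation)
  stopifnot(nrow(target_correlation) == k, ncol(target_correlation) == k,
            length(scale) == k, all(scale >= 0))
  if (max(abs(target_correlation - t(target_correlation))) > 1e-10)
    stop("target correlation matrix must be symmetric")
  if (max(abs(diag(target_correlation) - 1)) > 1e-10)
    stop("target correlation matrix must have unit diagonal")
  ev <- eigen(target_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target correlation matrix is not positive semi-definite")
  dimnames(target_correlation) <- list(feature_names, feature_names)
  structure(list(feature_names = feature_names,
                 target_correlation = target_correlation,
                 scale = stats::setNames(as.numeric(scale), feature_names)),
            class = "deviation_structure")
}

#' Default latent deviation structure
#'
#' Strong negative FA-RD and FA-MD coupling, positive MD-RD/MD-L1 coupling,
#' weak links from the diffusion block to cortical morphometrics, and a
#' moderate surface-area-cognition association — the qualitative pattern of
#' empirical deviation-score correlations in developmental multimodal data.
#'
#' @return A [deviation_structure()] over `FA, MD, RD, L1, CT, SA, COG`.
#' @export
default_deviation_structure <- function() {
  nm <- c("FA", "MD", "RD", "L1", "CT", "SA", "COG")
  R <- diag(7)
  dimnames(R) <- list(nm, nm)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("FA", "MD", -0.65); set_r("FA", "RD", -0.88); set_r("FA", "L1", -0.03)
  # diffusivity cross-couplings chosen so the matrix stays positive definite
  # while preserving the strong FA-RD coupling
  set_r("MD", "RD", 0.78);  set_r("MD", "L1", 0.72);  set_r("RD", "L1", 0.42)
  set_r("CT", "FA", 0.05);  set_r("CT", "MD", -0.03); set_r("CT", "RD", -0.04)
  set_r("CT", "L1", 0.01);  set_r("CT", "SA", 0.13);  set_r("CT", "COG", 0.05)
  set_r("SA", "FA", 0.27);  set_r("SA", "MD", -0.15); set_r("SA", "RD", -0.20)
  set_r("SA", "L1", 0.05);  set_r("SA", "COG", 0.32)
  set_r("COG", "FA", 0.17); set_r("COG", "MD", -0.10)
  set_r("COG", "RD", -0.12); set_r("COG", "L1", -0.05)
  # nudge to the nearest PSD matrix if rounding made it indefinite
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    v <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(v) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    dimnames(R) <- list(nm, nm)
  }
  deviation_structure(nm, R,
                      scale = c(FA = 0.015, MD = 0.020, RD = 0.025, L1 = 0.025,
                                CT = 0.080, SA = 0.100, COG = 0.800))
}

#' Injected deviation-domain effect
#'
#' Ground-truth linear association between one latent psychopathology domain
#' (or the general score) and one feature's latent deviation, in standardized
#' units: deviation-Z units per SD of domain score.
#'
#' @param feature_name Modeled feature receiving the effect.
#' @param domain_index Integer 1..7, or `"general"`.
#' @param beta Standardized effect size.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(feature_name, domain_index, beta) {
  ok_dom <- (is.numeric(domain_index) && domain_index %in% 1:7) ||
    identical(domain_index, "general")
  if (!ok_dom) stop("domain_index must be an integer in 1..7 or \"general\"")
  stopifnot(is.character(feature_name), length(feature_name) == 1L,
            is.numeric(beta), is.finite(beta))
  structure(list(feature_name = feature_name, domain_index = domain_index,
                 beta = as.numeric(beta)),
            class = "effect_spec")
}

#' Default questionnaire item model
#'
#' 129 items partitioned into 7 near-equal blocks (one latent domain each),
#' loading 0.7 on their domain. Items are 4-level ordinal; thresholds on the
#' unit-variance latent item scale give right-skewed marginal category
#' frequencies of roughly 60/25/10/5 percent, typical of symptom screens in a
#' population sample.
#'
#' @param n_items Number of items (default 129).
#' @param n_domains Number of latent domains (default 7).
#' @param loading Item loading on its domain (default 0.7).
#' @param thresholds Increasing cutpoints on the latent item scale.
#' @return List with `loadings` (n_items x n_domains matrix) and `thresholds`.
#' @export
default_item_model <- function(n_items = 129, n_domains = 7, loading = 0.7,
                               thresholds = stats::qnorm(c(0.60, 0.85, 0.95))) {
  stopifnot(n_items >= n_domains, all(diff(thresholds) > 0),
            loading > 0, loading < 1)
  dom_of <- sort(rep_len(seq_len(n_domains), n_items))
  L <- matrix(0, n_items, n_domains)
  L[cbind(seq_len(n_items), dom_of)] <- loading
  rownames(L) <- sprintf("psy_%03d", seq_len(n_items))
  colnames(L) <- sprintf("domain%d", seq_len(n_domains))
  list(loadings = L, thresholds = as.numeric(thresholds))
}

# Standardized right-skewed latent domain draw: Gamma(shape) centered/scaled.
# Super-Gaussian and skewed, as symptom-burden latents are; also makes the
# ICA rotation identifiable.
rskew_std <- function(n, shape = 2) {
  (stats::rgamma(n, shape = shape, rate = 1) - shape) / sqrt(shape)
}

# Derive reproducible per-stage substreams from one global seed.
seed_substreams <- function(seed, n = 8L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic cohort
#'
#' Draws `n` subjects with ages uniform over the configured range, sex
#' Bernoulli(0.5), brain features as trajectory(age, sex) + scaled latent
#' deviation + measurement noise. Latent deviations are Gaussian with the
#' `dev_structure` correlation imposed exactly on the realized sample
#' (moment-conditioned draw), so recovery studies see the target structure
#' rather than its sampling error. 14 cognitive tests load on the latent cognition
#' feature, and 129 ordinal psychopathology items generated from 7
#' right-skewed latent domains through `item_model`. Effects in `effects`
#' add `beta` times the (standardized) domain score to the named feature's
#' unit-variance latent deviation.
#'
#' @param n Number of subjects (>= 10).
#' @param trajectories Named list of [trajectory_spec()]; must cover
#'   `dev_structure$feature_names`.
#' @param dev_structure A [deviation_structure()].
#' @param effects List of [effect_spec()] (may be empty).
#' @param item_model As returned by [default_item_model()].
#' @param n_cognitive_tests Number of battery tests (default 14).
#' @param cognitive_loading Test loading on latent cognition (default 0.7).
#' @param seed Integer seed (required; identical inputs + seed give an
#'   identical table).
#' @return A `data.frame` (class `cohort_table`): `subject_id`, `age`, `sex`,
#'   one column per brain feature, `cog_01..cog_14`, `psy_001..psy_129`.
#'   Ground-truth latents are attached as `attr(, "latents")` (a list with
#'   `deviations`, `domains`, `general`, `cognition`) for recovery studies.
#' @export
generate_cohort <- function(n,
                            trajectories = default_trajectories(),
                            dev_structure = default_deviation_structure(),
                            effects = list(),
                            item_model = default_item_model(),
                            n_cognitive_tests = 14L,
                            cognitive_loading = 0.7,
                            seed) {
  if (missing(seed)) stop("seed must be supplied")
  if (n < 10) stop("n must be at least 10")
  stopifnot(inherits(dev_structure, "deviation_structure"))
  feats <- dev_structure$feature_names
  if (!all(feats %in% names(trajectories)))
    stop("trajectories must cover all features in dev_structure")
  L <- item_model$loadings
  n_domains <- ncol(L)
  if (nrow(L) < 1 || n_domains < 1 || any(!is.finite(L)))
    stop("invalid item loading matrix")
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    if (!e$feature_name %in% feats)
      stop(sprintf("effect feature '%s' is not a modeled feature", e$feature_name))
  }

  ss <- seed_substreams(seed, 6L)
  age_range <- trajectories[[feats[1]]]$age_range

  set.seed(ss[1])
  age <- stats::runif(n, age_range[1], age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)

  # latent domain scores (standardized, right-skewed, independent)
  set.seed(ss[2])
  domains <- matrix(rskew_std(n * n_domains), n, n_domains)
  colnames(domains) <- colnames(L)
  general <- rowMeans(domains)

  # latent deviations: correlated Gaussian + injected domain effects.
  # The raw draws are centered and decorrelated before the target structure
  # is imposed, so the realized sample correlation matches the target
  # exactly (moment-conditioned draw); injected effects then perturb it by
  # their known amount.
  set.seed(ss[3])
  R <- dev_structure$target_correlation
  er <- eigen(R, symmetric = TRUE)
  Lr <- er$vectors %*% diag(sqrt(pmax(er$values, 1e-12)), nrow(R))
  Z <- matrix(stats::rnorm(n * length(feats)), n)
  Z <- sweep(Z, 2, colMeans(Z))
  Z <- Z %*% backsolve(chol(stats::cov(Z)), diag(length(feats)))
  dev <- Z %*% t(Lr)
  colnames(dev) <- feats
  sd_general <- 1 / sqrt(n_domains)  # theoretical SD of the mean of 7 iid latents
  for (e in effects) {
    src <- if (identical(e$domain_index, "general")) general / sd_general
           else domains[, e$domain_index]
    dev[, e$feature_name] <- dev[, e$feature_name] + e$beta * src
  }

  # brain/cognition features: trajectory + scaled deviation + noise
  set.seed(ss[4])
  feat_mat <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
  for (f in feats) {
    spec <- trajectories[[f]]
    feat_mat[, f] <- trajectory_value(spec, age, sex) +
      dev_structure$scale[f] * dev[, f] +
      stats::rnorm(n, 0, spec$noise_sd)
  }

  # cognitive battery: one-factor model on the standardized cognition feature
  set.seed(ss[5])
  cog <- feat_mat[, "COG"]
  cog_sd <- stats::sd(cog)
  cog_std <- if (cog_sd > 0) (cog - mean(cog)) / cog_sd else cog * 0
  lam <- cognitive_loading
  tests <- lam * matrix(cog_std, n, n_cognitive_tests) +
    sqrt(1 - lam^2) * matrix(stats::rnorm(n * n_cognitive_tests), n)
  colnames(tests) <- sprintf("cog_%02d", seq_len(n_cognitive_tests))

  # ordinal items: thresholded latent-Gaussian given domain scores
  set.seed(ss[6])
  uniq <- sqrt(pmax(1 - rowSums(L^2), 0))
  item_latent <- domains %*% t(L) +
    matrix(stats::rnorm(n * nrow(L)), n) * matrix(uniq, n, nrow(L), byrow = TRUE)
  items <- matrix(0L, n, nrow(L), dimnames = list(NULL, rownames(L)))
  for (th in item_model$thresholds)
    items <- items + (item_latent > th)

  brain_cols <- setdiff(feats, "COG")
  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    age = age, sex = sex,
                    feat_mat[, brain_cols, drop = FALSE],
                    tests, items, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "age_range") <- age_range
  attr(out, "latents") <- list(deviations = dev, domains = domains,
                               general = general, cognition = cog)
  out
}

#' Write / read a cohort table as delimited text
#'
#' Comma-separated, header row, one subject per row; numeric values are
#' serialized with 17 significant digits so a write/read round trip
#' reproduces values exactly.
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output (input) file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `data.frame` of class `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  write_table17(as.data.frame(cohort), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

# Full-precision text serialization shared by all stage outputs.
write_table17 <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
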