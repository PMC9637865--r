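# Out-of-sample deviation scores by k-fold cross-validation: each subject's
# Z comes from the model fitted on the other k-1 folds, with the spline
# basis rebuilt on the training ages of each fold.

#' Out-of-sample fit metrics
#'
#' Population (1/n) variances are used throughout. MSLL is the mean
#' standardized log loss: mean negative log predictive density minus that of
#' the trivial Gaussian predictor with mean `ref_mean` and variance
#' `ref_var` (negative values mean the model beats the trivial predictor).
#' A degenerate Pearson correlation (constant predictions) is reported as 0
#' with `rho_degenerate = TRUE`.
#'
#' @param y Observed values (length >= 2, nonzero variance).
#' @param yhat Predictive means.
#' @param yvar Predictive variances (needed for `msll`; may be `NULL`).
#' @param ref_mean,ref_var Trivial-predictor Gaussian parameters; default to
#'   the population mean/variance of `y`.
#' @return List: `explained_variance`, `smse`, `msll`, `rho`,
#'   `rho_degenerate`.
#' @export
fit_metrics <- function(y, yhat, yvar = NULL,
                        ref_mean = mean(y), ref_var = pvar(y)) {
  n <- length(y)
  if (n < 2 || length(yhat) != n) stop("y and yhat must have equal length >= 2")
  vy <- pvar(y)
  if (vy <= 0) stop("y has zero variance")
  resid <- y - yhat
  ev <- 1 - pvar(resid) / vy
  smse <- mean(resid^2) / vy
  msll <- NA_real_
  if (!is.null(yvar)) {
    if (length(yvar) != n || any(yvar <= 0)) stop("invalid predictive variances")
    nlpd <- 0.5 * log(2 * pi * yvar) + resid^2 / (2 * yvar)
    nlpd0 <- 0.5 * log(2 * pi * ref_var) + (y - ref_mean)^2 / (2 * ref_var)
    msll <- mean(nlpd - nlpd0)
  }
  sd_yhat <- sqrt(pvar(yhat))
  rho_degenerate <- sd_yhat < 1e-12
  rho <- if (rho_degenerate) 0 else stats::cor(y, yhat)
  list(explained_variance = ev, smse = smse, msll = msll,
       rho = rho, rho_degenerate = rho_degenerate)
}

# population variance
pvar <- function(x) mean((x - mean(x))^2)

#' Seeded k-fold partition
#'
#' Uniform seeded shuffle followed by a contiguous split into k near-equal
#' folds (no stratification).
#'
#' @param n Number of subjects.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed.
#' @return Integer vector of fold labels 1..k, one per subject.
#' @export
make_folds <- function(n, k, seed) {
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("need at least k subjects")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), times = sizes)
  folds
}

#' Cross-validated deviation scores for one feature
#'
#' Partitions subjects into `k` folds (seeded shuffle, contiguous split),
#' rebuilds the spline basis on each training fold's ages, fits the BLR
#' normative model on the training folds, and scores the held-out fold.
#' Test ages outside the training range are clamped to the training boundary
#' (with a warning). Metrics are computed on the pooled out-of-fold
#' predictions; the trivial predictor for MSLL uses the pooled training-side
#' mean/variance of the observed feature.
#'
#' @param cohort A cohort `data.frame` with columns `subject_id`, `age`,
#'   `sex` and the feature.
#' @param feature Feature column name.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param n_interior_knots,degree Spline basis parameters.
#' @return List with `deviations` (data.frame: `subject_id`, `feature`, `z`,
#'   `fold`), `metrics` (from [fit_metrics()]), and `fits` (per-fold
#'   `normative_fit` objects).
#' @export
crossval_deviations <- function(cohort, feature, k = 10L, seed,
                                n_interior_knots = 3L, degree = 3L) {
  if (missing(seed)) stop("seed must be supplied")
  if (!feature %in% names(cohort)) stop(sprintf("feature '%s' not found", feature))
  y_all <- cohort[[feature]]
  n <- nrow(cohort)
  folds <- make_folds(n, k, seed)

  z <- numeric(n)
  mu <- numeric(n)
  vv <- numeric(n)
  fits <- vector("list", k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    te <- !tr
    basis <- build_spline_basis(cohort$age[tr], n_interior_knots, degree)
    Xtr <- build_design(cohort$age[tr], cohort$sex[tr], basis)
    Xte <- build_design(cohort$age[te], cohort$sex[te], basis, clamp = TRUE)
    fit <- fit_blr(Xtr, y_all[tr])
    pr <- predict(fit, Xte)
    z[te] <- deviation_z(y_all[te], pr$mean, pr$variance)
    mu[te] <- pr$mean
    vv[te] <- pr$variance
    fits[[fold]] <- fit
  }
  deviations <- data.frame(subject_id = cohort$subject_id,
                           feature = feature, z = z, fold = folds,
                           stringsAsFactors = FALSE)
  metrics <- fit_metrics(y_all, mu, vv)
  list(deviations = deviations, metrics = metrics, fits = fits)
}

#' Cross-validated deviations for several features
#'
#' @param cohort Cohort table.
#' @param features Character vector of feature columns.
#' @param ... Passed to [crossval_deviations()].
#' @return List with `deviations` (wide data.frame: `subject_id`, one
#'   `<feature>_dev` column per feature), `long` (stacked per-feature
#'   deviation tables) and `metrics` (data.frame, one row per feature).
#' @export
crossval_deviations_multi <- function(cohort, features, ...) {
  wide <- data.frame(subject_id = cohort$subject_id, stringsAsFactors = FALSE)
  long <- list()
  met <- list()
  for (f in features) {
    res <- crossval_deviations(cohort, f, ...)
    wide[[paste0(f, "_dev")]] <- res$deviations$z
    long[[f]] <- res$deviations
    met[[f]] <- data.frame(feature = f,
                           explained_variance = res$metrics$explained_variance,
                           smse = res$metrics$smse,
                           msll = res$metrics$msll,
                           rho = res$metrics$rho,
                           stringsAsFactors = FALSE)
  }
  list(deviations = wide,
       long = do.call(rbind, c(long, list(make.row.names = FALSE))),
       metrics = do.call(rbind, c(met, list(make.row.names = FALSE))))
}
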