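# Behavioral decomposition: the general cognitive factor (first principal
# component of the test battery) and the psychopathology domains
# (stability-resampled fixed-point ICA over the questionnaire items, plus
# the mean-weight general-psychopathology proxy).

#' General cognitive factor from a test battery
#'
#' Standardizes each test, extracts the first principal component, and
#' standardizes the scores. The sign is oriented so the mean loading is
#' positive (higher score = better performance when tests are scored
#' higher-is-better).
#'
#' @param tests Numeric matrix or data.frame, one column per test (no
#'   missing values, each column with nonzero variance, more rows than
#'   columns).
#' @return List of class `cognitive_factor`: `scores` (standardized, mean 0,
#'   SD 1), `loadings` (correlation of each test with the component),
#'   `variance_explained` (fraction of total standardized variance).
#' @export
cognitive_general_factor <- function(tests) {
  X <- as.matrix(tests)
  if (any(is.na(X))) stop("missing values in the test battery")
  n <- nrow(X)
  if (n <= ncol(X)) stop("need more subjects than tests")
  sds <- apply(X, 2, stats::sd)
  if (any(sds <= 0)) stop("constant test column")
  Xs <- scale(X)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  loadings <- drop(stats::cor(Xs, scores))
  if (mean(loadings) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  scores <- (scores - mean(scores)) / stats::sd(scores)
  structure(list(scores = scores,
                 loadings = stats::setNames(loadings, colnames(X)),
                 variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2)),
            class = "cognitive_factor")
}

# One symmetric fixed-point ICA run (tanh contrast) in whitened space.
# Z: n x q whitened data (unit covariance). Returns the final q x q
# orthonormal W (columns = source directions) together with the last
# update size `conv` (max |,|cos angle| - 1| across columns; < tol means
# the fixed point was reached).
fastica_run <- function(Z, tol = 1e-4, maxit = 200L) {
  q <- ncol(Z); n <- nrow(Z)
  W <- matrix(stats::rnorm(q * q), q)
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  conv <- Inf
  for (it in seq_len(maxit)) {
    WX <- Z %*% W                      # n x q source estimates
    G <- tanh(WX)
    Gp <- 1 - G^2
    W1 <- crossprod(Z, G) / n - W * matrix(colMeans(Gp), q, q, byrow = TRUE)
    W1 <- sym_decorrelate(W1)
    conv <- max(abs(abs(colSums(W1 * W)) - 1))
    W <- W1
    if (conv < tol) break
  }
  list(W = W, conv = conv, converged = conv < tol)
}

#' Stability-resampled ICA of questionnaire items
#'
#' Column-standardizes and whitens the item data (PCA reduction to
#' `n_components`), runs a symmetric fixed-point ICA with tanh nonlinearity
#' `n_runs` times from seeded random initializations — each run on a
#' bootstrap resample of the subjects, so only structure that is stable
#' under resampling reproduces — pools all estimated source directions,
#' clusters them by average-linkage agglomeration on `1 - |correlation|`,
#' and takes each cluster's centrotype (the member most similar to the rest
#' of its cluster) as the representative component.
#' The per-component stability index is the mean within-cluster similarity
#' minus the mean similarity to estimates outside the cluster; indices below
#' 0.5 trigger a warning (no reproducible non-Gaussian structure).
#'
#' Components are sign-oriented so the sum of the 10 largest-|loading| item
#' loadings is positive (higher weight = more symptoms) and ordered by
#' explained item variance, descending. Subject weights are the projections
#' of the standardized data onto the representative components.
#'
#' @param items Numeric matrix/data.frame of item scores (no missing
#'   values), subjects in rows.
#' @param n_components Number of components (default 7).
#' @param n_runs Number of randomized ICA runs to pool (default 20).
#' @param bootstrap Resample subjects with replacement per run (default
#'   `TRUE`); set `FALSE` to vary only the random initialization.
#' @param seed Integer seed.
#' @return List of class `domain_scores`: `weights` (n x n_components),
#'   `mixing` (items x components loading matrix), `general` (row mean of
#'   the weights), `stability` (per component, in [0, 1] up to sampling
#'   noise).
#' @export
ica_domains <- function(items, n_components = 7L, n_runs = 20L,
                        bootstrap = TRUE, seed) {
  if (missing(seed)) stop("seed must be supplied")
  X <- as.matrix(items)
  if (any(is.na(X))) stop("missing values in items")
  n <- nrow(X)
  if (n <= n_components) stop("need more subjects than components")
  if (n_runs < 1) stop("n_runs must be >= 1")
  sds <- apply(X, 2, stats::sd)
  if (any(sds <= 0)) stop("constant item column")
  Xs <- scale(X)

  # whiten: PCA reduction to n_components, unit variance
  sv <- svd(Xs, nu = 0, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  if (any(d < 1e-10)) stop("fewer informative dimensions than components")
  K <- sv$v %*% diag(sqrt(n - 1) / d, n_components)   # whitening matrix (p x q)
  Z <- Xs %*% K                                        # n x q, unit covariance

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  # Runs that reach the fixed point are pooled; runs that merely stall are
  # pooled too, since their scatter across resamples is exactly what the
  # stability index measures. Only runs still far from any fixed point are
  # dropped; all runs failing outright is an error.
  W_all <- list()
  n_conv <- 0L
  for (r in seq_len(n_runs)) {
    if (bootstrap) {
      # a resample is not white any more: re-center and re-whiten it, run
      # ICA there, then map the directions back to the common whitened space
      Zr <- Z[sample.int(n, n, replace = TRUE), , drop = FALSE]
      Zr <- sweep(Zr, 2, colMeans(Zr))
      Kr <- backsolve(chol(stats::cov(Zr)), diag(n_components))
      run <- fastica_run(Zr %*% Kr)
      V <- Kr %*% run$W
      V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
    } else {
      run <- fastica_run(Z)
      V <- run$W
    }
    if (run$converged) n_conv <- n_conv + 1L
    if (run$conv < 0.5) W_all[[length(W_all) + 1L]] <- V
  }
  if (!length(W_all)) stop("ICA failed to converge in all runs")
  if (n_conv == 0L)
    warning("no ICA run reached the fixed-point tolerance; estimates are stall points")
  est <- do.call(cbind, W_all)            # q x (runs*q) pooled directions
  if (ncol(est) < n_components)
    stop("fewer distinct estimates than components")

  # similarity of source estimates = |cosine| of whitened directions
  S <- abs(crossprod(est))
  S[S > 1] <- 1
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  cl <- stats::cutree(hc, k = n_components)

  reps <- matrix(NA_real_, nrow(est), n_components)
  stability <- numeric(n_components)
  for (j in seq_len(n_components)) {
    idx <- which(cl == j)
    Sj <- S[idx, idx, drop = FALSE]
    within <- if (length(idx) > 1)
      (rowSums(Sj) - 1) / (length(idx) - 1) else rep(1, 1)
    centro <- idx[which.max(within)]
    reps[, j] <- est[, centro]
    w_in <- if (length(idx) > 1) mean(Sj[upper.tri(Sj)]) else 1
    out_idx <- which(cl != j)
    w_out <- if (length(out_idx)) mean(S[idx, out_idx]) else 0
    stability[j] <- w_in - w_out
  }

  weights <- Z %*% reps                   # subject weights (projections)
  mixing <- crossprod(Xs, weights) / (n - 1)  # item loadings

  # sign orientation: top-10 |loading| items sum positive
  for (j in seq_len(n_components)) {
    top <- order(abs(mixing[, j]), decreasing = TRUE)[seq_len(min(10, nrow(mixing)))]
    if (sum(mixing[top, j]) < 0) {
      mixing[, j] <- -mixing[, j]
      weights[, j] <- -weights[, j]
      reps[, j] <- -reps[, j]
    }
  }

  # order by explained item variance, descending
  ord <- order(colSums(mixing^2), decreasing = TRUE)
  weights <- weights[, ord, drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  stability <- stability[ord]

  colnames(weights) <- colnames(mixing) <- sprintf("IC%d", seq_len(n_components))
  rownames(mixing) <- colnames(X)
  names(stability) <- colnames(weights)
  if (any(stability < 0.5))
    warning(sprintf("%d component(s) with stability below 0.5: weakly identifiable structure",
                    sum(stability < 0.5)))
  structure(list(weights = weights, mixing = mixing,
                 general = rowMeans(weights), stability = stability),
            class = "domain_scores")
}

#' General-psychopathology proxy
#'
#' Row-wise arithmetic mean of the 7 component weights.
#'
#' @param weights n x 7 matrix of domain weights.
#' @return Per-subject general score.
#' @export
general_psychopathology <- function(weights) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 7) stop("expected exactly 7 domain columns")
  rowMeans(weights)
}
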