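# Bayesian linear regression with isotropic Gaussian weight prior
# (precision alpha) and Gaussian noise (precision beta):
#   y = Phi w + e,  w ~ N(0, alpha^-1 I),  e ~ N(0, beta^-1 I).
# Hyperparameters are chosen by maximizing the log marginal likelihood
#   log p(y | alpha, beta)
# over (log alpha, log beta) with a Powell conjugate-direction search.
# All evidence/posterior algebra goes through one SVD of the design, so
# hyperparameter evaluations are O(p) each.

#' Powell conjugate-direction minimizer
#'
#' Derivative-free minimization: cycles of Brent line searches along a
#' direction set, replacing the direction of largest decrease with the net
#' cycle displacement. Suited to low-dimensional smooth objectives such as
#' the 2-D marginal-likelihood surface over (log alpha, log beta).
#'
#' @param fn Objective returning a scalar; minimized.
#' @param par Numeric start point.
#' @param lower,upper Box bounds on the parameters.
#' @param maxit Maximum cycles.
#' @param reltol Relative convergence tolerance on the objective.
#' @return List with `par`, `value`, `counts` (cycles used), `convergence`
#'   (0 if tolerance met).
#' @export
powell_optim <- function(fn, par, lower = rep(-20, length(par)),
                         upper = rep(20, length(par)),
                         maxit = 100L, reltol = 1e-9) {
  n <- length(par)
  par <- pmin(pmax(par, lower), upper)
  dirs <- diag(n)
  f <- fn(par)
  if (!is.finite(f)) stop("objective not finite at the start point")

  line_min <- function(p, d) {
    # feasible step interval along d within the box
    tlo <- -Inf; thi <- Inf
    for (i in seq_len(n)) {
      if (d[i] > 0) {
        tlo <- max(tlo, (lower[i] - p[i]) / d[i])
        thi <- min(thi, (upper[i] - p[i]) / d[i])
      } else if (d[i] < 0) {
        tlo <- max(tlo, (upper[i] - p[i]) / d[i])
        thi <- min(thi, (lower[i] - p[i]) / d[i])
      }
    }
    if (!is.finite(tlo) || !is.finite(thi) || thi <= tlo)
      return(list(t = 0, f = fn(p)))
    opt <- stats::optimize(function(t) fn(p + t * d), c(tlo, thi), tol = 1e-10)
    list(t = opt$minimum, f = opt$objective)
  }

  conv <- 1L
  for (it in seq_len(maxit)) {
    p0 <- par; f0 <- f
    biggest <- 0; ibig <- 1L
    for (i in seq_len(n)) {
      lm <- line_min(par, dirs[, i])
      if (f - lm$f > biggest) { biggest <- f - lm$f; ibig <- i }
      par <- par + lm$t * dirs[, i]
      f <- lm$f
    }
    if (2 * (f0 - f) <= reltol * (abs(f0) + abs(f)) + 1e-300) { conv <- 0L; break }
    dnew <- par - p0
    if (sqrt(sum(dnew^2)) > 1e-12) {
      lm <- line_min(par, dnew)
      if (lm$f < f) {
        par <- par + lm$t * dnew
        f <- lm$f
        dirs[, ibig] <- dnew / sqrt(sum(dnew^2))
      }
    }
  }
  list(par = par, value = f, counts = it, convergence = conv)
}

# Evidence and posterior in the SVD coordinates of the design.
# Returns a closure environment reused across hyperparameter evaluations.
blr_svd_state <- function(Phi, y) {
  sv <- svd(Phi)
  list(U = sv$u, d = sv$d, V = sv$v,
       c = sv$d * drop(crossprod(sv$u, y)),  # d_i * (u_i' y)
       uy = drop(crossprod(sv$u, y)),
       yy = sum(y^2), n = length(y), p = ncol(Phi))
}

blr_log_evidence_state <- function(st, alpha, beta) {
  a <- alpha + beta * st$d^2
  m <- beta * st$c / a                      # posterior mean, V-basis coords
  rss <- st$yy - 2 * sum(st$c * m) + sum(st$d^2 * m^2)
  E <- beta / 2 * rss + alpha / 2 * sum(m^2)
  st$p / 2 * log(alpha) + st$n / 2 * log(beta) - E -
    0.5 * sum(log(a)) - st$n / 2 * log(2 * pi)
}

#' Log marginal likelihood of the BLR model at fixed hyperparameters
#'
#' @param design Design matrix (n x p).
#' @param y Target vector.
#' @param alpha Prior precision on the weights.
#' @param beta Noise precision.
#' @return Log evidence `log p(y | alpha, beta)` in nats.
#' @export
blr_log_evidence <- function(design, y, alpha, beta) {
  stopifnot(alpha > 0, beta > 0, nrow(design) == length(y))
  blr_log_evidence_state(blr_svd_state(design, y), alpha, beta)
}

#' Fit a Bayesian linear regression by evidence maximization
#'
#' Maximizes the log marginal likelihood over (log alpha, log beta) with a
#' Powell search started at `(0, log(1/var(y)))`; on a non-finite result the
#' start is jittered and the search restarted (up to 3 times). The posterior
#' over weights at the optimum is Gaussian with mean
#' `beta * A^-1 Phi' y` and covariance `A^-1`, `A = alpha I + beta Phi'Phi`.
#'
#' @param design Design matrix with labeled columns (n x p, n >= p).
#' @param y Target vector with nonzero variance.
#' @param alpha,beta Optional fixed hyperparameters; when both are given the
#'   optimizer is skipped.
#' @return An object of class `normative_fit`: `weight_posterior_mean`,
#'   `weight_posterior_covariance`, `alpha`, `beta`, `log_evidence`,
#'   `log_evidence_start`, `columns`.
#' @export
fit_blr <- function(design, y, alpha = NULL, beta = NULL) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (n != length(y)) stop("design rows and y length differ")
  if (n < p) stop("need at least as many rows as design columns")
  if (any(!is.finite(design)) || any(!is.finite(y))) stop("non-finite inputs")
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) stop("y has zero variance")

  st <- blr_svd_state(design, y)
  neg_ev <- function(lp) -blr_log_evidence_state(st, exp(lp[1]), exp(lp[2]))

  if (!is.null(alpha) && !is.null(beta)) {
    stopifnot(alpha > 0, beta > 0)
    log_ev_start <- log_ev <- blr_log_evidence_state(st, alpha, beta)
  } else {
    start <- c(0, log(1 / vy))
    log_ev_start <- -neg_ev(start)
    opt <- NULL
    for (attempt in 0:3) {
      s <- if (attempt == 0) start else start + stats::rnorm(2, 0, attempt)
      s <- pmin(pmax(s, -20), 20)
      res <- tryCatch(powell_optim(neg_ev, s), error = function(e) NULL)
      if (!is.null(res) && is.finite(res$value) && all(is.finite(res$par))) {
        opt <- res
        break
      }
    }
    if (is.null(opt)) stop("hyperparameter optimization failed after restarts")
    alpha <- exp(opt$par[1]); beta <- exp(opt$par[2])
    log_ev <- -opt$value
  }

  a <- alpha + beta * st$d^2
  m_coord <- beta * st$c / a
  w_mean <- drop(st$V %*% m_coord)
  w_cov <- st$V %*% (t(st$V) / a)
  w_cov <- (w_cov + t(w_cov)) / 2
  names(w_mean) <- colnames(design)
  dimnames(w_cov) <- list(colnames(design), colnames(design))
  structure(list(weight_posterior_mean = w_mean,
                 weight_posterior_covariance = w_cov,
                 alpha = alpha, beta = beta,
                 log_evidence = log_ev,
                 log_evidence_start = log_ev_start,
                 columns = colnames(design),
                 n = n),
            class = "normative_fit")
}

#' Posterior predictive mean and variance
#'
#' @param object A `normative_fit`.
#' @param design New design matrix with the same column layout as used in
#'   fitting.
#' @param ... Unused.
#' @return List with `mean` and `variance` vectors; every variance is at
#'   least the noise floor `1/beta`.
#' @export
predict.normative_fit <- function(object, design, ...) {
  design <- as.matrix(design)
  if (nrow(design) == 0)
    return(list(mean = numeric(0), variance = numeric(0)))
  if (ncol(design) != length(object$weight_posterior_mean) ||
      (!is.null(colnames(design)) &&
       !identical(colnames(design), object$columns)))
    stop("design columns do not match the fitted layout")
  mu <- drop(design %*% object$weight_posterior_mean)
  qf <- rowSums((design %*% object$weight_posterior_covariance) * design)
  list(mean = mu, variance = 1 / object$beta + pmax(qf, 0))
}

#' Deviation Z-score
#'
#' `(observed - predicted mean) / predictive SD` — the subject-level
#' standardized departure from the normative prediction.
#'
#' @param observed Observed value(s).
#' @param pred_mean Predictive mean(s).
#' @param pred_var Predictive variance(s), all > 0.
#' @return Z-score(s).
#' @export
deviation_z <- function(observed, pred_mean, pred_var) {
  if (any(pred_var <= 0)) stop("predictive variance must be positive")
  (observed - pred_mean) / sqrt(pred_var)
}
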