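# Deviation-behavior association stage. For each (deviation score, behavioral
# domain) pair a Gaussian linear model
#   z = b0 + b_age * age_std + b_sex * sex + b_dom * domain_std + e
# is fitted with independent Normal priors on the coefficients (a proper
# Normal(0, prior_sd^2) on the tested domain coefficient — required for the
# Savage-Dickey ratio) and a half-Student-t(3, 0, 2.5) prior on the residual
# SD. Conditional on sigma the posterior over coefficients is Gaussian;
# sigma is marginalized numerically on a log-spaced grid, which also yields
# exact iid posterior draws (draw sigma from the grid weights, then
# coefficients from the conditional Gaussian). BF01 is the Savage-Dickey
# density ratio: posterior density of b_dom at 0 over its prior density at 0.

#' Pearson correlation matrix with significance stars
#'
#' @param deviations Numeric matrix/data.frame (complete cases), >= 2
#'   columns, each with nonzero variance, >= 3 rows.
#' @return List of class `correlation_matrix`: `labels`, `r`, `p` (two-sided
#'   t-test), `stars` (`***` p < .001, `**` p < .01, `*` p < .05).
#' @export
correlation_matrix <- function(deviations) {
  X <- as.matrix(deviations)
  n <- nrow(X); m <- ncol(X)
  if (m < 2) stop("need at least 2 columns")
  if (n < 3) stop("need at least 3 rows")
  if (any(is.na(X))) stop("complete cases only")
  if (any(apply(X, 2, stats::sd) <= 0)) stop("constant column")
  r <- stats::cor(X)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  stars <- matrix("", m, m, dimnames = dimnames(r))
  stars[p < 0.05] <- "*"
  stars[p < 0.01] <- "**"
  stars[p < 0.001] <- "***"
  diag(stars) <- ""
  structure(list(labels = colnames(X), r = r, p = p, stars = stars),
            class = "correlation_matrix")
}

#' Standardize predictors to mean 0, SD 1
#'
#' @param ... Numeric vectors with nonzero variance.
#' @return A list of standardized vectors (same names/order).
#' @export
standardize_predictors <- function(...) {
  vars <- list(...)
  lapply(vars, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) stop("constant predictor cannot be standardized")
    (x - mean(x)) / s
  })
}

# log density of the half-Student-t(df, 0, scale) prior on sigma
log_half_t <- function(sigma, df = 3, scale = 2.5) {
  stats::dt(sigma / scale, df = df, log = TRUE) - log(scale) + log(2)
}

#' Fit the Bayesian association linear model
#'
#' @param z Deviation-score outcome vector (may be length 0 for a prior-only
#'   run, in which case the posterior equals the prior).
#' @param age_std Standardized age.
#' @param sex Sex codes \{0,1\} (entered unstandardized).
#' @param domain_std Standardized domain score.
#' @param prior_sd Prior SD of the domain coefficient (default 1).
#' @param covariate_prior_sd Prior SD of intercept/age/sex coefficients
#'   (default 10).
#' @param sigma_grid_size Number of grid points for the residual-SD
#'   marginalization (default 400).
#' @return Object of class `association_model` with posterior summaries of
#'   the domain coefficient (`b_mean`, `b_sd`, `post_density0`), grid
#'   internals for sampling, and the coefficient layout.
#' @export
fit_bayesian_lm <- function(z, age_std, sex, domain_std, prior_sd = 1,
                            covariate_prior_sd = 10, sigma_grid_size = 400L) {
  prior <- c(intercept = covariate_prior_sd, age = covariate_prior_sd,
             sex = covariate_prior_sd, domain = prior_sd)
  if (!is.finite(prior_sd) || prior_sd <= 0)
    stop("the domain coefficient needs a proper prior (finite positive SD)")
  n <- length(z)
  if (n == 0) {
    # prior-only: posterior over b_dom is its prior
    return(structure(list(n = 0L, prior_sd = prior_sd,
                          b_mean = 0, b_sd = prior_sd,
                          post_density0 = stats::dnorm(0, 0, prior_sd),
                          grid = NULL, coef_names = names(prior)),
                     class = "association_model"))
  }
  if (length(age_std) != n || length(sex) != n || length(domain_std) != n)
    stop("input lengths differ")
  X <- cbind(intercept = 1, age = age_std, sex = sex, domain = domain_std)
  if (any(!is.finite(X)) || any(!is.finite(z))) stop("non-finite inputs")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient predictor set")

  p <- ncol(X)
  S_inv <- diag(1 / prior^2, p)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, z))
  yty <- sum(z^2)

  # residual-SD grid around the OLS residual scale
  ols <- stats::lm.fit(X, z)
  s_hat <- sqrt(max(sum(ols$residuals^2) / max(n - p, 1), 1e-12))
  sig <- exp(seq(log(s_hat / 6), log(s_hat * 6), length.out = sigma_grid_size))

  # log marginal p(y | sigma) via the p x p form of the Gaussian integral:
  # y ~ N(0, sigma^2 I + X S X'), with S the prior covariance.
  Shalf <- diag(prior, p)
  A0 <- Shalf %*% XtX %*% Shalf
  b0 <- drop(Shalf %*% Xty)
  logZ <- numeric(length(sig))
  m_dom <- v_dom <- numeric(length(sig))
  mean_list <- matrix(0, length(sig), p)
  chol_list <- vector("list", length(sig))
  for (i in seq_along(sig)) {
    s2 <- sig[i]^2
    M <- diag(p) + A0 / s2
    cM <- chol(M)
    # quadratic form y' (s2 I + XSX')^{-1} y = (yty - b0' M^{-1} b0 / s2) / s2
    Minv_b0 <- backsolve(cM, forwardsolve(t(cM), b0))
    quad <- (yty - sum(b0 * Minv_b0) / s2) / s2
    logdet <- n * log(s2) + 2 * sum(log(diag(cM)))
    logZ[i] <- -0.5 * (n * log(2 * pi) + logdet + quad)
    # conditional posterior over coefficients given sigma
    A <- XtX / s2 + S_inv
    cA <- chol(A)
    m <- backsolve(cA, forwardsolve(t(cA), Xty / s2))
    V <- chol2inv(cA)
    mean_list[i, ] <- m
    chol_list[[i]] <- chol(V)
    m_dom[i] <- m[p]
    v_dom[i] <- V[p, p]
  }
  lp <- logZ + log_half_t(sig)
  # trapezoid weights on the sigma scale
  dsig <- diff(sig)
  wts <- c(dsig[1] / 2, (dsig[-1] + dsig[-length(dsig)]) / 2,
           dsig[length(dsig)] / 2)
  lw <- lp + log(wts)
  lw <- lw - max(lw)
  w <- exp(lw); w <- w / sum(w)

  b_mean <- sum(w * m_dom)
  b_var <- sum(w * (v_dom + m_dom^2)) - b_mean^2
  post_density0 <- sum(w * stats::dnorm(0, m_dom, sqrt(v_dom)))
  sigma_mean <- sum(w * sig)

  structure(list(n = n, prior_sd = prior_sd,
                 b_mean = b_mean, b_sd = sqrt(max(b_var, 0)),
                 post_density0 = post_density0,
                 sigma_posterior_mean = sigma_mean,
                 grid = list(sigma = sig, w = w, m_dom = m_dom,
                             sd_dom = sqrt(v_dom), mean = mean_list,
                             chol = chol_list),
                 coef_names = colnames(X)),
            class = "association_model")
}

#' Posterior quantiles of the domain coefficient
#'
#' The marginal posterior of the domain coefficient is a mixture of normals
#' over the residual-SD grid; quantiles are found by root-solving the
#' mixture CDF.
#'
#' @param model An `association_model`.
#' @param probs Probabilities (default the 95% interval).
#' @return Named numeric vector of quantiles.
#' @export
posterior_quantiles <- function(model, probs = c(0.025, 0.975)) {
  if (is.null(model$grid)) {
    q <- stats::qnorm(probs, 0, model$prior_sd)
  } else {
    g <- model$grid
    cdf <- function(b) sum(g$w * stats::pnorm(b, g$m_dom, g$sd_dom))
    lo <- min(g$m_dom - 10 * g$sd_dom); hi <- max(g$m_dom + 10 * g$sd_dom)
    q <- vapply(probs, function(pr)
      stats::uniroot(function(b) cdf(b) - pr, c(lo, hi), tol = 1e-10)$root,
      numeric(1))
  }
  stats::setNames(q, sprintf("q%g", probs))
}

#' Exact posterior draws from the association model
#'
#' Samples the residual SD from its (gridded) marginal posterior, then the
#' coefficient vector from its conditional Gaussian — iid draws, no Markov
#' chain.
#'
#' @param model An `association_model`.
#' @param draws Number of draws (default 4000).
#' @param seed Integer seed.
#' @return Matrix of draws with columns `intercept`, `age`, `sex`, `domain`,
#'   `sigma`.
#' @export
sample_posterior <- function(model, draws = 4000L, seed) {
  if (missing(seed)) stop("seed must be supplied")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  p <- length(model$coef_names)
  if (is.null(model$grid)) {
    out <- cbind(matrix(stats::rnorm(draws * (p - 1), 0, 10), draws),
                 stats::rnorm(draws, 0, model$prior_sd),
                 NA_real_)
    colnames(out) <- c(model$coef_names, "sigma")
    return(out)
  }
  g <- model$grid
  idx <- sample.int(length(g$sigma), draws, replace = TRUE, prob = g$w)
  eps <- matrix(stats::rnorm(draws * p), draws)
  out <- matrix(NA_real_, draws, p + 1,
                dimnames = list(NULL, c(model$coef_names, "sigma")))
  for (i in unique(idx)) {
    rows <- which(idx == i)
    out[rows, seq_len(p)] <- matrix(g$mean[i, ], length(rows), p, byrow = TRUE) +
      eps[rows, , drop = FALSE] %*% g$chol[[i]]
  }
  out[, p + 1] <- g$sigma[idx]
  out
}

#' Savage-Dickey Bayes factor for the domain coefficient
#'
#' `BF01 = posterior density at 0 / prior density at 0`. The analytic path
#' evaluates the normal-mixture posterior density at zero; the sampling path
#' uses a Gaussian kernel density (Silverman bandwidth) on posterior draws.
#' BF01 > 1 favors the null (no association), < 1 the alternative.
#'
#' @param model An `association_model`.
#' @param method `"analytic"` (default) or `"sampling"`.
#' @param draws,seed Sampling-path settings (`draws` must be >= 1000).
#' @return BF01 (positive scalar).
#' @export
savage_dickey_bf <- function(model, method = c("analytic", "sampling"),
                             draws = 4000L, seed = 1L) {
  method <- match.arg(method)
  prior0 <- stats::dnorm(0, 0, model$prior_sd)
  if (method == "analytic") {
    post0 <- model$post_density0
  } else {
    if (draws < 1000) stop("need at least 1000 draws for a stable density estimate")
    b <- sample_posterior(model, draws, seed)[, "domain"]
    bw <- stats::bw.nrd0(b)
    post0 <- mean(stats::dnorm(0, b, bw))
  }
  # keep BF01 strictly positive when the posterior density at 0 underflows
  max(post0, .Machine$double.xmin) / prior0
}

#' Classify a Bayes factor into the evidence bands
#'
#' BF01 < 1 weighs toward the alternative: [0.3, 1) anecdotal, [0.1, 0.3)
#' moderate, [0.03, 0.1) strong, [0.01, 0.03) very strong, < 0.01 extreme.
#' BF01 > 1 weighs toward the null: (1, 3] anecdotal, (3, 10] moderate,
#' (10, 30] strong, (30, 100] very strong, > 100 extreme. BF01 = 1 is
#' evidence in either direction.
#'
#' @param bf01 Positive Bayes factor (null over alternative).
#' @return Character label, e.g. `"strong (alternative)"`.
#' @export
classify_bf <- function(bf01) {
  if (!is.finite(bf01) || bf01 <= 0) stop("BF01 must be positive")
  if (bf01 == 1) return("evidence in either direction")
  if (bf01 < 1) {
    lab <- if (bf01 >= 0.3) "anecdotal" else if (bf01 >= 0.1) "moderate"
      else if (bf01 >= 0.03) "strong" else if (bf01 >= 0.01) "very strong"
      else "extreme"
    return(paste0(lab, " (alternative)"))
  }
  lab <- if (bf01 <= 3) "anecdotal" else if (bf01 <= 10) "moderate"
    else if (bf01 <= 30) "strong" else if (bf01 <= 100) "very strong"
    else "extreme"
  paste0(lab, " (null)")
}

#' Association grid over deviations and behavioral scores
#'
#' One Bayesian linear model per (brain deviation feature x behavioral
#' predictor) pair, where the predictors are the 7 ICA domain weights, the
#' general-psychopathology proxy, and the cognitive deviation score. Each
#' model standardizes its own domain predictor and age; sex enters as the
#' raw \{0,1\} code.
#'
#' @param deviations data.frame of deviation scores (columns `<feature>_dev`).
#' @param domains n x 7 matrix of ICA weights.
#' @param general Per-subject general-psychopathology score.
#' @param cog_dev Cognitive deviation score.
#' @param age,sex Covariates.
#' @param prior_sd Prior SD of the domain coefficient.
#' @param seed Integer seed (for the sampling cross-check path; the reported
#'   values come from the analytic path and are deterministic).
#' @return data.frame, sorted by feature then domain: `feature`, `domain`,
#'   `B`, `ci_low`, `ci_high`, `BF01`, `label`, `direction`.
#' @export
run_association_grid <- function(deviations, domains, general, cog_dev,
                                 age, sex, prior_sd = 1, seed = 1L) {
  dev_cols <- grep("_dev$", names(deviations), value = TRUE)
  n <- nrow(deviations)
  stopifnot(nrow(as.matrix(domains)) == n, length(general) == n,
            length(cog_dev) == n, length(age) == n, length(sex) == n)
  preds <- c(as.list(as.data.frame(as.matrix(domains))),
             list(general = general, COG_dev = cog_dev))
  age_std <- standardize_predictors(age = age)$age
  rows <- list()
  for (f in dev_cols) {
    z <- deviations[[f]]
    for (d in names(preds)) {
      dom_std <- standardize_predictors(x = preds[[d]])$x
      model <- fit_bayesian_lm(z, age_std, sex, dom_std, prior_sd = prior_sd)
      bf <- savage_dickey_bf(model)
      ci <- posterior_quantiles(model)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, domain = d, B = model$b_mean,
        ci_low = ci[1], ci_high = ci[2], BF01 = bf,
        label = classify_bf(bf),
        direction = ifelse(model$b_mean >= 0, "positive", "negative"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$feature, out$domain), , drop = FALSE]
}
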