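#' @name taxon-glm
#' @title Per-taxon count GLMs
#' @description
#' Maximum-likelihood fits of a single taxon's counts under four families
#' with a log link and a log-size-factor offset: Poisson, negative binomial
#' (NB2), zero-inflated negative binomial (intercept-only inflation) and
#' hurdle (binomial zero part sharing the count-part design + zero-truncated
#' NB count part, offset in the count part). The ZINB and truncated-NB
#' likelihoods are maximized with analytic gradients. Each fit records its
#' log-likelihood, parameter count and `BIC = -2 loglik + k log(n)`;
#' non-converged fits are flagged and excluded from family selection.
NULL

glm_families <- c("poisson", "nb", "zinb", "hurdle")

mc_fit <- function(family, coef, se, loglik, n_params, n, converged,
                   note = "", extra = list()) {
  structure(list(family = family, coef = coef, se = se, loglik = loglik,
                 n_params = n_params, n = n,
                 bic = -2 * loglik + n_params * log(n),
                 converged = converged, note = note, extra = extra),
            class = "mc_glm_fit")
}

failed_fit <- function(family, n, note) {
  structure(list(family = family, coef = NULL, se = NULL, loglik = -Inf,
                 n_params = NA_integer_, n = n, bic = Inf, converged = FALSE,
                 note = note, extra = list()), class = "mc_glm_fit")
}

# NB2 log density pieces used by the hand-rolled likelihoods -------------

nb_dlogf_deta <- function(y, mu, theta) y - mu * (y + theta) / (mu + theta)
nb_dlogf_dtheta <- function(y, mu, theta)
  digamma(y + theta) - digamma(theta) + log(theta) + 1 -
    log(theta + mu) - (y + theta) / (theta + mu)
nb_logf0 <- function(mu, theta) theta * (log(theta) - log(theta + mu))
nb_dlogf0_deta <- function(mu, theta) -theta * mu / (theta + mu)
nb_dlogf0_dtheta <- function(mu, theta)
  log(theta) - log(theta + mu) + mu / (theta + mu)

fit_poisson <- function(y, X, offset) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, offset = offset,
                                    family = stats::poisson())),
    error = function(e) NULL)
  if (is.null(fit)) return(failed_fit("poisson", length(y), "glm.fit error"))
  mu <- fit$fitted.values
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  vc <- tryCatch(solve(crossprod(X, X * mu)), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, ncol(X)) else sqrt(diag(vc))
  mc_fit("poisson", stats::setNames(fit$coefficients, colnames(X)),
         stats::setNames(se, colnames(X)), ll, ncol(X), length(y),
         converged = fit$converged)
}

fit_nb <- function(y, X, offset) {
  env <- new.env()
  env$y <- y; env$X <- X; env$off <- offset
  warned <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(y ~ 0 + X + offset(off), data = env,
                   control = stats::glm.control(maxit = 50)),
      warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") }),
    error = function(e) NULL)
  if (is.null(fit)) return(failed_fit("nb", length(y), "glm.nb error"))
  cf <- stats::setNames(stats::coef(fit), colnames(X))
  se <- tryCatch(stats::setNames(sqrt(diag(stats::vcov(fit))), colnames(X)),
                 error = function(e) stats::setNames(rep(NA_real_, ncol(X)),
                                                     colnames(X)))
  ll <- as.numeric(stats::logLik(fit))   # includes theta as a parameter
  mc_fit("nb", cf, se, ll, ncol(X) + 1L, length(y),
         converged = isTRUE(fit$converged),
         note = if (warned) "glm.nb warning (theta at boundary?)" else "",
         extra = list(theta = fit$theta))
}

zinb_nll <- function(par, y, X, offset) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)]) + offset
  theta <- exp(par[p + 1L])
  pi0 <- stats::plogis(par[p + 2L])
  mu <- exp(eta)
  is0 <- y == 0
  ll <- numeric(length(y))
  ll[!is0] <- log1p(-pi0) +
    stats::dnbinom(y[!is0], mu = mu[!is0], size = theta, log = TRUE)
  l0 <- nb_logf0(mu[is0], theta)
  ll[is0] <- log(pi0 + exp(log1p(-pi0) + l0))
  -sum(ll)
}

zinb_grad <- function(par, y, X, offset) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)]) + offset
  theta <- exp(par[p + 1L])
  w <- par[p + 2L]
  pi0 <- stats::plogis(w)
  mu <- exp(eta)
  is0 <- y == 0
  deta <- numeric(length(y)); dtheta <- numeric(length(y)); dw <- numeric(length(y))
  # positive counts
  yp <- y[!is0]; mup <- mu[!is0]
  deta[!is0] <- nb_dlogf_deta(yp, mup, theta)
  dtheta[!is0] <- nb_dlogf_dtheta(yp, mup, theta)
  dw[!is0] <- -pi0
  # zeros: L = pi0 + (1 - pi0) f0
  mu0 <- mu[is0]
  f0 <- exp(nb_logf0(mu0, theta))
  L <- pi0 + (1 - pi0) * f0
  deta[is0] <- (1 - pi0) * f0 * nb_dlogf0_deta(mu0, theta) / L
  dtheta[is0] <- (1 - pi0) * f0 * nb_dlogf0_dtheta(mu0, theta) / L
  dw[is0] <- (1 - f0) * pi0 * (1 - pi0) / L
  -c(drop(crossprod(X, deta)), theta * sum(dtheta), sum(dw))
}

fit_zinb <- function(y, X, offset) {
  p <- ncol(X)
  start_fit <- fit_nb(y, X, offset)
  beta0 <- if (!is.null(start_fit$coef) && all(is.finite(start_fit$coef)))
    start_fit$coef else rep(0, p)
  theta0 <- start_fit$extra$theta %||% 1
  if (!is.finite(theta0) || theta0 <= 0) theta0 <- 1
  pi_start <- min(max(mean(y == 0) / 2, 0.02), 0.45)
  par0 <- c(beta0, log(min(theta0, 50)), stats::qlogis(pi_start))
  opt <- tryCatch(
    stats::nlminb(par0, zinb_nll, gradient = zinb_grad, y = y, X = X,
                  offset = offset,
                  lower = c(rep(-30, p), -8, -8), upper = c(rep(30, p), 8, 8),
                  control = list(iter.max = 300, eval.max = 400)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective))
    return(failed_fit("zinb", length(y), "zinb optimization failed"))
  cf <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  hess <- tryCatch(stats::optimHess(opt$par, zinb_nll, zinb_grad, y = y,
                                    X = X, offset = offset),
                   error = function(e) NULL)
  se <- rep(NA_real_, p)
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc)[seq_len(p)] > 0))
      se <- sqrt(diag(vc)[seq_len(p)])
  }
  mc_fit("zinb", cf, stats::setNames(se, colnames(X)), -opt$objective,
         p + 2L, length(y), converged = opt$convergence == 0,
         extra = list(theta = exp(opt$par[p + 1L]),
                      pi = stats::plogis(opt$par[p + 2L])))
}

ztnb_nll <- function(par, y, X, offset) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)]) + offset
  theta <- exp(par[p + 1L])
  mu <- exp(eta)
  l0 <- nb_logf0(mu, theta)
  ll <- stats::dnbinom(y, mu = mu, size = theta, log = TRUE) -
    log1p(-pmin(exp(l0), 1 - 1e-12))
  -sum(ll)
}

ztnb_grad <- function(par, y, X, offset) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)]) + offset
  theta <- exp(par[p + 1L])
  mu <- exp(eta)
  f0 <- pmin(exp(nb_logf0(mu, theta)), 1 - 1e-12)
  adj <- f0 / (1 - f0)
  deta <- nb_dlogf_deta(y, mu, theta) + adj * nb_dlogf0_deta(mu, theta)
  dtheta <- nb_dlogf_dtheta(y, mu, theta) + adj * nb_dlogf0_dtheta(mu, theta)
  -c(drop(crossprod(X, deta)), theta * sum(dtheta))
}

fit_hurdle <- function(y, X, offset) {
  n <- length(y)
  z <- as.integer(y > 0)
  if (all(z == 1L) || all(z == 0L))
    return(failed_fit("hurdle", n, "degenerate zero part (all zero or all positive)"))
  separated <- FALSE
  bin <- tryCatch(
    withCallingHandlers(
      stats::glm.fit(X, z, family = stats::binomial()),
      warning = function(w) { separated <<- TRUE; invokeRestart("muffleWarning") }),
    error = function(e) NULL)
  if (is.null(bin)) return(failed_fit("hurdle", n, "zero-part fit failed"))
  pz <- bin$fitted.values
  ll_bin <- sum(z * log(pmax(pz, 1e-12)) + (1 - z) * log(pmax(1 - pz, 1e-12)))

  pos <- y > 0
  yp <- y[pos]; Xp <- X[pos, , drop = FALSE]; offp <- offset[pos]
  p <- ncol(X)
  if (sum(pos) < p + 2L)
    return(failed_fit("hurdle", n, "too few positive counts for the count part"))
  start_fit <- fit_nb(yp, Xp, offp)
  beta0 <- if (!is.null(start_fit$coef) && all(is.finite(start_fit$coef)))
    start_fit$coef else rep(0, p)
  theta0 <- start_fit$extra$theta %||% 1
  if (!is.finite(theta0) || theta0 <= 0) theta0 <- 1
  opt <- tryCatch(
    stats::nlminb(c(beta0, log(min(theta0, 50))), ztnb_nll,
                  gradient = ztnb_grad, y = yp, X = Xp, offset = offp,
                  lower = c(rep(-30, p), -8), upper = c(rep(30, p), 8),
                  control = list(iter.max = 300, eval.max = 400)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective))
    return(failed_fit("hurdle", n, "count-part optimization failed"))
  cf <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  mc_fit("hurdle", cf, stats::setNames(rep(NA_real_, p), colnames(X)),
         ll_bin - opt$objective, 2L * p + 1L, n,
         converged = opt$convergence == 0 && bin$converged,
         note = if (separated) "possible separation in zero part" else "",
         extra = list(theta = exp(opt$par[p + 1L]),
                      zero_coef = stats::setNames(bin$coefficients, colnames(X)),
                      ll_zero = ll_bin, ll_count = -opt$objective))
}

#' Fit one taxon's counts under a chosen family
#'
#' @param y non-negative integer count vector.
#' @param X design matrix (full column rank after dummy coding).
#' @param offset per-sample offset, usually `log(size factors)`.
#' @param family one of `"poisson"`, `"nb"`, `"zinb"`, `"hurdle"`.
#' @return an `mc_glm_fit`: coefficients, log-likelihood, parameter count,
#'   BIC, convergence flag. Non-convergence is flagged, not thrown.
#' @export
fit_taxon_glm <- function(y, X, offset = rep(0, length(y)),
                          family = c("poisson", "nb", "zinb", "hurdle")) {
  family <- match.arg(family)
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    abort_mc("counts must be non-negative integers", "mc_validation_error")
  if (all(y == 0))
    abort_mc("all-zero response; taxon should have been prevalence-filtered",
             "mc_validation_error")
  if (qr(X)$rank < ncol(X))
    abort_mc("design matrix is rank deficient", "mc_validation_error")
  switch(family,
         poisson = fit_poisson(y, X, offset),
         nb = fit_nb(y, X, offset),
         zinb = fit_zinb(y, X, offset),
         hurdle = fit_hurdle(y, X, offset))
}

#' Select the count family by BIC on the full model
#'
#' Fits every candidate family on the full design and returns the converged
#' family with the lowest BIC; ties (within 1e-9) go to the simplest family
#' in the fixed order poisson < nb < zinb < hurdle. The selected family is
#' then reused for the nested comparison of the same taxon.
#'
#' @inheritParams fit_taxon_glm
#' @param families candidate families, in precedence order.
#' @return list: `family` (name), `fit` (the winning fit), `fits` (all).
#' @export
select_distribution <- function(y, X, offset = rep(0, length(y)),
                                families = glm_families) {
  fits <- lapply(families, function(f) fit_taxon_glm(y, X, offset, f))
  names(fits) <- families
  ok <- vapply(fits, function(f) f$converged && is.finite(f$bic), logical(1L))
  if (!any(ok))
    abort_mc("no count family converged for this taxon", "mc_fit_error")
  bics <- vapply(fits, function(f) f$bic, numeric(1L))
  bics[!ok] <- Inf
  best <- which(bics <= min(bics) + 1e-9)[1L]   # precedence = list order
  list(family = families[best], fit = fits[[best]], fits = fits)
}

#' Likelihood-ratio test of nested fits
#'
#' `2 (loglik_full - loglik_reduced)` clipped at zero, chi-squared p-value
#' on the parameter-count difference.
#'
#' @param full,reduced `mc_glm_fit` objects of the same family on the same
#'   data, reduced nested in full.
#' @return c(statistic, df, p).
#' @export
lrt_compare <- function(full, reduced) {
  if (full$family != reduced$family)
    abort_mc("LRT requires the same family for both fits", "mc_validation_error")
  if (full$n != reduced$n)
    abort_mc("LRT requires fits on the same data", "mc_validation_error")
  df <- full$n_params - reduced$n_params
  if (df < 0)
    abort_mc("models are not nested (reduced has more parameters)",
             "mc_validation_error")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  c(statistic = stat, df = df, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone in rank order and capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    abort_mc("p-values must lie in [0, 1]", "mc_validation_error")
  stats::p.adjust(pvals, method = "BH")
}
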