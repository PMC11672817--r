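#' Gibbs chain configuration
#'
#' Desk-scale defaults (20,000 iterations, 4,000 burn-in, thinning 10) keep
#' a full fit fast while leaving ~1,600 stored draws; production-scale runs
#' (e.g. 500,000 / 100,000 / 50) are configured the same way.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in burn-in iterations discarded before storage.
#' @param thin thinning interval for stored draws.
#' @param seed optional integer seed; when non-`NULL` the sampler is
#'   bit-reproducible.
#' @return list of class `chain_config`.
#' @export
chain_config <- function(n_iter = 20000L, burn_in = 4000L, thin = 10L,
                         seed = NULL) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (burn_in < 0L || thin < 1L) stop("burn_in must be >= 0 and thin >= 1")
  if ((n_iter - burn_in) %/% thin < 1L)
    stop("no draws would be stored; increase n_iter or reduce thin")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "chain_config")
}

#' Variance priors for the Gibbs sampler
#'
#' Scaled inverse chi-square priors `(nu, S)` per component; the defaults
#' `nu = -2, S = 0` are flat on the variances (the full-conditional degrees
#' of freedom become `n - 2`), matching common animal-breeding practice.
#' For the bivariate threshold model `nu_u` and `nu_pe` are the
#' inverse-Wishart prior degrees of freedom added to the posterior
#' (default -3 = flat for a 2x2 matrix, zero scale).
#'
#' @param nu_u,s_u prior for the additive genetic variance.
#' @param nu_pe,s_pe prior for the permanent-environment variance.
#' @param nu_e,s_e prior for the residual variance.
#' @return list of class `variance_priors`.
#' @export
variance_priors <- function(nu_u = -2, s_u = 0, nu_pe = -2, s_pe = 0,
                            nu_e = -2, s_e = 0) {
  structure(list(nu_u = nu_u, s_u = s_u, nu_pe = nu_pe, s_pe = s_pe,
                 nu_e = nu_e, s_e = s_e), class = "variance_priors")
}

csc <- function(m) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  list(i = m@i, p = m@p, x = m@x)
}

#' Gibbs sampler for the Gaussian repeatability animal model
#'
#' Single-site Gibbs updates of all location effects followed by scaled
#' inverse chi-square draws of the three variance components. With
#' `fix_variances` the variances are held at the supplied values
#' (degenerate priors), in which case the chain's stationary distribution
#' is centred exactly on the mixed-model-equation solutions of
#' [solve_mme()].
#'
#' @param design a [build_design()] object.
#' @param ainv sparse A-inverse from [build_A_inverse()].
#' @param config a [chain_config()].
#' @param priors a [variance_priors()].
#' @param start optional [variance_components()] starting values; defaults
#'   to a 20/20/60 split of the phenotypic variance.
#' @param fix_variances optional [variance_components()]; when supplied the
#'   variances are never updated.
#' @param store_effects store the thinned draws of every location effect
#'   (memory grows with `n_store * (nf + n_u + n_pe)`).
#' @return a `posterior_chain` with elements `draws` (matrix with columns
#'   `sigma_u2`, `sigma_pe2`, `sigma_e2`, `h2`), `effects` (posterior mean
#'   and SD per effect), `effect_draws` (if requested), and `config`.
#' @export
gibbs_gaussian <- function(design, ainv, config = chain_config(),
                           priors = variance_priors(), start = NULL,
                           fix_variances = NULL, store_effects = FALSE) {
  stopifnot(inherits(design, "do_design"), inherits(config, "chain_config"))
  fixed <- !is.null(fix_variances)
  if (fixed) stopifnot(inherits(fix_variances, "variance_components"))
  if (!fixed) {
    for (blk in list(c(design$n_u, priors$nu_u, "additive"),
                     c(design$n_pe, priors$nu_pe, "permanent-environment"),
                     c(length(design$y), priors$nu_e, "residual"))) {
      if (as.numeric(blk[1]) + as.numeric(blk[2]) < 1)
        stop("too few levels to sample the ", blk[3],
             " variance under this prior; use fix_variances or a proper prior")
    }
  }
  init <- if (fixed) fix_variances
          else if (!is.null(start)) start
          else {
            vy <- stats::var(design$y)
            variance_components(0.2 * vy, 0.2 * vy, 0.6 * vy)
          }
  if (!is.null(config$seed)) set.seed(config$seed)
  M <- csc(Matrix::crossprod(design$W))
  Wt <- csc(Matrix::t(design$W))
  A <- csc(ainv)
  res <- gibbs_univariate_cpp(
    M$i, M$p, M$x, Wt$i, Wt$p, Wt$x, A$i, A$p, A$x,
    design$y, design$nf, design$n_u, design$n_pe,
    c(init$sigma_u2, init$sigma_pe2, init$sigma_e2),
    c(priors$nu_u, priors$nu_pe, priors$nu_e),
    c(priors$s_u, priors$s_pe, priors$s_e),
    config$n_iter, config$burn_in, config$thin,
    fixed, store_effects)
  colnames(res$draws) <- c("sigma_u2", "sigma_pe2", "sigma_e2", "h2")
  labels <- c(design$fixed_labels, design$animal_labels,
              design$animal_labels[design$pe_animal])
  effects <- data.frame(
    type = rep(c("fixed", "u", "pe"), c(design$nf, design$n_u, design$n_pe)),
    label = labels, mean = res$effect_mean, sd = res$effect_sd,
    stringsAsFactors = FALSE)
  if (store_effects) colnames(res$effect_draws) <- labels
  structure(list(draws = res$draws, effects = effects,
                 effect_draws = if (store_effects) res$effect_draws,
                 config = config, model = "gaussian"),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("Posterior chain (", x$model, " model): ", nrow(x$draws),
      " stored draws of ", ncol(x$draws), " parameters\n", sep = "")
  print(round(posterior_summary(x), 4))
  invisible(x)
}

#' Posterior summary of a chain
#'
#' @param chain a `posterior_chain`.
#' @return matrix with posterior mean, SD, 2.5% and 97.5% quantiles, Geweke
#'   z and lag-1 autocorrelation per stored parameter.
#' @export
posterior_summary <- function(chain) {
  d <- chain$draws
  t(apply(d, 2, function(v) {
    c(mean = mean(v), sd = stats::sd(v),
      q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)),
      geweke_z = geweke_z(v),
      lag1_autocorr = autocorrelation(v, 1L)[2L])
  }))
}

#' @export
summary.posterior_chain <- function(object, ...) posterior_summary(object)

#' Trace plot of a stored parameter
#'
#' @param x a `posterior_chain`.
#' @param param column name of `x$draws`.
#' @param ... passed to [plot()].
#' @export
plot.posterior_chain <- function(x, param = "h2", ...) {
  v <- x$draws[, param]
  plot(v, type = "l", xlab = "stored draw", ylab = param, ...)
  invisible(x)
}

#' Draw censorship liabilities
#'
#' Samples from the normal full conditional of a liability truncated by its
#' observed binary state against the threshold 0: strictly positive when
#' the record is censored (`status = 1`), non-positive otherwise. The
#' sampler is stable for arbitrarily extreme means (tail draws use a
#' translated-exponential rejection scheme rather than the inverse CDF).
#'
#' @param status binary censorship status (0/1), recycled against `mean`.
#' @param mean full-conditional mean of the liability.
#' @param sd full-conditional standard deviation.
#' @return numeric vector of liability draws.
#' @export
sample_liability <- function(status, mean, sd = 1) {
  n <- max(length(status), length(mean), length(sd))
  status <- as.integer(rep_len(status, n))
  if (!all(status %in% c(0L, 1L))) stop("status must be 0 or 1")
  rtnorm_sign_cpp(status, rep_len(as.numeric(mean), n),
                  rep_len(as.numeric(sd), n))
}

# spectral density at frequency zero, AR-model based (for Geweke and MCSE)
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(20L, floor(length(x) / 5))),
    error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (length(fit$ar) == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Monte Carlo standard error of a chain mean
#'
#' `sqrt(s0 / n)` with `s0` the AR-based estimate of the spectral density
#' at frequency zero, accounting for autocorrelation of the draws.
#'
#' @param x numeric vector of draws.
#' @return scalar MCSE.
#' @export
mcse <- function(x) sqrt(spectrum0_ar(x) / length(x))

#' Geweke convergence diagnostic
#'
#' z-score comparing the mean of the first `frac1` of the chain with the
#' mean of the last `frac2`, using AR-based spectral-density estimates of
#' the two segment variances. A constant chain returns 0 by convention.
#'
#' @param x numeric vector of stored draws (at least 100).
#' @param frac1 fraction of the chain in the early window.
#' @param frac2 fraction in the late window.
#' @return scalar z-score.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100L) stop("need at least 100 draws for the Geweke diagnostic")
  if (stats::var(x) == 0) return(0)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  denom <- spectrum0_ar(a) / length(a) + spectrum0_ar(b) / length(b)
  if (denom <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(denom)
}

#' Sample autocorrelation function
#'
#' @param x numeric vector of draws (length at least `2 * max_lag`).
#' @param max_lag largest lag.
#' @return numeric vector of autocorrelations at lags `0..max_lag`
#'   (lag 0 is exactly 1).
#' @export
autocorrelation <- function(x, max_lag) {
  x <- as.numeric(x)
  if (length(x) < 2L * max_lag) stop("chain too short for max_lag")
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  names(ac) <- 0:max_lag
  ac
}
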