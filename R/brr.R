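#' Default scaled-inverse-chi-squared hyperparameters
#'
#' Reproduces the reference default rule for Bayesian ridge regression
#' priors: degrees of freedom nu_beta = nu_E = 5, and scales chosen so the
#' prior modes partition the phenotypic variance according to `R2_prior`
#' (the a-priori share of variance explained by markers):
#' tau_E = Var(y) (1 - R2)(nu_E + 2) and
#' tau_beta = Var(y) R2 / sum_j Var(x_j) * (nu_beta + 2), where the scale is
#' parameterized as a prior sum of squares so that the prior mode of a
#' Scale-inv-chi2(nu, tau) variance is tau / (nu + 2).
#'
#' @param y phenotype vector.
#' @param X marker matrix (no intercept column).
#' @param R2_prior prior proportion of variance explained by markers,
#'   default 0.5.
#' @param nu degrees of freedom for both priors, default 5.
#' @return list of class `brr_prior`: `nu_beta`, `tau_beta`, `nu_E`,
#'   `tau_E`, `R2_prior`.
#' @export
default_hyperparameters <- function(y, X, R2_prior = 0.5, nu = 5) {
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) stop("Var(y) must be positive")
  if (R2_prior <= 0 || R2_prior >= 1)
    stop("R2_prior must lie strictly between 0 and 1")
  sum_vx <- sum(apply(X, 2, var))
  if (sum_vx <= 0) stop("X has no variable columns")
  out <- list(nu_beta = nu,
              tau_beta = vy * R2_prior / sum_vx * (nu + 2),
              nu_E = nu,
              tau_E = vy * (1 - R2_prior) * (nu + 2),
              R2_prior = R2_prior)
  class(out) <- "brr_prior"
  out
}

#' Bayesian ridge regression by Gibbs sampling
#'
#' Fits y = b0 + X beta + e with beta_j ~ N(0, sigma2_beta) and
#' scaled-inverse-chi-squared priors on both variances, by single-site Gibbs
#' updates over markers (the intercept is carried as an unpenalized column).
#' Default chain settings keep one post-burn-in draw in five:
#' (20000 - 5000) / 5 = 3000 retained samples.
#'
#' @param y phenotype vector.
#' @param X marker matrix (individuals x markers), dosages 0/1/2; columns
#'   are used as supplied (no centering) unless `center = TRUE`.
#' @param n_iter,burn_in,thin chain settings.
#' @param prior list from [default_hyperparameters()]; computed from the
#'   data when NULL.
#' @param seed optional integer seed (chains are bit-reproducible for a
#'   fixed seed).
#' @param center center the marker columns before sampling (off by default;
#'   recorded in the metadata).
#' @param fix_sigma2_beta,fix_sigma2_e optional positive values freezing a
#'   variance at a known value instead of sampling it (used for
#'   conjugate-posterior checks).
#' @return object of class `brr_fit`: `samples` (S x (M+1), intercept
#'   first), `posterior_mean` (named, intercept + effects),
#'   `sigma2_beta_draws`, `sigma2_e_draws`, `prior`, `meta`.
#' @export
fit_brr <- function(y, X, n_iter = 20000, burn_in = 5000, thin = 5,
                    prior = NULL, seed = NULL, center = FALSE,
                    fix_sigma2_beta = NULL, fix_sigma2_e = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  if (anyNA(y) || anyNA(X)) stop("NA/NaN in y or X")
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if ((n_iter - burn_in) %% thin != 0)
    stop("(n_iter - burn_in) must be a multiple of thin")
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  if (is.null(prior)) prior <- default_hyperparameters(y, X)
  Xd <- cbind(`(Intercept)` = 1, X)
  pen <- c(FALSE, rep(TRUE, ncol(X)))
  res <- brr_gibbs_cpp(as.numeric(y), Xd, pen,
                       prior$nu_beta, prior$tau_beta,
                       prior$nu_E, prior$tau_E,
                       as.integer(n_iter), as.integer(burn_in),
                       as.integer(thin),
                       if (is.null(fix_sigma2_beta)) -1 else fix_sigma2_beta,
                       if (is.null(fix_sigma2_e)) -1 else fix_sigma2_e)
  colnames(res$samples) <- colnames(Xd)
  out <- list(samples = res$samples,
              posterior_mean = colMeans(res$samples),
              sigma2_beta_draws = res$sigma2_beta,
              sigma2_e_draws = res$sigma2_e,
              prior = prior,
              meta = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                          n_samples = nrow(res$samples), seed = seed,
                          centered = center,
                          update_scheme = "single-site Gibbs",
                          fixed_sigma2_beta = fix_sigma2_beta,
                          fixed_sigma2_e = fix_sigma2_e))
  class(out) <- "brr_fit"
  out
}

#' @export
print.brr_fit <- function(x, ...) {
  cat(sprintf("brr_fit: %d retained samples, %d markers (+ intercept)\n",
              x$meta$n_samples, ncol(x$samples) - 1L))
  cat(sprintf("posterior mean sigma2_E = %.4g, sigma2_beta = %.4g\n",
              mean(x$sigma2_e_draws), mean(x$sigma2_beta_draws)))
  invisible(x)
}

#' Marker-effect posterior means (without intercept)
#'
#' @param fit a `brr_fit`.
#' @return named numeric vector of M posterior-mean marker effects.
#' @export
marker_effects <- function(fit) {
  stopifnot(inherits(fit, "brr_fit"))
  fit$posterior_mean[-1]
}

#' Marker-effect posterior samples (without intercept)
#'
#' @param fit a `brr_fit`.
#' @return S x M matrix of thinned post-burn-in draws.
#' @export
effect_samples <- function(fit) {
  stopifnot(inherits(fit, "brr_fit"))
  fit$samples[, -1, drop = FALSE]
}
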