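#' Predicted mean of a BC1S2 cross
#'
#' After one backcross to the recipient, progeny carry on expectation 3/4 of
#' the recipient genome and 1/4 of the donor genome, so
#' mu = 3/4 x_R' beta + 1/4 x_D' beta (+ intercept, added once).
#'
#' @param x_R,x_D parental genotype vectors coded 0/2.
#' @param beta_hat marker effects (posterior means), no intercept.
#' @param intercept scalar added once, default 0.
#' @return scalar predicted mean.
#' @export
predict_cross_mean <- function(x_R, x_D, beta_hat, intercept = 0) {
  .check_parental(x_R); .check_parental(x_D)
  stopifnot(length(x_R) == length(beta_hat),
            length(x_D) == length(beta_hat))
  intercept + 0.75 * sum(x_R * beta_hat) + 0.25 * sum(x_D * beta_hat)
}

.quad_form_blocks <- function(beta, Sigma) {
  if (inherits(Sigma, "progeny_covariance")) {
    if (length(beta) != attr(Sigma, "m"))
      stop("beta length does not match the covariance matrix")
    sum(vapply(Sigma, function(b) {
      bb <- beta[b$markers]
      drop(crossprod(bb, b$Sigma %*% bb))
    }, numeric(1)))
  } else {
    if (length(beta) != nrow(Sigma))
      stop("beta length does not match the covariance matrix")
    drop(crossprod(beta, Sigma %*% beta))
  }
}

#' Progeny-variance prediction: variance of posterior means (VPM)
#'
#' sigma2 = beta_hat' Sigma beta_hat, the quadratic form of the
#' posterior-mean marker effects in the progeny marker covariance, computed
#' blockwise per chromosome.
#'
#' @param beta_hat marker effects (no intercept).
#' @param Sigma a [progeny_covariance_matrix()] object (or dense matrix)
#'   for the same cross.
#' @return scalar predicted progeny variance.
#' @export
predict_cross_variance_vpm <- function(beta_hat, Sigma) {
  .quad_form_blocks(beta_hat, Sigma)
}

#' Progeny-variance prediction: posterior mean variance (PMV)
#'
#' sigma2 = mean over MCMC samples s of beta^(s)' Sigma beta^(s); equals
#' VPM plus tr(Sigma Cov(beta samples)), so PMV >= VPM whenever Sigma is
#' positive semi-definite.
#'
#' @param posterior a `brr_fit`, or an S x M matrix of effect samples
#'   (no intercept).
#' @param Sigma a [progeny_covariance_matrix()] object (or dense matrix).
#' @return scalar predicted progeny variance.
#' @export
predict_cross_variance_pmv <- function(posterior, Sigma) {
  B <- if (inherits(posterior, "brr_fit")) effect_samples(posterior)
       else as.matrix(posterior)
  if (nrow(B) < 1) stop("posterior must contain at least one sample")
  if (inherits(Sigma, "progeny_covariance")) {
    if (ncol(B) != attr(Sigma, "m"))
      stop("sample dimension does not match the covariance matrix")
    tot <- 0
    for (b in Sigma) {
      Bb <- B[, b$markers, drop = FALSE]
      tot <- tot + sum((Bb %*% b$Sigma) * Bb)
    }
    tot / nrow(B)
  } else {
    sum((B %*% Sigma) * B) / nrow(B)
  }
}

#' Usefulness criterion
#'
#' UC = mu + i h sigma2 (variance scale, the default, matching the working
#' definition UC = mu + i * sigma2_A with h = 1) or UC = mu + i h sigma
#' (`scale = "sd"`, the classical standard-deviation form). i = 2.07
#' corresponds to a 5% selection rate; h is the prediction accuracy.
#'
#' @param mu predicted cross mean.
#' @param sigma2 predicted progeny variance (>= 0).
#' @param i selection intensity, default 2.07.
#' @param h prediction accuracy, default 1.
#' @param scale `"variance"` (default) or `"sd"`.
#' @return scalar UC.
#' @export
usefulness_criterion <- function(mu, sigma2, i = 2.07, h = 1,
                                 scale = c("variance", "sd")) {
  scale <- match.arg(scale)
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative")
  if (scale == "variance") mu + i * h * sigma2 else mu + i * h * sqrt(sigma2)
}

#' Full prediction for one donor x recipient cross
#'
#' Combines the mean prediction (3/4-1/4 parental weighting), the VPM and
#' PMV progeny-variance predictions and the usefulness criterion into one
#' record.
#'
#' @param x_R,x_D parental genotypes coded 0/2 (map order).
#' @param posterior a `brr_fit` for the chosen training set.
#' @param map genetic map (used to assemble Sigma); alternatively supply a
#'   precomputed `Sigma`.
#' @param Sigma optional precomputed [progeny_covariance_matrix()].
#' @param i,h,uc_scale usefulness-criterion settings.
#' @return one-row data.frame with `mu_hat`, `sigma2_vpm`, `sigma2_pmv`,
#'   `uc_vpm`, `uc_pmv`, `i`, `h`, `uc_scale`.
#' @export
predict_cross <- function(x_R, x_D, posterior, map = NULL, Sigma = NULL,
                          i = 2.07, h = 1,
                          uc_scale = c("variance", "sd")) {
  uc_scale <- match.arg(uc_scale)
  stopifnot(inherits(posterior, "brr_fit"))
  if (is.null(Sigma)) {
    if (is.null(map)) stop("supply either map or Sigma")
    Sigma <- progeny_covariance_matrix(x_R, x_D, map)
  }
  beta <- marker_effects(posterior)
  b0 <- unname(posterior$posterior_mean[1])
  mu <- unname(predict_cross_mean(x_R, x_D, beta, intercept = b0))
  v_vpm <- predict_cross_variance_vpm(beta, Sigma)
  v_pmv <- predict_cross_variance_pmv(posterior, Sigma)
  data.frame(row.names = NULL,
             mu_hat = mu,
             sigma2_vpm = v_vpm,
             sigma2_pmv = v_pmv,
             uc_vpm = usefulness_criterion(mu, max(v_vpm, 0), i, h,
                                           uc_scale),
             uc_pmv = usefulness_criterion(mu, max(v_pmv, 0), i, h,
                                           uc_scale),
             i = i, h = h, uc_scale = uc_scale,
             stringsAsFactors = FALSE)
}
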