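# REML for y = 1 mu + A + E, A ~ N(0, K sA2), E ~ N(0, I sE2), by spectral
# decomposition of the intercept-projected kinship (EMMA-style): the
# restricted likelihood reduces to a 1-D profile over the variance ratio.

.reml_spectral <- function(y, K, tol = 1e-8) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (n < 3) stop("need at least 3 observations for REML")
  if (sd(y) < 1e-12) {
    return(list(mu = mean(y), sigma2_A = 0, sigma2_E = 0,
                loglik_reml = Inf, converged = TRUE))
  }
  # orthonormal contrast basis Q (perp to the intercept), valid for any
  # rank of K; the restricted likelihood is that of Q'y ~ N(0, Q'VQ)
  Q <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  eg <- eigen(crossprod(Q, K %*% Q), symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  eta <- drop(crossprod(eg$vectors, crossprod(Q, y)))
  # profile restricted loglik over ratio lambda = sA2 / sE2
  prof <- function(loglambda) {
    lam <- exp(loglambda)
    w <- xi * lam + 1
    s2e <- sum(eta^2 / w) / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * s2e) + sum(log(w)) + (n - 1))
  }
  opt <- optimize(prof, interval = c(-25, 25), maximum = TRUE,
                  tol = tol)
  # compare against the boundary lambda -> 0 (pure error model)
  cand <- c(opt$maximum, -50)
  ll <- vapply(cand, prof, numeric(1))
  best <- cand[which.max(ll)]
  lam <- exp(best)
  w <- xi * lam + 1
  s2e <- sum(eta^2 / w) / (n - 1)
  s2a <- lam * s2e
  floor_v <- 1e-10
  if (s2a < floor_v) s2a <- 0
  if (s2e < floor_v) s2e <- 0
  # GLS intercept under the fitted covariance
  V <- K * s2a + diag(s2e, n)
  Vi1 <- solve(V, rep(1, n))
  mu <- sum(Vi1 * y) / sum(Vi1)
  list(mu = mu, sigma2_A = s2a, sigma2_E = s2e,
       loglik_reml = max(ll), converged = TRUE)
}

#' REML estimation of a family mean and additive variance
#'
#' Fits y = 1 mu + A + E with A ~ N(0, K sigma2_A) and E ~ N(0, I sigma2_E)
#' by restricted maximum likelihood; one fit per family gives the per-family
#' mean performance and additive genetic variance. The two-component model is
#' reduced to a one-dimensional profile over the variance ratio through a
#' spectral decomposition of the projected kinship, which also handles
#' singular K.
#'
#' @param y numeric vector of adjusted means (one per individual).
#' @param K kinship matrix for the same individuals (from [kinship_noia()]
#'   computed on this family).
#' @return list of class `variance_components`: `mu`, `sigma2_A`,
#'   `sigma2_E`, `loglik_reml`.
#' @export
fit_family_gblup <- function(y, K) {
  if (inherits(K, "kinship_noia")) K <- K$K
  out <- .reml_spectral(y, K)
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("mu = %.4g, sigma2_A = %.4g, sigma2_E = %.4g\n",
              x$mu, x$sigma2_A, x$sigma2_E))
  invisible(x)
}

#' GBLUP prediction of unobserved individuals
#'
#' Builds the NOIA kinship over the union of training and validation
#' individuals (genotype frequencies computed on that union), estimates the
#' variance components on the training set by REML, and back-solves the BLUP
#' of every individual's additive value. Predicted phenotype = mu + A.
#'
#' @param y_TS named numeric vector of training phenotypes; names must match
#'   rownames of `dosages`.
#' @param dosages dosage matrix over training plus validation individuals.
#' @param var_components optional list with `sigma2_A`, `sigma2_E` to skip
#'   the REML step (the intercept is still re-estimated by GLS).
#' @return list of class `blup_result`: `predicted_genetic_values` (named,
#'   all individuals), `predicted_phenotypes` (mu + A), `fitted_mu`,
#'   `var_components`, `kinship`.
#' @export
gblup_predict <- function(y_TS, dosages, var_components = NULL) {
  if (is.null(names(y_TS)) || is.null(rownames(dosages)))
    stop("y_TS and dosages must carry individual ids")
  if (!all(names(y_TS) %in% rownames(dosages)))
    stop("training individuals missing from the dosage matrix")
  kin <- kinship_noia(dosages)
  K <- kin$K
  ts <- match(names(y_TS), rownames(dosages))
  if (is.null(var_components)) {
    vc <- fit_family_gblup(y_TS, K[ts, ts, drop = FALSE])
  } else {
    vc <- var_components
    V <- K[ts, ts, drop = FALSE] * vc$sigma2_A +
      diag(vc$sigma2_E, length(ts))
    Vi1 <- solve(V, rep(1, length(ts)))
    vc$mu <- sum(Vi1 * y_TS) / sum(Vi1)
  }
  n_ts <- length(ts)
  if (vc$sigma2_A <= 0) {
    A <- setNames(rep(0, nrow(K)), rownames(dosages))
  } else {
    V <- K[ts, ts, drop = FALSE] * vc$sigma2_A + diag(vc$sigma2_E, n_ts)
    rhs <- solve(V, y_TS - vc$mu)
    A <- setNames(drop(K[, ts, drop = FALSE] %*% rhs) * vc$sigma2_A,
                  rownames(dosages))
  }
  out <- list(predicted_genetic_values = A,
              predicted_phenotypes = vc$mu + A,
              fitted_mu = vc$mu,
              var_components = vc,
              kinship = kin)
  class(out) <- "blup_result"
  out
}

#' Fixed parental-effects model for cross means
#'
#' Ordinary least squares of adjusted means on additive donor and recipient
#' main effects, y = mu + gamma_donor + rho_recipient + e, under sum-to-zero
#' contrasts for each factor. The predicted mean of any cross is
#' mu + gamma_i + rho_j; predicted means do not depend on the
#' identifiability constraint.
#'
#' @param y numeric vector of hybrid adjusted means.
#' @param donor,recipient parental labels, one per observation.
#' @return list of class `parental_effects`: `intercept`, `donor_effects`,
#'   `recipient_effects` (both named, summing to zero), `constraint`.
#' @export
fit_parental_fixed_effects <- function(y, donor, recipient) {
  donor <- factor(donor)
  recipient <- factor(recipient)
  stopifnot(length(y) == length(donor), length(y) == length(recipient))
  df <- data.frame(y = y, donor = donor, recipient = recipient)
  ctr <- list(donor = "contr.sum", recipient = "contr.sum")
  if (nlevels(donor) == 1) ctr$donor <- NULL
  if (nlevels(recipient) == 1) ctr$recipient <- NULL
  form <- if (length(ctr)) {
    stats::as.formula(paste("y ~",
                            paste(names(ctr), collapse = " + ")))
  } else y ~ 1
  fit <- lm(form, data = df, contrasts = if (length(ctr)) ctr else NULL)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("disconnected design: aliased effects for ", paste(bad,
                                                            collapse = ", "))
  }
  expand <- function(fac, prefix) {
    k <- nlevels(fac)
    eff <- setNames(rep(0, k), levels(fac))
    if (k > 1) {
      b <- cf[grep(paste0("^", prefix), names(cf))]
      eff[seq_len(k - 1)] <- b
      eff[k] <- -sum(b)
    }
    eff
  }
  out <- list(intercept = unname(cf["(Intercept)"]),
              donor_effects = expand(donor, "donor"),
              recipient_effects = expand(recipient, "recipient"),
              constraint = "sum-to-zero")
  class(out) <- "parental_effects"
  out
}

#' Predicted cross mean from fixed parental effects
#'
#' @param fit object from [fit_parental_fixed_effects()].
#' @param donor,recipient parental ids (must be levels seen at fit time).
#' @return numeric predicted mean(s), mu + gamma_donor + rho_recipient.
#' @export
predict_parental_mean <- function(fit, donor, recipient) {
  if (!all(donor %in% names(fit$donor_effects)))
    stop("unknown donor level")
  if (!all(recipient %in% names(fit$recipient_effects)))
    stop("unknown recipient level")
  fit$intercept + fit$donor_effects[donor] +
    fit$recipient_effects[recipient]
}
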