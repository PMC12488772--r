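#' Resolve a training set of a given composition
#'
#' Training-set types for predicting a target family, defined on the
#' crossing design: `F` (the target family itself, minus the validation
#' set), `OFO` (one-family-out: all individuals of all other families),
#' `R` (families sharing the target's recipient, target excluded), `D`
#' (sharing the donor), `RD` (union of R and D), `Disc` (families sharing
#' neither parent). `with_family_fraction` adds the target-family
#' individuals not in the validation set to any non-F type.
#'
#' @param design crossing design (`family_id`, `recipient_id`, `donor_id`).
#' @param individuals data.frame with `individual_id`, `family_id`.
#' @param target_family family whose progeny are predicted.
#' @param ts_type one of `"F"`, `"OFO"`, `"R"`, `"D"`, `"RD"`, `"Disc"`.
#' @param vs_ids validation-set individual ids (subset of the target
#'   family); excluded from the training set.
#' @param with_family_fraction add the non-VS third of the target family.
#' @return list of class `training_set`: `member_ids`, `ts_type`,
#'   `target_family`, `with_family_fraction`.
#' @export
build_training_set <- function(design, individuals, target_family,
                               ts_type = c("F", "OFO", "R", "D", "RD",
                                           "Disc"),
                               vs_ids = character(),
                               with_family_fraction = FALSE) {
  ts_type <- match.arg(ts_type)
  if (!target_family %in% design$family_id)
    stop("unknown target family: ", target_family)
  tgt <- design[design$family_id == target_family, ]
  fam_ids <- function(fams)
    individuals$individual_id[individuals$family_id %in% fams]
  own <- setdiff(fam_ids(target_family), vs_ids)
  if (!all(vs_ids %in% fam_ids(target_family)))
    stop("vs_ids must belong to the target family")
  others <- design[design$family_id != target_family, ]
  fams <- switch(ts_type,
    F = target_family,
    OFO = others$family_id,
    R = others$family_id[others$recipient_id == tgt$recipient_id],
    D = others$family_id[others$donor_id == tgt$donor_id],
    RD = others$family_id[others$recipient_id == tgt$recipient_id |
                            others$donor_id == tgt$donor_id],
    Disc = others$family_id[others$recipient_id != tgt$recipient_id &
                              others$donor_id != tgt$donor_id])
  members <- if (ts_type == "F") own else fam_ids(fams)
  if (ts_type != "F" && with_family_fraction)
    members <- union(members, own)
  if (length(members) == 0)
    stop("empty training set for type ", ts_type, " and family ",
         target_family)
  out <- list(member_ids = members, ts_type = ts_type,
              target_family = target_family,
              with_family_fraction = with_family_fraction)
  class(out) <- "training_set"
  out
}

#' Predictive ability
#'
#' Pearson correlation between observed adjusted means and predicted values
#' on a validation set.
#'
#' @param observed,predicted numeric vectors (>= 3 pairs, both
#'   non-constant).
#' @return correlation in \[-1, 1\].
#' @export
predictive_ability <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("constant input vector")
  cor(observed, predicted)
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the range of the observed values.
#'
#' @param predicted,observed numeric vectors.
#' @return nonnegative scalar.
#' @export
nrmse <- function(predicted, observed) {
  stopifnot(length(observed) == length(predicted))
  rng <- diff(range(observed))
  if (rng == 0) stop("observed values have zero range")
  sqrt(mean((predicted - observed)^2)) / rng
}

# named phenotype vector for one trait
.pheno_vector <- function(sim, trait) {
  ph <- sim$pheno[sim$pheno$trait == trait, ]
  if (nrow(ph) == 0) stop("unknown trait: ", trait)
  setNames(ph$value, ph$individual_id)
}

# common validation-set draws: a list of id vectors, one per repetition
.draw_vs <- function(ids, n_reps, vs_fraction) {
  n_vs <- round(length(ids) * vs_fraction)
  lapply(seq_len(n_reps), function(r) sample(ids, n_vs))
}

#' Within-family cross-validation
#'
#' For each repetition, two-thirds of a family are sampled as validation
#' set, the GBLUP model is calibrated on the remaining third, and the
#' predictive ability is the correlation between observed and predicted
#' values on the validation set. Degenerate repetitions (constant observed
#' or predicted values) are recorded as NA and excluded from the mean.
#'
#' @param y named phenotype vector for the family.
#' @param dosages dosage matrix for the same individuals.
#' @param n_reps number of repetitions, default 100.
#' @param vs_fraction validation fraction, default 2/3.
#' @param seed optional integer seed (fixing it fixes the partitions).
#' @return list: `per_rep` data.frame (`repetition`, `pa`), `mean_pa`,
#'   `n_dropped`.
#' @export
within_family_cv <- function(y, dosages, n_reps = 100, vs_fraction = 2 / 3,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(dosages)
  stopifnot(!is.null(ids), all(names(y) %in% ids))
  if (length(ids) < 3) stop("family size must be at least 3")
  vs_list <- .draw_vs(ids, n_reps, vs_fraction)
  pa <- vapply(vs_list, function(vs) {
    ts <- setdiff(ids, vs)
    fit <- gblup_predict(y[ts], dosages)
    pred <- fit$predicted_phenotypes[vs]
    if (sd(y[vs]) == 0 || sd(pred) == 0) return(NA_real_)
    cor(y[vs], pred)
  }, numeric(1))
  list(per_rep = data.frame(repetition = seq_len(n_reps), pa = pa),
       mean_pa = mean(pa, na.rm = TRUE),
       n_dropped = sum(is.na(pa)))
}

#' Predictive ability of alternative training-set compositions
#'
#' Repeated evaluation of one target family under several training-set
#' types, with validation sets common to all types within a repetition (so
#' types are compared on identical targets). For inter-family types without
#' family augmentation the training set does not depend on the repetition,
#' so the model is calibrated once and only the validation correlations
#' vary across repetitions.
#'
#' @param sim a `bridge_sim` dataset.
#' @param target_family family to predict.
#' @param trait trait name.
#' @param ts_types character vector of types (see
#'   [build_training_set()]).
#' @param n_reps repetitions, default 100.
#' @param vs_fraction validation fraction of the family, default 2/3.
#' @param with_family_fraction augment non-F types with the non-VS third.
#' @param seed optional integer seed.
#' @return long data.frame: `family`, `ts_type`, `repetition`, `pa`.
#' @export
evaluate_ts_pa <- function(sim, target_family, trait,
                           ts_types = c("F", "OFO", "R", "D", "RD",
                                        "Disc"),
                           n_reps = 100, vs_fraction = 2 / 3,
                           with_family_fraction = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- .pheno_vector(sim, trait)
  fam_ids <- sim$individuals$individual_id[
    sim$individuals$family_id == target_family]
  vs_list <- .draw_vs(fam_ids, n_reps, vs_fraction)
  out <- list()
  for (tt in ts_types) {
    fixed_ts <- tt != "F" && !with_family_fraction
    if (fixed_ts) {
      ts <- build_training_set(sim$design, sim$individuals, target_family,
                               tt)
      sub <- c(ts$member_ids, fam_ids)
      fit <- gblup_predict(y[ts$member_ids], sim$progeny[sub, ,
                                                         drop = FALSE])
      pred_all <- fit$predicted_phenotypes
      pa <- vapply(vs_list, function(vs) {
        p <- pred_all[vs]
        if (sd(y[vs]) == 0 || sd(p) == 0) return(NA_real_)
        cor(y[vs], p)
      }, numeric(1))
    } else {
      pa <- vapply(vs_list, function(vs) {
        ts <- build_training_set(sim$design, sim$individuals,
                                 target_family, tt, vs_ids = vs,
                                 with_family_fraction =
                                   with_family_fraction)
        sub <- union(ts$member_ids, fam_ids)
        fit <- gblup_predict(y[ts$member_ids],
                             sim$progeny[sub, , drop = FALSE])
        p <- fit$predicted_phenotypes[vs]
        if (sd(y[vs]) == 0 || sd(p) == 0) return(NA_real_)
        cor(y[vs], p)
      }, numeric(1))
    }
    out[[tt]] <- data.frame(family = target_family, ts_type = tt,
                            repetition = seq_len(n_reps), pa = pa,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Share of usefulness-criterion variation due to the mean
#'
#' With UC = mu + i sigma2 across crosses, the mean's contribution is read
#' as the covariance share cov(mu, UC) / var(UC) (and the variance term
#' contributes the complement). This is one concrete decomposition of the
#' "variation of UC"; the choice is recorded here and in the output.
#'
#' @param mu_per_cross,sigma2_per_cross per-cross means and variances
#'   (>= 3 crosses).
#' @param i selection intensity, default 2.07.
#' @return fraction in \[0, 1\] for uncorrelated components (can exceed the
#'   unit interval when mean and variance are strongly correlated).
#' @export
uc_decomposition <- function(mu_per_cross, sigma2_per_cross, i = 2.07) {
  stopifnot(length(mu_per_cross) == length(sigma2_per_cross))
  if (length(mu_per_cross) < 3) stop("need at least 3 crosses")
  uc <- mu_per_cross + i * sigma2_per_cross
  v <- var(uc)
  if (v == 0) stop("UC has zero variance across crosses")
  cov(mu_per_cross, uc) / v
}

#' @importFrom stats cov
NULL

#' Commercial grain-yield index
#'
#' YI = GY + 2.5 (H2O_ref - H2O), in 0.1 t/ha, penalizing grain humidity at
#' harvest against a reference hybrid's trial-mean humidity.
#'
#' @param GY grain yield (0.1 t/ha).
#' @param H2O grain humidity at harvest (percent).
#' @param H2O_reference reference humidity (percent).
#' @return numeric index value(s).
#' @export
yield_index <- function(GY, H2O, H2O_reference) {
  GY + 2.5 * (H2O_reference - H2O)
}

#' Evaluate cross-level mean/variance/UC predictions against observed values
#'
#' "Observed" per-cross means and additive variances come from the
#' per-family REML fits; predictions come from Bayesian ridge regression
#' calibrated on each training-set composition, combined with the
#' progeny-covariance machinery. Reports, per training-set type and
#' parameter (mean, variance, UC), the correlation, RMSE and NRMSE over
#' crosses.
#'
#' @param sim a `bridge_sim` dataset.
#' @param trait trait name.
#' @param ts_types training-set types to evaluate.
#' @param method `"vpm"`, `"pmv"` or both.
#' @param families families to treat as prediction targets (default: all).
#' @param i,h,uc_scale usefulness-criterion settings.
#' @param n_iter,burn_in,thin MCMC settings passed to [fit_brr()].
#' @param seed optional integer seed.
#' @return list: `metrics` (long data.frame: ts_type, method, parameter,
#'   correlation, rmse, nrmse), `per_cross` (predicted and observed values
#'   per family and type), `observed` (per-family REML estimates).
#' @export
evaluate_cross_predictions <- function(sim, trait,
                                       ts_types = c("F", "OFO", "R", "D",
                                                    "RD", "Disc"),
                                       method = c("vpm", "pmv"),
                                       families = NULL,
                                       i = 2.07, h = 1,
                                       uc_scale = "variance",
                                       n_iter = 20000, burn_in = 5000,
                                       thin = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  method <- match.arg(method, several.ok = TRUE)
  y <- .pheno_vector(sim, trait)
  if (is.null(families)) families <- sim$design$family_id
  # observed per-family mean and additive variance (M1)
  obs <- do.call(rbind, lapply(families, function(f) {
    ids <- sim$individuals$individual_id[sim$individuals$family_id == f]
    kin <- kinship_noia(sim$progeny[ids, , drop = FALSE])
    vc <- fit_family_gblup(y[ids], kin)
    data.frame(family = f, mu_obs = vc$mu, sigma2_obs = vc$sigma2_A,
               stringsAsFactors = FALSE)
  }))
  obs$uc_obs <- usefulness_criterion(obs$mu_obs, obs$sigma2_obs, i, h,
                                     uc_scale)
  rows <- list()
  for (f in families) {
    k <- match(f, sim$design$family_id)
    x_R <- sim$parents[sim$design$recipient_id[k], ]
    x_D <- sim$parents[sim$design$donor_id[k], ]
    Sigma <- progeny_covariance_matrix(x_R, x_D, sim$map)
    for (tt in ts_types) {
      ts <- build_training_set(sim$design, sim$individuals, f, tt)
      fit <- fit_brr(y[ts$member_ids],
                     sim$progeny[ts$member_ids, , drop = FALSE],
                     n_iter = n_iter, burn_in = burn_in, thin = thin)
      pred <- predict_cross(x_R, x_D, fit, Sigma = Sigma, i = i, h = h,
                            uc_scale = uc_scale)
      rows[[paste(f, tt)]] <- cbind(
        data.frame(family = f, ts_type = tt, stringsAsFactors = FALSE),
        pred)
    }
  }
  per_cross <- merge(do.call(rbind, rows), obs, by = "family")
  metrics <- list()
  for (tt in ts_types) {
    d <- per_cross[per_cross$ts_type == tt, ]
    for (mth in method) {
      v_col <- paste0("sigma2_", mth)
      uc_col <- paste0("uc_", mth)
      add <- function(parameter, p, o) {
        data.frame(ts_type = tt, method = mth, parameter = parameter,
                   correlation = if (sd(o) > 0 && sd(p) > 0) cor(o, p)
                                 else NA_real_,
                   rmse = sqrt(mean((p - o)^2)),
                   nrmse = nrmse(p, o), stringsAsFactors = FALSE)
      }
      metrics[[paste(tt, mth)]] <- rbind(
        add("mean", d$mu_hat, d$mu_obs),
        add("variance", d[[v_col]], d$sigma2_obs),
        add("uc", d[[uc_col]], d$uc_obs))
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  list(metrics = metrics, per_cross = per_cross, observed = obs)
}
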