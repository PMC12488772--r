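#' Default pipeline configuration
#'
#' All knobs of the end-to-end analysis with the reference design shape.
#' The list round-trips losslessly through JSON serialization; every
#' stochastic stage derives its own seed from `seed`.
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(n_chromosomes = 10, length_morgan = 1.7,
                    markers_per_chromosome = 200,
                    n_recipients = 7, n_donors = 9, n_families = 20,
                    family_sizes = 38:66,
                    sharing = list(consensus_freq = 0.5,
                                   recipient_div = 0.3, donor_div = 0.5),
                    n_qtl_per_chromosome = 20,
                    traits = list(GY = list(heritability = 0.5))),
    cv = list(n_reps = 100, vs_fraction = 2 / 3,
              ts_types = c("F", "OFO", "R", "D", "RD", "Disc")),
    mcmc = list(n_iter = 20000, burn_in = 5000, thin = 5),
    uc = list(i = 2.07, h = 1, scale = "variance"),
    windows = list(window_size = 100, step = 20),
    stages = list(family_estimates = TRUE, ts_evaluation = TRUE,
                  cross_predictions = TRUE, donor_selection = TRUE)
  )
}

.stage_seed <- function(seed, offset) (seed * 1000L + offset) %% .Machine$integer.max

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> per-family REML estimates (mean, additive variance, UC) ->
#' training-set evaluation by cross-validation -> Bayesian ridge regression
#' and cross mean/variance/UC prediction -> H-criterion forward donor
#' selection. All tables are written as TSV under `out_dir` together with a
#' `manifest.json` recording the configuration, its hash and the seeds, so
#' any stage can be reproduced exactly.
#'
#' @param config list from [default_pipeline_config()] (possibly modified).
#' @param out_dir output directory (created if absent).
#' @return (invisibly) list with the in-memory results per stage and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("ucbridge_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  results <- list()
  tryCatch({
    sc <- config$simulate
    sim <- simulate_dataset(
      n_chromosomes = sc$n_chromosomes, length_morgan = sc$length_morgan,
      markers_per_chromosome = sc$markers_per_chromosome,
      n_recipients = sc$n_recipients, n_donors = sc$n_donors,
      n_families = sc$n_families, family_sizes = sc$family_sizes,
      sharing = sc$sharing, traits = sc$traits,
      n_qtl_per_chromosome = if (is.null(sc$n_qtl_per_chromosome)) 0
                             else sc$n_qtl_per_chromosome,
      seed = .stage_seed(config$seed, 1))
    results$sim <- sim
    write_map(sim$map, file.path(out_dir, "map.tsv"))
    write_genotypes(sim$parents, file.path(out_dir, "parents.tsv"))
    write_genotypes(sim$progeny, file.path(out_dir, "progeny.tsv"))
    write_design(sim$design, file.path(out_dir, "design.tsv"))
    write_phenotypes(sim$pheno, file.path(out_dir, "phenotypes.tsv"))
    traits <- names(sc$traits)

    if (isTRUE(config$stages$family_estimates)) {
      stage <- "family_estimates"
      rows <- list()
      for (tr in traits) {
        y <- .pheno_vector(sim, tr)
        for (f in sim$design$family_id) {
          ids <- sim$individuals$individual_id[
            sim$individuals$family_id == f]
          vc <- fit_family_gblup(y[ids],
                                 kinship_noia(sim$progeny[ids, ]))
          rows[[paste(tr, f)]] <- data.frame(
            trait = tr, family = f, mu = vc$mu, sigma2_A = vc$sigma2_A,
            sigma2_E = vc$sigma2_E,
            uc = usefulness_criterion(vc$mu, vc$sigma2_A, config$uc$i,
                                      config$uc$h, config$uc$scale),
            stringsAsFactors = FALSE)
        }
      }
      fam <- do.call(rbind, rows)
      rownames(fam) <- NULL
      results$family_estimates <- fam
      write.table(fam, file.path(out_dir, "family_estimates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (isTRUE(config$stages$ts_evaluation)) {
      stage <- "ts_evaluation"
      rows <- list()
      for (tr in traits) {
        for (f in sim$design$family_id) {
          pa <- evaluate_ts_pa(sim, f, tr,
                               ts_types = config$cv$ts_types,
                               n_reps = config$cv$n_reps,
                               vs_fraction = config$cv$vs_fraction,
                               seed = .stage_seed(config$seed, 2))
          pa$trait <- tr
          rows[[paste(tr, f)]] <- pa
        }
      }
      ts_eval <- do.call(rbind, rows)
      rownames(ts_eval) <- NULL
      results$ts_evaluation <- ts_eval
      write.table(ts_eval, file.path(out_dir, "ts_evaluation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (isTRUE(config$stages$cross_predictions)) {
      stage <- "cross_predictions"
      cp <- list()
      for (tr in traits) {
        ev <- evaluate_cross_predictions(
          sim, tr, ts_types = config$cv$ts_types,
          i = config$uc$i, h = config$uc$h,
          uc_scale = config$uc$scale,
          n_iter = config$mcmc$n_iter, burn_in = config$mcmc$burn_in,
          thin = config$mcmc$thin, seed = .stage_seed(config$seed, 3))
        ev$metrics$trait <- tr
        ev$per_cross$trait <- tr
        cp[[tr]] <- ev
      }
      results$cross_predictions <- cp
      write.table(do.call(rbind, lapply(cp, `[[`, "metrics")),
                  file.path(out_dir, "cross_prediction_metrics.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(do.call(rbind, lapply(cp, `[[`, "per_cross")),
                  file.path(out_dir, "cross_predictions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (isTRUE(config$stages$donor_selection)) {
      stage <- "donor_selection"
      tr <- traits[1]
      y <- .pheno_vector(sim, tr)
      set.seed(.stage_seed(config$seed, 4))
      full_fit <- fit_brr(y, sim$progeny,
                          n_iter = config$mcmc$n_iter,
                          burn_in = config$mcmc$burn_in,
                          thin = config$mcmc$thin)
      win <- build_windows(sim$map, config$windows$window_size,
                           config$windows$step)
      HE <- hebv(sim$parents, marker_effects(full_fit), win)
      lambda <- attr(win, "lambda")
      recipients <- unique(sim$design$recipient_id)
      donors <- unique(
        rownames(sim$parents)[attr(sim$parents, "role") == "donor"])
      traj <- list()
      for (r in recipients) {
        init <- sim$design$donor_id[sim$design$recipient_id == r]
        cand <- setdiff(donors, init)
        if (length(cand) == 0) next
        tj <- forward_select_donors(r, init, cand, HE, lambda)
        tj$recipient <- r
        tj$trait <- tr
        traj[[r]] <- tj
      }
      sel <- do.call(rbind, traj)
      rownames(sel) <- NULL
      results$donor_selection <- sel
      write.table(sel, file.path(out_dir, "donor_selection.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial outputs in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "ucbridge",
    version = as.character(utils::packageVersion("ucbridge")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$out_dir <- out_dir
  invisible(results)
}
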