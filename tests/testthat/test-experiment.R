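test_that("training-set compositions implement the design set algebra", {
  des <- toy_design(); ind <- toy_individuals()
  ids <- function(fams) ind$individual_id[ind$family_id %in% fams]

  ts <- function(type, ...) build_training_set(des, ind, "AC", type, ...)
  expect_setequal(ts("R")$member_ids, ids("AD"))
  expect_setequal(ts("D")$member_ids, ids("BC"))
  expect_setequal(ts("RD")$member_ids, ids(c("AD", "BC")))
  expect_setequal(ts("Disc")$member_ids, ids("BE"))
  expect_setequal(ts("OFO")$member_ids, ids(c("AD", "BC", "BE")))

  # RD = R union D; Disc disjoint from RD; OFO = R + D + Disc
  expect_setequal(ts("RD")$member_ids,
                  union(ts("R")$member_ids, ts("D")$member_ids))
  expect_length(intersect(ts("Disc")$member_ids, ts("RD")$member_ids), 0)
  expect_setequal(ts("OFO")$member_ids,
                  union(ts("RD")$member_ids, ts("Disc")$member_ids))

  # F excludes the validation set; augmentation adds the non-VS third
  vs <- ids("AC")[1:2]
  expect_setequal(ts("F", vs_ids = vs)$member_ids, setdiff(ids("AC"), vs))
  expect_setequal(
    ts("Disc", vs_ids = vs, with_family_fraction = TRUE)$member_ids,
    union(ids("BE"), setdiff(ids("AC"), vs)))

  # a family whose recipient is used once has an empty R set
  des2 <- rbind(des, data.frame(family_id = "XZ", recipient_id = "X",
                                donor_id = "Z", n_progeny = 2L))
  ind2 <- rbind(ind, data.frame(individual_id = c("XZ_1", "XZ_2"),
                                family_id = "XZ"))
  expect_error(build_training_set(des2, ind2, "XZ", "R"),
               "empty training set")
  expect_error(build_training_set(des, ind, "ZZ", "F"), "unknown")
})

test_that("predictive ability and NRMSE match their closed forms", {
  expect_equal(predictive_ability(1:5, 1:5), 1)
  expect_equal(predictive_ability(1:5, -(1:5)), -1)
  expect_equal(predictive_ability(c(1, 2, 3), c(1, 2, 4)),
               cor(c(1, 2, 3), c(1, 2, 4)))
  expect_error(predictive_ability(c(1, 1, 1), 1:3), "constant")
  expect_error(predictive_ability(1:2, 1:2), "3 pairs")

  expect_equal(nrmse(c(1, 9), c(0, 10)), 0.1)
  expect_equal(nrmse(1:4, 1:4), 0)
  expect_equal(nrmse(10 * c(1, 9), 10 * c(0, 10)), 0.1)  # scale invariant
  expect_error(nrmse(1:3, rep(2, 3)), "zero")
})

test_that("UC variation decomposition behaves at its corner cases", {
  mu <- c(3, 7, 5, 9)
  expect_equal(uc_decomposition(mu, rep(2, 4)), 1)       # constant variance
  expect_equal(uc_decomposition(rep(4, 4), c(1, 3, 2, 5)), 0)  # constant mean
  # symmetric contributions split 50/50
  expect_equal(uc_decomposition(c(0, 1, 2), c(0, 1, 2) / 2.07), 0.5)
  expect_error(uc_decomposition(rep(1, 3), rep(1, 3)), "zero variance")
})

test_that("yield index trades yield against humidity at 2.5 per point", {
  expect_equal(yield_index(95, 30, 30), 95)
  expect_equal(yield_index(100, 28, 30), 105)
  expect_equal(yield_index(100, 34, 30), 90)
})

test_that("within-family cross-validation is deterministic and calibrated", {
  sim <- small_sim()
  fam <- sim$design$family_id[2]
  ids <- sim$individuals$individual_id[sim$individuals$family_id == fam]
  y <- setNames(sim$pheno$value[match(ids, sim$pheno$individual_id)], ids)
  dos <- sim$progeny[ids, ]

  cv1 <- within_family_cv(y, dos, n_reps = 5, seed = 42)
  cv2 <- within_family_cv(y, dos, n_reps = 5, seed = 42)
  expect_identical(cv1$per_rep, cv2$per_rep)
  expect_true(all(abs(cv1$per_rep$pa) <= 1, na.rm = TRUE))

  # permuted phenotypes: mean PA compatible with zero
  set.seed(9)
  yp <- setNames(sample(y), names(y))
  cvp <- within_family_cv(yp, dos, n_reps = 30, seed = 10)
  n_vs <- round(length(ids) * 2 / 3)
  expect_lt(abs(cvp$mean_pa), 3 / sqrt(n_vs))
})

test_that("noiseless large families are predicted almost perfectly", {
  map <- simulate_genetic_map(5, 1.0, 20)
  set.seed(12)
  xR <- sample(c(0, 2), 100, replace = TRUE)
  xD <- sample(c(0, 2), 100, replace = TRUE)
  dos <- simulate_bc1s2_family(xR, xD, map, 200, seed = 13)
  arch <- list(true_effects = rnorm(100), heritability = 1,
               error_variance = 0)
  ph <- simulate_trait(dos, arch, seed = 14)
  y <- setNames(ph$value, ph$individual_id)
  cv <- within_family_cv(y, dos, n_reps = 5, seed = 15)
  expect_gte(cv$mean_pa, 0.95)
})

test_that("evaluate_ts_pa shares validation draws and reproduces itself", {
  sim <- small_sim()
  fam <- sim$design$family_id[1]
  pa1 <- evaluate_ts_pa(sim, fam, "GY", ts_types = c("F", "OFO"),
                        n_reps = 4, seed = 5)
  pa2 <- evaluate_ts_pa(sim, fam, "GY", ts_types = c("F", "OFO"),
                        n_reps = 4, seed = 5)
  expect_identical(pa1, pa2)
  expect_setequal(unique(pa1$ts_type), c("F", "OFO"))
  expect_equal(nrow(pa1), 8)
})

test_that("cross-level evaluation recovers self-consistent predictions", {
  # strong-signal check: F-calibrated BRR predicts the per-family means
  # with high correlation across families
  sim <- cached("sim_crosspred", simulate_dataset(
    n_chromosomes = 2, length_morgan = 1.0, markers_per_chromosome = 25,
    n_recipients = 3, n_donors = 3, n_families = 6,
    family_sizes = 25:30,
    traits = list(GY = list(heritability = 0.8)),
    n_qtl_per_chromosome = 5, seed = 33))
  ev <- evaluate_cross_predictions(sim, "GY", ts_types = "F",
                                   n_iter = 2500, burn_in = 500,
                                   thin = 4, seed = 3)
  m <- ev$metrics
  expect_setequal(m$parameter, c("mean", "variance", "uc"))
  cor_mean <- m$correlation[m$parameter == "mean" & m$method == "vpm"]
  expect_gte(cor_mean, 0.9)
  # identical predictions and observations give perfect metrics
  expect_equal(nrmse(ev$observed$mu_obs, ev$observed$mu_obs), 0)
})
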