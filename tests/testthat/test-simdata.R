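test_that("genetic maps are sorted, sized and spaced as requested", {
  map <- simulate_genetic_map(1, 1.0, 2)
  expect_equal(map$position_morgan, c(0, 1))

  map <- simulate_genetic_map(1, 2.0, 5)
  expect_equal(diff(map$position_morgan), rep(0.5, 4))

  map <- simulate_genetic_map(2, 1.5, 100, spacing = "uniform", seed = 7)
  expect_equal(nrow(map), 200)
  expect_false(anyDuplicated(map$marker_id) > 0)
  for (ch in unique(map$chromosome))
    expect_true(all(diff(map$position_morgan[map$chromosome == ch]) > 0))
  map2 <- simulate_genetic_map(2, 1.5, 100, spacing = "uniform", seed = 7)
  expect_identical(map, map2)

  expect_error(simulate_genetic_map(1, 1.0, 1), "at least 2")
  expect_error(simulate_genetic_map(1, 0, 5), "> 0")
})

test_that("simulated parents are inbred and reproducible", {
  map <- simulate_genetic_map(2, 1.0, 40)
  p <- simulate_parents(map, 3, 4, seed = 5)
  expect_true(all(p %in% c(0, 2)))
  expect_equal(rownames(p), c("R1", "R2", "R3", "D1", "D2", "D3", "D4"))
  expect_identical(p, simulate_parents(map, 3, 4, seed = 5))

  # forced polymorphism: recipients always consensus, donors always flipped
  q <- simulate_parents(map, 2, 2,
                        sharing = list(consensus_freq = 0.5,
                                       recipient_div = 0,
                                       donor_div = 1), seed = 5)
  expect_true(all(q["R1", ] != q["D1", ]))
  expect_true(all(q["R2", ] != q["D2", ]))
})

test_that("gametes respect homozygosity and complete linkage", {
  map <- simulate_genetic_map(1, 1.0, 10)
  hom <- rbind(rep(1L, 10), rep(1L, 10))
  expect_equal(simulate_gamete(hom, map, seed = 1), rep(1L, 10))

  # zero genetic distance: markers always co-inherited
  map0 <- data.frame(marker_id = c("a", "b"), chromosome = "C1",
                     position_morgan = c(0.3, 0.3))
  haps <- rbind(c(1L, 1L), c(0L, 0L))
  for (s in 1:25) {
    g <- simulate_gamete(haps, map0, seed = s)
    expect_true(g[1] == g[2])
  }
})

test_that("F1 recombinant fraction matches the Haldane map function", {
  map <- data.frame(marker_id = c("a", "b"), chromosome = "C1",
                    position_morgan = c(0, 0.5))
  n <- 20000
  set.seed(42)
  h1 <- matrix(1L, n, 2); h2 <- matrix(0L, n, 2)
  g <- ucbridge:::gametes_cpp(h1, h2, 0L, 1L, map$position_morgan)
  rec <- mean(g[, 1] != g[, 2])
  expected <- 0.5 * (1 - exp(-2 * 0.5))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(rec - expected), 3 * se)
})

test_that("BC1S2 families segregate with the design's expected frequencies", {
  map <- simulate_genetic_map(1, 1.0, 5)
  xR <- rep(0, 5); xD <- rep(2, 5)
  n <- 20000
  dos <- simulate_bc1s2_family(xR, xD, map, n, seed = 9)
  expect_true(all(dos %in% 0:2))
  # donor-allele frequency 1/4, heterozygosity 1/8 (per marker; linked
  # markers are correlated so each is tested on its own n individuals)
  freq <- mean(dos[, 1]) / 2
  se_f <- sqrt((5 / 8) / 4 / n)
  expect_lt(abs(freq - 0.25), 3 * se_f)
  het <- mean(dos[, 1] == 1)
  se_h <- sqrt(0.125 * 0.875 / n)
  expect_lt(abs(het - 0.125), 3 * se_h)

  # monomorphic markers stay homozygous recipient
  xD2 <- c(0, 2, 0, 2, 0)
  dos2 <- simulate_bc1s2_family(xR, xD2, map, 50, seed = 2)
  expect_true(all(dos2[, c(1, 3, 5)] == 0))

  expect_identical(simulate_bc1s2_family(xR, xD, map, 20, seed = 3),
                   simulate_bc1s2_family(xR, xD, map, 20, seed = 3))
  expect_error(simulate_bc1s2_family(xR, xD, map, 0), "n_progeny")
  expect_error(simulate_bc1s2_family(c(1, 0, 0, 0, 0), xD, map, 5),
               "homozygous")
})

test_that("markers on different chromosomes are in linkage equilibrium", {
  map <- simulate_genetic_map(2, 0.8, 2)
  xR <- rep(0, 4); xD <- rep(2, 4)
  dos <- simulate_bc1s2_family(xR, xD, map, 5000, seed = 13)
  r <- cor(dos[, 2], dos[, 3])   # last marker chr1 vs first marker chr2
  expect_lt(abs(r), 3 / sqrt(5000))
})

test_that("cross designs are incomplete but connected", {
  des <- simulate_cross_design(paste0("R", 1:7), paste0("D", 1:9),
                               n_families = 20, seed = 4)
  expect_equal(nrow(des), 20)
  expect_false(anyDuplicated(des[, c("recipient_id", "donor_id")]) > 0)
  expect_setequal(unique(des$recipient_id), paste0("R", 1:7))
  expect_setequal(unique(des$donor_id), paste0("D", 1:9))
  expect_true(all(des$n_progeny %in% 38:66))
})

test_that("simulated traits honor the architecture", {
  map <- simulate_genetic_map(1, 1.0, 10)
  dos <- simulate_bc1s2_family(rep(0, 10), rep(2, 10), map, 400, seed = 1)

  arch0 <- list(true_effects = rep(0, 10), heritability = NULL,
                error_variance = 2.5)
  ph <- simulate_trait(dos, arch0, seed = 2)
  expect_lt(abs(var(ph$value) - 2.5) / 2.5, 0.25)

  arch1 <- list(true_effects = rnorm(10), heritability = 1,
                error_variance = 0)
  ph1 <- simulate_trait(dos, arch1, seed = 3)
  expect_equal(ph1$value, unname(drop(dos %*% arch1$true_effects)))

  expect_error(
    simulate_trait(dos, list(true_effects = rep(0, 10),
                             heritability = 1.5)), "heritability")
})

test_that("realized heritability tracks the target", {
  map <- simulate_genetic_map(2, 1.0, 25)
  dos <- simulate_bc1s2_family(rep(0, 50), rep(2, 50), map, 5000, seed = 6)
  arch <- simulate_architecture(50, heritability = 0.5, seed = 7)
  ph <- simulate_trait(dos, arch, seed = 8)
  g <- attr(ph, "genetic_values")
  h2_real <- var(g) / var(ph$value)
  expect_lt(abs(h2_real - 0.5), 0.05)
})

test_that("empirical progeny variance matches BC1S2 genotype algebra", {
  expect_equal(empirical_progeny_variance(c(0, 2), c(0, 2),
                                          simulate_genetic_map(1, 1, 2),
                                          c(0, 0), 100, seed = 1), 0)
  # single segregating locus: Var(dosage) = 5/8 from frequencies
  # {11/16, 1/8, 3/16}
  n <- 2e5
  v <- empirical_progeny_variance(c(0, 0), c(2, 0),
                                  simulate_genetic_map(1, 1, 2),
                                  c(1, 0), n, seed = 5)
  se <- sqrt((1.0 - (5 / 8)^2) / n)   # fourth-central-moment formula
  expect_lt(abs(v - 5 / 8), 3 * se)
  # unlinked chromosomes: variances add
  map2 <- simulate_genetic_map(2, 1, 2)
  v2 <- empirical_progeny_variance(rep(0, 4), c(2, 0, 2, 0), map2,
                                   c(1, 0, 1, 0), n, seed = 6)
  expect_lt(abs(v2 - 2 * 5 / 8), 6 * se)
})

test_that("simulate_dataset assembles a coherent bridge design", {
  sim <- small_sim()
  expect_s3_class(sim, "bridge_sim")
  expect_equal(nrow(sim$progeny), sum(sim$design$n_progeny))
  expect_equal(sim$individuals$individual_id, rownames(sim$progeny))
  expect_equal(nrow(sim$pheno), nrow(sim$progeny))
  # regenerating with the same seed is bit-identical
  sim2 <- simulate_dataset(
    n_chromosomes = 3, length_morgan = 1.2, markers_per_chromosome = 30,
    n_recipients = 3, n_donors = 3, n_families = 6,
    family_sizes = 18:24,
    traits = list(GY = list(heritability = 0.6)),
    n_qtl_per_chromosome = 5, seed = 11)
  expect_identical(sim$progeny, sim2$progeny)
  expect_identical(sim$pheno, sim2$pheno)
})
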