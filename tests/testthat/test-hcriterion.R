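test_that("window construction covers every marker without spanning", {
  map1 <- simulate_genetic_map(1, 1, 100)
  w <- build_windows(map1)
  expect_length(w, 1)
  expect_equal(w[[1]], 1:100)
  expect_equal(attr(w, "lambda"), 0.2)

  map2 <- simulate_genetic_map(1, 1, 200)
  w2 <- build_windows(map2)
  starts <- vapply(w2, min, integer(1))
  expect_equal(starts, c(1L, 21L, 41L, 61L, 81L, 101L))
  expect_true(all(vapply(w2, max, integer(1)) <= 200))
  expect_equal(max(vapply(w2, max, integer(1))), 200)

  # truncation at the chromosome end
  map3 <- simulate_genetic_map(1, 1, 110)
  w3 <- build_windows(map3)
  expect_equal(vapply(w3, min, integer(1)), c(1L, 21L))
  expect_equal(w3[[2]], 21:110)

  # windows never span a chromosome boundary; every marker covered
  map4 <- simulate_genetic_map(2, 1, 130)
  w4 <- build_windows(map4)
  chrom_of <- map4$chromosome
  for (win in w4)
    expect_length(unique(chrom_of[win]), 1)
  expect_setequal(sort(unique(unlist(w4))), seq_len(260))

  expect_error(build_windows(map1, window_size = 10, step = 20), "step")
})

test_that("HEBV sums genotype-weighted effects within windows", {
  map <- simulate_genetic_map(1, 1, 3)
  X <- rbind(L1 = c(2, 0, 2), L2 = c(0, 0, 0), L1b = c(2, 0, 2))
  beta <- c(0.5, 1, -0.25)
  w <- build_windows(map, window_size = 3, step = 1)
  H <- hebv(X, beta, w)
  expect_equal(unname(H["L1", 1]), 0.5)         # 2*0.5 + 0 + 2*(-0.25)
  expect_equal(unname(H["L2", 1]), 0)
  expect_equal(H["L1", ], H["L1b", ])           # duplicated line
  expect_equal(unname(hebv(X, c(0, 0, 0), w)), matrix(0, 3, 1),
               ignore_attr = TRUE)
  expect_error(hebv(X, c(1, 2), w), "length")
})

test_that("H criterion takes windowwise maxima over the pool", {
  HEBV <- rbind(rec = c(1, 2), cand = c(3, 1))
  expect_equal(h_criterion("cand", "rec", character(), HEBV, 0.2),
               0.2 * (3 + 2))
  # candidate identical to recipient leaves the baseline unchanged
  HEBV2 <- rbind(rec = c(1, 2), twin = c(1, 2), d1 = c(0.5, 3))
  base <- 0.2 * sum(pmax(HEBV2["rec", ], HEBV2["d1", ]))
  expect_equal(h_criterion("twin", "rec", "d1", HEBV2, 0.2), base)
  # dominated candidate adds nothing
  HEBV3 <- rbind(rec = c(5, 5), weak = c(1, 2))
  expect_equal(h_criterion("weak", "rec", character(), HEBV3, 0.2),
               0.2 * 10)
  expect_error(h_criterion("d1", "rec", "d1", HEBV2, 0.2), "already")
})

test_that("forward selection is monotone, deterministic and ordered", {
  set.seed(61)
  for (rep in 1:5) {
    n_win <- 15
    HEBV <- matrix(rnorm(8 * n_win), 8, n_win,
                   dimnames = list(c("rec", paste0("d", 1:7)), NULL))
    traj <- forward_select_donors("rec", character(), paste0("d", 1:7),
                                  HEBV, 0.2)
    expect_equal(nrow(traj), 7)
    expect_true(all(diff(traj$H) >= -1e-12))
    expect_gte(traj$H[1], attr(traj, "H0"))
    # doubling lambda doubles H, leaves the order unchanged
    traj2 <- forward_select_donors("rec", character(), paste0("d", 1:7),
                                   HEBV, 0.4)
    expect_equal(traj2$donor, traj$donor)
    expect_equal(traj2$H, 2 * traj$H, tolerance = 1e-12)
  }

  # a uniformly dominated candidate is selected after its dominator
  HEBV <- rbind(rec = c(0, 0, 0), big = c(3, 2, 1), small = c(2, 1, 0))
  traj <- forward_select_donors("rec", character(), c("small", "big"),
                                HEBV, 0.2)
  expect_equal(traj$donor, c("big", "small"))
  # the dominated addition leaves H at the plateau
  expect_equal(traj$H[2], traj$H[1])

  single <- forward_select_donors("rec", character(), "big", HEBV, 0.2)
  expect_equal(nrow(single), 1)
})

test_that("dominated candidates never change the criterion", {
  set.seed(62)
  for (rep in 1:10) {
    HEBV <- matrix(rnorm(3 * 10), 3, 10,
                   dimnames = list(c("rec", "d1", "cand"), NULL))
    # force the candidate below the current pool maximum everywhere
    HEBV["cand", ] <- pmin(HEBV["rec", ], HEBV["d1", ]) - abs(rnorm(10))
    base <- 0.2 * sum(pmax(HEBV["rec", ], HEBV["d1", ]))
    expect_equal(h_criterion("cand", "rec", "d1", HEBV, 0.2), base)
  }
})

test_that("UC ranking and H ranking can disagree by construction", {
  # three markers, effectively unlinked; effects (1, -3, 0.5)
  map <- data.frame(marker_id = c("m1", "m2", "m3"), chromosome = "C1",
                    position_morgan = c(0, 5, 10))
  beta <- c(1, -3, 0.5)
  parents <- rbind(rec = c(2, 0, 0),
                   hiUC = c(2, 2, 0),   # segregates at the big-|effect|
                   hiH = c(2, 0, 2))    # carries a new favorable window
  post <- constant_posterior(beta)
  w <- build_windows(map, window_size = 1, step = 1)
  HE <- hebv(parents, beta, w)
  hv <- vapply(c("hiUC", "hiH"), function(cand)
    h_criterion(cand, "rec", character(), HE, 1), numeric(1))
  expect_gt(hv["hiH"], hv["hiUC"])     # H prefers the complementary donor
  uc <- rank_donors_by_uc("rec", c("hiUC", "hiH"), parents, post, map)
  expect_equal(uc$donor[1], "hiUC")    # UC prefers the variance donor
  expect_equal(uc$rank, 1:2)
  # both orders are reported unchanged side by side
  expect_gt(uc$uc[1], uc$uc[2])
})

test_that("UC ranking puts the higher-variance cross first at equal means", {
  map <- simulate_genetic_map(1, 1, 4)
  beta <- c(1, 1, 1, 1)
  # both donors give the same cross mean, but d_var segregates more
  parents <- rbind(rec = c(2, 2, 0, 0),
                   d_flat = c(2, 2, 0, 0),
                   d_var = c(0, 0, 2, 2))
  post <- constant_posterior(beta)
  r <- rank_donors_by_uc("rec", c("d_flat", "d_var"), parents, post, map)
  expect_equal(r$donor[1], "d_var")
  expect_equal(r$mu_hat[1], r$mu_hat[2], tolerance = 1e-12)
})
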