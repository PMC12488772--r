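# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small but structurally complete dataset: 5 chromosome arms, 6 families
small_sim <- function() {
  cached("small_sim", simulate_dataset(
    n_chromosomes = 3, length_morgan = 1.2, markers_per_chromosome = 30,
    n_recipients = 3, n_donors = 3, n_families = 6,
    family_sizes = 18:24,
    traits = list(GY = list(heritability = 0.6)),
    n_qtl_per_chromosome = 5,
    seed = 11))
}

# toy crossing design used for training-set set-algebra checks
toy_design <- function() {
  data.frame(
    family_id = c("AC", "AD", "BC", "BE"),
    recipient_id = c("A", "A", "B", "B"),
    donor_id = c("C", "D", "C", "E"),
    n_progeny = c(3L, 3L, 3L, 3L),
    stringsAsFactors = FALSE)
}

toy_individuals <- function() {
  d <- toy_design()
  data.frame(
    individual_id = paste0(rep(d$family_id, d$n_progeny), "_",
                           unlist(lapply(d$n_progeny, seq_len))),
    family_id = rep(d$family_id, d$n_progeny),
    stringsAsFactors = FALSE)
}

# minimal hand-built marker-effect posterior (degenerate chain: every
# sample equals beta), for exercising prediction code paths with known
# effects
constant_posterior <- function(beta, intercept = 0, S = 5) {
  samples <- matrix(rep(c(intercept, beta), each = S), nrow = S)
  colnames(samples) <- c("(Intercept)",
                         paste0("M", seq_along(beta)))
  structure(list(samples = samples,
                 posterior_mean = colMeans(samples),
                 sigma2_beta_draws = rep(1, S),
                 sigma2_e_draws = rep(1, S),
                 prior = NULL,
                 meta = list(n_samples = S)),
            class = "brr_fit")
}

# direct (non-spectral) restricted log-likelihood for y = 1 mu + A + E,
# used as an independent REML oracle
reml_loglik_direct <- function(y, K, sigma2_A, sigma2_E) {
  n <- length(y)
  V <- K * sigma2_A + diag(sigma2_E, n)
  ones <- rep(1, n)
  Vi <- solve(V)
  XtViX <- drop(crossprod(ones, Vi %*% ones))
  mu <- drop(crossprod(ones, Vi %*% y)) / XtViX
  r <- y - mu
  -0.5 * ((n - 1) * log(2 * pi) + determinant(V)$modulus +
            log(XtViX) + drop(crossprod(r, Vi %*% r)))
}
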