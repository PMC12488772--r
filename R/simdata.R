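#' Simulate a genetic map
#'
#' Builds a marker map with positions in Morgans, either evenly spaced or
#' uniformly drawn, sorted within chromosome. Genetic distances between
#' markers on the same chromosome derive from these positions and drive both
#' the meiosis simulator and the expected-recombination machinery.
#'
#' @param n_chromosomes number of chromosomes.
#' @param length_morgan chromosome length(s) in Morgans (recycled).
#' @param markers_per_chromosome marker count(s) per chromosome (recycled),
#'   each at least 2.
#' @param spacing `"even"` (default) for equidistant markers from 0 to the
#'   chromosome length, or `"uniform"` for positions drawn uniformly at
#'   random and sorted.
#' @param seed optional integer seed.
#' @return A data.frame with columns `marker_id`, `chromosome`,
#'   `position_morgan`; positions strictly increasing within chromosome.
#' @examples
#' map <- simulate_genetic_map(2, 1.5, 100, seed = 1)
#' @export
simulate_genetic_map <- function(n_chromosomes, length_morgan,
                                 markers_per_chromosome,
                                 spacing = c("even", "uniform"),
                                 seed = NULL) {
  spacing <- match.arg(spacing)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_chromosomes >= 1)
  len <- rep_len(length_morgan, n_chromosomes)
  nm <- rep_len(markers_per_chromosome, n_chromosomes)
  if (any(len <= 0)) stop("chromosome lengths must be > 0")
  if (any(nm < 2)) stop("each chromosome needs at least 2 markers")
  out <- vector("list", n_chromosomes)
  for (c in seq_len(n_chromosomes)) {
    pos <- if (spacing == "even") {
      seq(0, len[c], length.out = nm[c])
    } else {
      p <- sort(runif(nm[c], 0, len[c]))
      # break ties (vanishingly rare) to keep positions strictly increasing
      while (any(diff(p) <= 0)) p <- sort(p + runif(nm[c], 0, 1e-9))
      p
    }
    out[[c]] <- data.frame(
      marker_id = sprintf("C%d_M%03d", c, seq_len(nm[c])),
      chromosome = sprintf("C%d", c),
      position_morgan = pos,
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  map
}

.check_map <- function(map) {
  stopifnot(all(c("marker_id", "chromosome", "position_morgan") %in%
                  names(map)))
  if (anyDuplicated(map$marker_id))
    stop("duplicated marker ids in map")
  sp <- split(map$position_morgan, factor(map$chromosome,
                                          levels = unique(map$chromosome)))
  if (any(vapply(sp, function(p) any(diff(p) < 0), logical(1))))
    stop("map positions must be sorted within chromosome")
  invisible(map)
}

# 0-based start/end marker index per chromosome, in map order
.chrom_index <- function(map) {
  chrom <- factor(map$chromosome, levels = unique(map$chromosome))
  idx <- split(seq_len(nrow(map)), chrom)
  list(start = vapply(idx, min, integer(1)) - 1L,
       end = vapply(idx, max, integer(1)) - 1L)
}

#' Simulate homozygous parental lines
#'
#' Draws fully inbred recipient and donor lines coded 0/2 per marker. Each
#' marker has a consensus allele; every recipient deviates from the consensus
#' independently with probability `recipient_div` and every donor with
#' probability `donor_div`, so recipients resemble each other more than they
#' resemble donors (the elite-pool vs genetic-resource contrast).
#'
#' @param map genetic map from [simulate_genetic_map()].
#' @param n_recipients,n_donors line counts (defaults mirror a 7-recipient,
#'   9-donor design).
#' @param sharing list with elements `consensus_freq` (probability the
#'   consensus allele is "2"), `recipient_div`, `donor_div` (per-marker
#'   deviation probabilities).
#' @param seed optional integer seed.
#' @return Matrix (lines x markers) with entries in {0, 2}; rownames
#'   `R1..Rn` then `D1..Dn`; attribute `role` labels each row.
#' @export
simulate_parents <- function(map, n_recipients = 7, n_donors = 9,
                             sharing = list(consensus_freq = 0.5,
                                            recipient_div = 0.3,
                                            donor_div = 0.5),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check_map(map)
  m <- nrow(map)
  stopifnot(n_recipients >= 1, n_donors >= 1)
  consensus <- rbinom(m, 1, sharing$consensus_freq)
  draw <- function(n, div) {
    flip <- matrix(rbinom(n * m, 1, div), n, m, byrow = FALSE)
    2L * abs(sweep(flip, 2, consensus, function(f, c) abs(f - c)))
  }
  rec <- draw(n_recipients, sharing$recipient_div)
  don <- draw(n_donors, sharing$donor_div)
  geno <- rbind(rec, don)
  rownames(geno) <- c(sprintf("R%d", seq_len(n_recipients)),
                      sprintf("D%d", seq_len(n_donors)))
  colnames(geno) <- map$marker_id
  attr(geno, "role") <- c(rep("recipient", n_recipients),
                          rep("donor", n_donors))
  geno
}

#' Simulate one gamete from a phased genotype
#'
#' Crossover counts per chromosome are Poisson with mean equal to the
#' chromosome length in Morgans, crossover positions are uniform, and there
#' is no interference (Haldane model). Uses the current RNG state unless a
#' seed is given.
#'
#' @param haplotypes 2 x m matrix of phased alleles (0/1), columns in map
#'   order.
#' @param map genetic map covering the m markers.
#' @param seed optional integer seed.
#' @return Integer vector of m alleles.
#' @export
simulate_gamete <- function(haplotypes, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check_map(map)
  stopifnot(nrow(haplotypes) == 2, ncol(haplotypes) == nrow(map))
  ci <- .chrom_index(map)
  g <- gametes_cpp(matrix(as.integer(haplotypes[1, ]), 1),
                   matrix(as.integer(haplotypes[2, ]), 1),
                   ci$start, ci$end, map$position_morgan)
  as.integer(g[1, ])
}

#' Simulate a BC1S2 family
#'
#' Reproduces the bridging-population pedigree: F1 = recipient x donor, BC1 =
#' backcross of the F1 to the recipient, then two generations of selfing with
#' a single seed advanced each generation. Returns genotype dosages in the
#' same allele coding as the parents (count of the "2" allele), so markers
#' monomorphic between the parents are homozygous for the recipient allele in
#' every progeny.
#'
#' @param x_R,x_D recipient and donor genotypes, vectors coded 0/2.
#' @param map genetic map for the markers (same order).
#' @param n_progeny number of BC1S2 individuals (>= 1).
#' @param seed optional integer seed.
#' @param family_id label used to build individual ids.
#' @return Integer matrix (n_progeny x m) with entries in {0, 1, 2}.
#' @export
simulate_bc1s2_family <- function(x_R, x_D, map, n_progeny, seed = NULL,
                                  family_id = "F1") {
  if (!is.null(seed)) set.seed(seed)
  .check_map(map)
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  .check_parental(x_R); .check_parental(x_D)
  stopifnot(length(x_R) == nrow(map), length(x_D) == nrow(map))
  ci <- .chrom_index(map)
  dos <- bc1s2_cpp(as.integer(x_R / 2), as.integer(x_D / 2),
                   ci$start, ci$end, map$position_morgan,
                   as.integer(n_progeny))
  rownames(dos) <- sprintf("%s_I%04d", family_id, seq_len(n_progeny))
  colnames(dos) <- map$marker_id
  dos
}

.check_parental <- function(x) {
  if (!all(x %in% c(0, 2)))
    stop("parental genotypes must be homozygous, coded 0 or 2")
  invisible(x)
}

#' Simulate an incomplete crossing design
#'
#' Allocates donors to recipients so that each recipient is crossed to a
#' small number of donors (the design is incomplete: not all pairs occur),
#' every donor is used at least once, and family sizes vary. Defaults mirror
#' a 20-family design with 7 recipients, 9 donors, 2-3 donors per recipient
#' and 38-66 progeny per family.
#'
#' @param recipients,donors character vectors of line ids.
#' @param n_families total number of crosses.
#' @param family_sizes integer vector sampled from for per-family progeny
#'   counts.
#' @param seed optional integer seed.
#' @return data.frame with columns `family_id`, `recipient_id`, `donor_id`,
#'   `n_progeny`; (recipient, donor) pairs unique.
#' @export
simulate_cross_design <- function(recipients, donors, n_families = 20,
                                  family_sizes = 38:66, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- length(recipients); nd <- length(donors)
  if (n_families < max(nr, nd))
    stop("need at least as many families as recipients and as donors")
  if (n_families > nr * nd)
    stop("more families than available recipient x donor pairs")
  # spread family counts as evenly as possible over recipients
  base <- n_families %/% nr
  extra <- n_families %% nr
  per_rec <- rep(base, nr) + sample(rep(c(1L, 0L), c(extra, nr - extra)))
  if (any(per_rec > nd)) stop("a recipient would need more donors than exist")
  repeat {
    don_of <- lapply(per_rec, function(k) sample(donors, k))
    if (length(unique(unlist(don_of))) == nd) break
  }
  design <- data.frame(
    recipient_id = rep(recipients, per_rec),
    donor_id = unlist(don_of),
    stringsAsFactors = FALSE)
  design$family_id <- paste0(design$recipient_id, design$donor_id)
  design$n_progeny <- sample(family_sizes, n_families, replace = TRUE)
  design[, c("family_id", "recipient_id", "donor_id", "n_progeny")]
}

#' Define an additive trait architecture
#'
#' Simulation ground truth: one additive effect per marker and a target
#' heritability. The error variance is resolved against the realized genetic
#' variance when phenotypes are drawn.
#'
#' @param m number of markers.
#' @param effect_sd standard deviation of marker effects.
#' @param prop_qtl proportion of markers with nonzero effect.
#' @param heritability target ratio of genetic to phenotypic variance, in
#'   (0, 1].
#' @param seed optional integer seed.
#' @return list with `true_effects`, `heritability`, `error_variance`
#'   (NA until resolved by [simulate_trait()]).
#' @export
simulate_architecture <- function(m, effect_sd = 1, prop_qtl = 1,
                                  heritability = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (heritability <= 0 || heritability > 1)
    stop("heritability must be in (0, 1]")
  beta <- rnorm(m, 0, effect_sd)
  if (prop_qtl < 1)
    beta[sample.int(m, round((1 - prop_qtl) * m))] <- 0
  list(true_effects = beta, heritability = heritability,
       error_variance = NA_real_)
}

#' Simulate phenotypes from dosages and an additive architecture
#'
#' Phenotype = dosage %*% true_effects + Gaussian noise, one adjusted-mean
#' record per individual (the analysis consumes hybrid adjusted means
#' directly; no trial or tester structure is simulated). If
#' `architecture$error_variance` is NA, it is set so the realized
#' genetic-variance share matches `architecture$heritability`.
#'
#' @param dosages progeny dosage matrix (individuals x markers).
#' @param architecture list from [simulate_architecture()] (or with the same
#'   fields).
#' @param seed optional integer seed.
#' @param trait name of the trait.
#' @param family optional family label vector (recycled).
#' @return data.frame with columns `individual_id`, `family_id`, `trait`,
#'   `value`, plus attributes `genetic_values` and `error_variance`.
#' @export
simulate_trait <- function(dosages, architecture, seed = NULL,
                           trait = "trait", family = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  h2 <- architecture$heritability
  if (!is.null(h2) && (h2 <= 0 || h2 > 1))
    stop("heritability must be in (0, 1]")
  g <- drop(dosages %*% architecture$true_effects)
  ve <- architecture$error_variance
  if (is.null(ve) || is.na(ve)) {
    vg <- var(g)
    ve <- if (h2 == 1) 0 else vg * (1 - h2) / h2
  }
  if (ve < 0) stop("error_variance must be nonnegative")
  y <- g + if (ve > 0) rnorm(length(g), 0, sqrt(ve)) else 0
  out <- data.frame(
    individual_id = rownames(dosages),
    family_id = rep_len(family, nrow(dosages)),
    trait = trait,
    value = y,
    stringsAsFactors = FALSE)
  attr(out, "genetic_values") <- g
  attr(out, "error_variance") <- ve
  out
}

#' Monte-Carlo progeny variance of a cross
#'
#' Brute-force reference for the analytic progeny-variance prediction:
#' simulates `n_progeny` BC1S2 individuals from the cross and returns the
#' sample variance of their additive genetic values `dosage %*% beta`.
#'
#' @param x_R,x_D parental genotypes coded 0/2.
#' @param map genetic map.
#' @param beta fixed marker effects.
#' @param n_progeny number of simulated progenies (>= 2).
#' @param seed optional integer seed.
#' @return Nonnegative scalar.
#' @export
empirical_progeny_variance <- function(x_R, x_D, map, beta, n_progeny,
                                       seed = NULL) {
  if (n_progeny < 2) stop("n_progeny must be >= 2")
  dos <- simulate_bc1s2_family(x_R, x_D, map, n_progeny, seed = seed)
  var(drop(dos %*% beta))
}

#' Simulate a complete bridging-design dataset
#'
#' One call producing everything the downstream analysis consumes: map,
#' parents, incomplete crossing design, BC1S2 progeny dosages per family, and
#' adjusted-mean phenotypes for one or more additive traits. Defaults follow
#' the reference design shape: 7 recipients, 9 donors, 20 families of 38-66
#' BC1S2 individuals, 10 chromosomes of 1.7 Morgan.
#'
#' By default the causal loci are *hidden QTL*: extra loci interleaved with
#' the marker panel that carry the trait effects but are excluded from the
#' delivered genotype matrices. Panel markers then tag the QTL only through
#' within-family co-segregation, so marker-QTL linkage phase is consistent
#' across families sharing a parent and arbitrary across unrelated families
#' — the situation a real SNP array creates. Setting
#' `n_qtl_per_chromosome = 0` instead places the effects directly on panel
#' markers.
#'
#' @param n_chromosomes,length_morgan,markers_per_chromosome map parameters
#'   (`markers_per_chromosome` counts delivered panel markers).
#' @param n_recipients,n_donors,n_families,family_sizes design parameters.
#' @param sharing parental allele-sharing model, see [simulate_parents()].
#' @param traits named list of architecture settings; each element is a list
#'   with `effect_sd`, `prop_qtl`, `heritability` (missing fields take the
#'   [simulate_architecture()] defaults).
#' @param n_qtl_per_chromosome number of hidden causal loci per chromosome
#'   (shared across traits; effects drawn independently per trait).
#' @param seed integer seed governing all stages.
#' @return An object of class `bridge_sim`: list with `map`, `parents`,
#'   `design`, `progeny` (matrix, all individuals, panel markers only),
#'   `individuals` (data.frame individual_id/family_id), `pheno` (long
#'   data.frame), and `truth` (per-trait architectures over the full locus
#'   set, with resolved error variances, plus the hidden-QTL bookkeeping).
#' @export
simulate_dataset <- function(n_chromosomes = 10, length_morgan = 1.7,
                             markers_per_chromosome = 200,
                             n_recipients = 7, n_donors = 9,
                             n_families = 20, family_sizes = 38:66,
                             sharing = list(consensus_freq = 0.5,
                                            recipient_div = 0.3,
                                            donor_div = 0.5),
                             traits = list(GY = list(heritability = 0.5)),
                             n_qtl_per_chromosome = 20,
                             seed = 1) {
  set.seed(seed)
  loci_per_chrom <- markers_per_chromosome + n_qtl_per_chromosome
  map <- simulate_genetic_map(n_chromosomes, length_morgan,
                              loci_per_chrom)
  # designate hidden QTL positions, spread over each chromosome
  is_qtl <- rep(FALSE, nrow(map))
  if (n_qtl_per_chromosome > 0) {
    for (ch in unique(map$chromosome)) {
      ix <- which(map$chromosome == ch)
      is_qtl[sample(ix, n_qtl_per_chromosome)] <- TRUE
    }
  }
  parents <- simulate_parents(map, n_recipients, n_donors, sharing)
  design <- simulate_cross_design(rownames(parents)[seq_len(n_recipients)],
                                  rownames(parents)[n_recipients +
                                                      seq_len(n_donors)],
                                  n_families, family_sizes)
  prog <- vector("list", nrow(design))
  for (k in seq_len(nrow(design))) {
    prog[[k]] <- simulate_bc1s2_family(
      parents[design$recipient_id[k], ], parents[design$donor_id[k], ],
      map, design$n_progeny[k], family_id = design$family_id[k])
  }
  progeny <- do.call(rbind, prog)
  individuals <- data.frame(
    individual_id = rownames(progeny),
    family_id = rep(design$family_id, design$n_progeny),
    stringsAsFactors = FALSE)
  truth <- list()
  pheno <- list()
  for (tr in names(traits)) {
    spec <- traits[[tr]]
    arch <- simulate_architecture(
      nrow(map),
      effect_sd = if (is.null(spec$effect_sd)) 1 else spec$effect_sd,
      prop_qtl = if (is.null(spec$prop_qtl)) 1 else spec$prop_qtl,
      heritability = if (is.null(spec$heritability)) 0.5
                     else spec$heritability)
    # hidden-QTL mode: effects live on the QTL loci only
    if (any(is_qtl)) arch$true_effects[!is_qtl] <- 0
    ph <- simulate_trait(progeny, arch, trait = tr,
                         family = individuals$family_id)
    arch$error_variance <- attr(ph, "error_variance")
    arch$qtl_ids <- map$marker_id[is_qtl]
    truth[[tr]] <- arch
    pheno[[tr]] <- ph
  }
  # deliver only the panel markers; QTL stay hidden from the analysis
  panel <- !is_qtl
  out <- list(map = map[panel, , drop = FALSE],
              parents = parents[, panel, drop = FALSE],
              design = design,
              progeny = progeny[, panel, drop = FALSE],
              individuals = individuals,
              pheno = do.call(rbind, pheno), truth = truth, seed = seed)
  rownames(out$map) <- NULL
  attr(out$parents, "role") <- attr(parents, "role")
  rownames(out$pheno) <- NULL
  class(out) <- "bridge_sim"
  out
}

#' @export
print.bridge_sim <- function(x, ...) {
  cat("bridge_sim:", nrow(x$design), "BC1S2 families,",
      nrow(x$progeny), "individuals,", nrow(x$map), "markers on",
      length(unique(x$map$chromosome)), "chromosomes\n")
  cat("traits:", paste(names(x$truth), collapse = ", "), "\n")
  invisible(x)
}
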