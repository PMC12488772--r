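#' NOIA additive coefficients
#'
#' Natural and Orthogonal Interaction Approach coefficients computed from the
#' genotype frequencies of the analyzed subset. For marker frequencies
#' p_BB, p_Bb, p_bb the coefficient of an individual is
#' -(0 - p_Bb - 2 p_bb), -(1 - p_Bb - 2 p_bb) or -(2 - p_Bb - 2 p_bb) for
#' genotypes BB (dosage 0), Bb (dosage 1) and bb (dosage 2).
#'
#' @param dosages matrix (individuals x markers) with entries 0/1/2.
#' @param frequencies optional 3 x m matrix (rows p_BB, p_Bb, p_bb). When
#'   omitted, frequencies are computed from `dosages` itself — the subset
#'   being analyzed, which is the intended use.
#' @return Matrix H_A of centered coefficients, same dimnames as `dosages`.
#' @export
noia_additive_coefficients <- function(dosages, frequencies = NULL) {
  if (!all(dosages %in% 0:2)) stop("dosages must be coded 0/1/2")
  if (is.null(frequencies)) frequencies <- genotype_frequencies(dosages)
  if (any(abs(colSums(frequencies) - 1) > 1e-8))
    stop("genotype frequencies must sum to 1 at every marker")
  mean_dos <- frequencies["p_Bb", ] + 2 * frequencies["p_bb", ]
  h <- -sweep(dosages, 2, mean_dos, `-`)
  dimnames(h) <- dimnames(dosages)
  h
}

#' Genotype frequencies per marker
#'
#' @param dosages matrix with entries 0/1/2.
#' @return 3 x m matrix with rows `p_BB`, `p_Bb`, `p_bb`.
#' @export
genotype_frequencies <- function(dosages) {
  f <- rbind(p_BB = colMeans(dosages == 0),
             p_Bb = colMeans(dosages == 1),
             p_bb = colMeans(dosages == 2))
  colnames(f) <- colnames(dosages)
  f
}

#' NOIA additive kinship
#'
#' K = H_A H_A' / (tr(H_A H_A') / n), with H_A the NOIA coefficients built on
#' the genotype frequencies of this exact subset of individuals; tr(K) = n by
#' construction.
#'
#' @param dosages matrix (individuals x markers), entries 0/1/2.
#' @return list of class `kinship_noia` with `K` (n x n), `H_A`, and
#'   `subset_frequencies`; also carries the normalization constant `c` =
#'   tr(H_A H_A')/n.
#' @export
kinship_noia <- function(dosages) {
  freq <- genotype_frequencies(dosages)
  H <- noia_additive_coefficients(dosages, freq)
  G <- tcrossprod(H)
  tr <- sum(diag(G))
  if (tr <= 0)
    stop("degenerate input: every marker is monomorphic in this subset")
  n <- nrow(H)
  out <- list(K = G / (tr / n), H_A = H, subset_frequencies = freq,
              c = tr / n)
  class(out) <- "kinship_noia"
  out
}

#' Haldane recombination rate for DH progeny of an F1
#'
#' c1 = (1 - exp(-2 d)) / 2 for a genetic distance d in Morgans; d = Inf
#' (different chromosomes) gives the free-recombination limit 0.5.
#'
#' @param d_morgan nonnegative distance(s) in Morgans.
#' @return recombination rate(s) in \[0, 0.5\].
#' @export
haldane_c1 <- function(d_morgan) {
  if (any(d_morgan < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  0.5 * (1 - exp(-2 * d_morgan))
}

#' Expected recombination in a BC1S2 population
#'
#' Accumulates the meioses of the backcross and two selfing generations:
#' c = \[2 c1 / (1 + 2 c1)\] (1 - (1 - 2 c1)^2 / 4) + ((1 - 2 c1) / 2)^2 / 2.
#' Note that c(0) = 1/8: even fully linked marker pairs carry the residual
#' heterozygosity footprint of the design.
#'
#' @param c1 F1-DH recombination rate(s) in \[0, 0.5\].
#' @return expected recombination rate(s).
#' @export
bc1s2_recombination <- function(c1) {
  if (any(c1 < 0 | c1 > 0.5, na.rm = TRUE))
    stop("c1 must lie in [0, 0.5]")
  t <- 1 - 2 * c1
  (2 * c1 / (1 + 2 * c1)) * (1 - t^2 / 4) + 0.5 * (t / 2)^2
}

#' Parental linkage disequilibrium
#'
#' D^p = (1/16) (x_R - x_D)(x_R - x_D)' for a pair of homozygous parents
#' coded 0/2. Off-diagonal entries are 0 when the parents share an allele at
#' either marker, and +0.25 (coupling) or -0.25 (repulsion) otherwise; the
#' diagonal is 0.25 at markers segregating between the parents.
#'
#' @param x_R,x_D parental genotype vectors coded 0/2.
#' @return m x m matrix.
#' @export
parental_ld <- function(x_R, x_D) {
  .check_parental(x_R); .check_parental(x_D)
  stopifnot(length(x_R) == length(x_D))
  d <- x_R - x_D
  tcrossprod(d) / 16
}

#' Progeny marker-covariance matrix for a BC1S2 cross
#'
#' Sigma_ij = D^p_ij (1 - 2 c_ij)(3 - 2 c_ij), assembled per chromosome:
#' cross-chromosome pairs have c = 0.5 so their entries are exactly zero and
#' only within-chromosome blocks are stored.
#'
#' @param x_R,x_D parental genotypes coded 0/2 (map order).
#' @param map genetic map covering all markers.
#' @return Object of class `progeny_covariance`: list with one element per
#'   chromosome, each holding `markers` (indices into the map), `D_p`, `c1`,
#'   `c` and `Sigma` blocks; attribute `m` is the total marker count. Use
#'   [as.matrix()] to assemble the dense m x m matrix.
#' @export
progeny_covariance_matrix <- function(x_R, x_D, map) {
  .check_map(map)
  if (length(x_R) != nrow(map))
    stop("parental genotypes and map cover different marker sets")
  .check_parental(x_R); .check_parental(x_D)
  chrom <- factor(map$chromosome, levels = unique(map$chromosome))
  blocks <- lapply(split(seq_len(nrow(map)), chrom), function(ix) {
    pos <- map$position_morgan[ix]
    d <- abs(outer(pos, pos, `-`))
    c1 <- haldane_c1(d)
    cc <- bc1s2_recombination(c1)
    Dp <- parental_ld(x_R[ix], x_D[ix])
    Sigma <- Dp * (1 - 2 * cc) * (3 - 2 * cc)
    dimnames(Sigma) <- list(map$marker_id[ix], map$marker_id[ix])
    list(markers = ix, D_p = Dp, c1 = c1, c = cc, Sigma = Sigma)
  })
  attr(blocks, "m") <- nrow(map)
  attr(blocks, "marker_id") <- map$marker_id
  class(blocks) <- "progeny_covariance"
  blocks
}

#' @export
as.matrix.progeny_covariance <- function(x, ...) {
  m <- attr(x, "m")
  S <- matrix(0, m, m, dimnames = list(attr(x, "marker_id"),
                                       attr(x, "marker_id")))
  for (b in x) S[b$markers, b$markers] <- b$Sigma
  S
}

#' @export
print.progeny_covariance <- function(x, ...) {
  cat("progeny_covariance:", attr(x, "m"), "markers in", length(x),
      "chromosome blocks\n")
  invisible(x)
}
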