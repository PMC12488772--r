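#' Sliding haplotype windows along the genome
#'
#' Builds overlapping marker windows per chromosome: starts at marker 1,
#' 1 + step, 1 + 2 step, ...; each window spans `window_size` markers,
#' truncated at the chromosome end; window generation stops at the first
#' window reaching the last marker of the chromosome, so every marker is
#' covered and no window spans a chromosome boundary. The scaling factor
#' lambda = step / window_size (0.2 at the 100/20 defaults) is attached.
#'
#' @param map genetic map (markers ordered by chromosome then position).
#' @param window_size markers per window, default 100.
#' @param step start-to-start increment in markers, default 20.
#' @return list of class `haplotype_windows`: per window, the marker
#'   indices (into the map order); attributes `lambda`, `window_size`,
#'   `step`, `chromosome`.
#' @export
build_windows <- function(map, window_size = 100, step = 20) {
  .check_map(map)
  if (step < 1 || window_size < step)
    stop("need 1 <= step <= window_size")
  chrom <- factor(map$chromosome, levels = unique(map$chromosome))
  idx <- split(seq_len(nrow(map)), chrom)
  windows <- list()
  wchrom <- character()
  for (ch in names(idx)) {
    ix <- idx[[ch]]
    m <- length(ix)
    s <- 1
    repeat {
      e <- min(s + window_size - 1, m)
      windows[[length(windows) + 1]] <- ix[s:e]
      wchrom <- c(wchrom, ch)
      if (e >= m) break
      s <- s + step
      if (s > m) break
    }
  }
  # drop duplicated windows (possible on very short chromosomes)
  key <- vapply(windows, function(w) paste(w, collapse = ","),
                character(1))
  keep <- !duplicated(key)
  windows <- windows[keep]
  attr(windows, "chromosome") <- wchrom[keep]
  attr(windows, "lambda") <- step / window_size
  attr(windows, "window_size") <- window_size
  attr(windows, "step") <- step
  class(windows) <- "haplotype_windows"
  windows
}

#' @export
print.haplotype_windows <- function(x, ...) {
  cat("haplotype_windows:", length(x), "windows, lambda =",
      attr(x, "lambda"), "\n")
  invisible(x)
}

#' Haplotypic estimated breeding values
#'
#' HEBV = \[X o (1 beta')\] Z: entry (line, window) is the sum over the
#' window's markers of genotype times estimated marker effect — the genetic
#' value a line's haplotype contributes in that segment.
#'
#' @param parent_genotypes lines x markers matrix coded 0/2.
#' @param beta_hat posterior-mean marker effects (no intercept), from a fit
#'   calibrated on all individuals.
#' @param windows a [build_windows()] object.
#' @return lines x windows matrix, rownames preserved.
#' @export
hebv <- function(parent_genotypes, beta_hat, windows) {
  if (ncol(parent_genotypes) != length(beta_hat))
    stop("beta_hat length does not match the genotype matrix")
  W <- parent_genotypes * rep(beta_hat, each = nrow(parent_genotypes))
  out <- vapply(windows, function(ix)
    rowSums(W[, ix, drop = FALSE]), numeric(nrow(parent_genotypes)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = nrow(parent_genotypes))
  rownames(out) <- rownames(parent_genotypes)
  colnames(out) <- sprintf("W%03d", seq_len(length(windows)))
  out
}

.best_hebv <- function(HEBV, lines) {
  if (length(lines) == 1) HEBV[lines, ]
  else apply(HEBV[lines, , drop = FALSE], 2, max)
}

#' H criterion of a candidate donor
#'
#' H = lambda * sum over windows of the best HEBV among the candidate, the
#' recipient and the donors already incorporated — the expected value of the
#' best doubled-haploid line assembled from the pool's best haplotype
#' segments, scaled by the window overlap.
#'
#' @param candidate candidate donor id (row of `HEBV`).
#' @param recipient recipient id.
#' @param initial_donors ids of donors already crossed with the recipient
#'   (may be empty).
#' @param HEBV matrix from [hebv()].
#' @param lambda scaling factor, default the `lambda` attribute of the
#'   window set used (pass explicitly when HEBV was built elsewhere).
#' @return scalar H value.
#' @export
h_criterion <- function(candidate, recipient, initial_donors, HEBV,
                        lambda = 0.2) {
  pool <- c(candidate, recipient, initial_donors)
  if (candidate %in% initial_donors)
    stop("candidate is already an incorporated donor")
  if (!all(pool %in% rownames(HEBV)))
    stop("lines missing from HEBV: ",
         paste(setdiff(pool, rownames(HEBV)), collapse = ", "))
  lambda * sum(.best_hebv(HEBV, pool))
}

#' Forward selection of donors by the H criterion
#'
#' Iteratively incorporates the candidate donor maximizing the H criterion
#' given the recipient and previously incorporated donors, until all
#' candidates are ranked. The baseline H0 is computed from the recipient and
#' initial donors only; percent gain per step is 100 (H_step - H0) / H0.
#' Ties are broken lexicographically by donor id.
#'
#' @param recipient recipient id.
#' @param initial_donors donors already crossed with the recipient.
#' @param candidates candidate donor ids.
#' @param HEBV matrix from [hebv()].
#' @param lambda scaling factor (step / window_size).
#' @return data.frame of class `selection_trajectory`: `rank`, `donor`,
#'   `H`, `percent_gain`; attribute `H0` is the baseline.
#' @export
forward_select_donors <- function(recipient, initial_donors, candidates,
                                  HEBV, lambda = 0.2) {
  if (length(candidates) == 0) stop("no candidate donors")
  H0 <- lambda * sum(.best_hebv(HEBV, c(recipient, initial_donors)))
  incorporated <- initial_donors
  remaining <- sort(candidates)
  rows <- list()
  step <- 0
  while (length(remaining) > 0) {
    hv <- vapply(remaining, function(cand)
      h_criterion(cand, recipient, incorporated, HEBV, lambda),
      numeric(1))
    best <- remaining[which.max(hv)]   # ties: first in sorted order
    step <- step + 1
    rows[[step]] <- data.frame(rank = step, donor = best,
                               H = max(hv),
                               percent_gain = 100 * (max(hv) - H0) / H0,
                               stringsAsFactors = FALSE)
    incorporated <- c(incorporated, best)
    remaining <- setdiff(remaining, best)
  }
  out <- do.call(rbind, rows)
  attr(out, "H0") <- H0
  class(out) <- c("selection_trajectory", "data.frame")
  out
}

#' Rank candidate donors by predicted usefulness criterion
#'
#' Predicts the UC of each candidate donor x recipient cross (marker-effect
#' posterior plus progeny-covariance machinery) and ranks candidates in
#' decreasing UC order, for side-by-side comparison with the H-criterion
#' ranking.
#'
#' @param recipient recipient id (row of `parents`).
#' @param candidates candidate donor ids (rows of `parents`).
#' @param parents parental genotype matrix coded 0/2.
#' @param posterior a `brr_fit` (recommended: calibrated on an RD-type
#'   training set; the variance enters through the VPM method).
#' @param map genetic map.
#' @param i,h,uc_scale usefulness-criterion settings.
#' @param method `"vpm"` (default) or `"pmv"` variance prediction.
#' @return data.frame: `rank`, `donor`, `uc`, `mu_hat`, `sigma2`.
#' @export
rank_donors_by_uc <- function(recipient, candidates, parents, posterior,
                              map, i = 2.07, h = 1, uc_scale = "variance",
                              method = c("vpm", "pmv")) {
  method <- match.arg(method)
  stopifnot(recipient %in% rownames(parents),
            all(candidates %in% rownames(parents)))
  preds <- lapply(candidates, function(d) {
    p <- predict_cross(parents[recipient, ], parents[d, ], posterior,
                       map = map, i = i, h = h, uc_scale = uc_scale)
    data.frame(donor = d, uc = p[[paste0("uc_", method)]],
               mu_hat = p$mu_hat, sigma2 = p[[paste0("sigma2_", method)]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, preds)
  out <- out[order(-out$uc, out$donor), ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
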