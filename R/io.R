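# Plain-TSV readers and writers for the tabular formats the pipeline
# exchanges: genotype matrices (individuals x markers), genetic maps,
# long-format phenotypes and crossing designs.

#' Write / read a genotype matrix
#'
#' TSV with an `id` column followed by one column per marker.
#'
#' @param genotypes matrix with rownames (individuals) and colnames
#'   (markers).
#' @param path file path.
#' @return `write_genotypes`: the path, invisibly. `load_genotypes`: the
#'   validated matrix.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param type `"progeny"` accepts dosages 0/1/2; `"parental"` requires
#'   homozygous 0/2 calls.
#' @export
load_genotypes <- function(path, type = c("progeny", "parental")) {
  type <- match.arg(type)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop("first column must be 'id'")
  if (anyDuplicated(df$id)) stop("duplicated individual ids")
  g <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(g) || any(g != round(g)))
    stop("non-integer genotype entries")
  allowed <- if (type == "parental") c(0, 2) else 0:2
  bad <- which(!(g %in% allowed))
  if (length(bad)) {
    row <- ((bad[1] - 1) %% nrow(g)) + 1
    stop(sprintf("invalid %s genotype call at data line %d (individual %s)",
                 type, row, df$id[row]))
  }
  rownames(g) <- df$id
  g
}

#' Write / read a genetic map
#' @param map data.frame (`marker_id`, `chromosome`, `position_morgan`).
#' @param path file path.
#' @export
write_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @param unit `"morgan"` (default) or `"centimorgan"`; centimorgan input is
#'   converted, positions are always Morgans internally.
#' @export
load_map <- function(path, unit = c("morgan", "centimorgan")) {
  unit <- match.arg(unit)
  map <- read.delim(path, stringsAsFactors = FALSE)
  if (unit == "centimorgan") map$position_morgan <- map$position_morgan / 100
  .check_map(map)
  map
}

#' Write / read a long-format phenotype table
#' @param pheno data.frame (`individual_id`, `family_id`, `trait`, `value`).
#' @param path file path.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
load_phenotypes <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a crossing design
#' @param design data.frame (`family_id`, `recipient_id`, `donor_id`,
#'   `n_progeny`).
#' @param path file path.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
load_design <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Remove monomorphic markers
#'
#' Drops markers showing a single genotype call across the given panel and
#' reports the count removed. Idempotent.
#'
#' @param genotypes matrix (individuals x markers).
#' @return list: `genotypes` (filtered), `n_removed`, `removed` (ids).
#' @export
filter_monomorphic <- function(genotypes) {
  mono <- apply(genotypes, 2, function(x) length(unique(x)) == 1)
  if (all(mono)) stop("all markers are monomorphic")
  list(genotypes = genotypes[, !mono, drop = FALSE],
       n_removed = sum(mono),
       removed = colnames(genotypes)[mono])
}
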