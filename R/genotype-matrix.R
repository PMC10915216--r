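#' SNP genotype panel
#'
#' Container for an n x m panel of biallelic SNP genotypes coded as
#' counted-allele dosage (0, 1, 2; \code{NA} = missing) together with sample
#' and marker metadata.
#'
#' @param values integer or numeric matrix, samples in rows, SNPs in columns;
#'   entries must be 0, 1, 2 or \code{NA}.
#' @param sample_ids character vector of unique sample identifiers
#'   (default: rownames of \code{values} or \code{S1..Sn}).
#' @param snp_ids character vector of unique SNP identifiers
#'   (default: colnames of \code{values} or \code{SNP1..SNPm}).
#' @param chromosome character vector, one chromosome label per SNP
#'   (autosome number as string, or \code{"X"}/\code{"Y"}).
#' @param position non-negative integer vector of physical positions per SNP.
#' @param counted_allele character vector, the allele whose dosage is counted.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(values, sample_ids = NULL, snp_ids = NULL,
                            chromosome = NULL, position = NULL,
                            counted_allele = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  # fractional dosages in [0,2] are admitted so that mean-imputed panels
  # remain first-class; file readers enforce integer coding themselves
  ok <- is.na(values) | (values >= 0 & values <= 2)
  if (!all(ok)) {
    stop("genotype values must lie in [0, 2] or be NA; found ",
         paste(unique(values[!ok])[seq_len(min(5, sum(!ok)))], collapse = ", "))
  }
  n <- nrow(values); m <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (is.null(snp_ids)) {
    snp_ids <- colnames(values)
    if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(m))
  }
  if (is.null(chromosome)) chromosome <- rep("0", m)
  if (is.null(position)) position <- rep(0L, m)
  if (is.null(counted_allele)) counted_allele <- rep("A", m)
  chromosome <- as.character(chromosome)
  position <- as.integer(position)
  counted_allele <- as.character(counted_allele)
  if (length(sample_ids) != n) stop("sample_ids length does not match rows")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(snp_ids) != m) stop("snp_ids length does not match columns")
  if (length(chromosome) != m || length(position) != m ||
      length(counted_allele) != m) {
    stop("per-SNP metadata must have one entry per SNP")
  }
  if (any(position < 0, na.rm = TRUE)) stop("positions must be non-negative")
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         snp_ids = as.character(snp_ids), chromosome = chromosome,
         position = position, counted_allele = counted_allele),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat("genotype_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "SNPs\n")
  cat("  chromosomes:", paste(unique(x$chromosome)[seq_len(min(8,
      length(unique(x$chromosome))))], collapse = ", "),
      if (length(unique(x$chromosome)) > 8) "..." else "", "\n")
  cat("  missing genotypes:", nm,
      sprintf("(%.2f%%)", 100 * nm / length(x$values)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype panel by samples and/or SNPs
#'
#' @param x a \code{genotype_matrix}.
#' @param samples sample indices or ids to keep (default all).
#' @param snps SNP indices or ids to keep (default all).
#' @return A \code{genotype_matrix} restricted to the selection.
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  }
  mi <- if (is.null(snps)) seq_along(x$snp_ids) else {
    if (is.character(snps)) match(snps, x$snp_ids) else snps
  }
  if (anyNA(si)) stop("unknown sample ids in subset")
  if (anyNA(mi)) stop("unknown SNP ids in subset")
  genotype_matrix(x$values[si, mi, drop = FALSE],
                  sample_ids = x$sample_ids[si], snp_ids = x$snp_ids[mi],
                  chromosome = x$chromosome[mi], position = x$position[mi],
                  counted_allele = x$counted_allele[mi])
}
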