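#' Quality-control filter for a genotype panel
#'
#' Applies, in a fixed order, the standard marker-panel filters: (1) samples
#' below the sample call-rate threshold, (2) monomorphic SNPs, (3) SNPs on
#' sex chromosomes, (4) SNPs below the minor-allele-frequency threshold,
#' (5) SNPs below the SNP call-rate threshold. Each SNP is counted once, by
#' the first rule it fails, so the report tallies are reproducible.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param maf_min remove SNPs with minor allele frequency below this
#'   (default 0.05).
#' @param snp_callrate_min remove SNPs with call rate below this
#'   (default 0.90).
#' @param sample_callrate_min remove samples with call rate below this
#'   (default 0.90).
#' @return List with the filtered \code{genotypes} and a \code{report}
#'   (class \code{qc_report}) of per-rule removal counts and thresholds.
#' @export
qc_filter <- function(g, maf_min = 0.05, snp_callrate_min = 0.90,
                      sample_callrate_min = 0.90) {
  stopifnot(inherits(g, "genotype_matrix"))
  for (th in c(maf_min, snp_callrate_min, sample_callrate_min)) {
    if (th < 0 || th > 1) stop("thresholds must lie in [0, 1]")
  }
  n_in <- ncol(g$values)
  samp_cr <- rowMeans(!is.na(g$values))
  keep_s <- samp_cr >= sample_callrate_min
  n_samples_removed <- sum(!keep_s)
  if (!any(keep_s)) stop("all samples removed by sample call-rate filter")
  g <- subset_genotypes(g, samples = which(keep_s))

  V <- g$values
  p <- colMeans(V, na.rm = TRUE) / 2
  callrate <- colMeans(!is.na(V))
  mono <- !is.na(p) & (p == 0 | p == 1)
  sexc <- toupper(g$chromosome) %in% c("X", "Y", "XY", "MT")
  maf <- pmin(p, 1 - p)
  low_maf <- !is.na(maf) & maf < maf_min
  low_cr <- callrate < snp_callrate_min
  # first-failing-rule attribution, fixed order
  fail_mono <- mono
  fail_sex <- sexc & !fail_mono
  fail_maf <- low_maf & !fail_mono & !fail_sex
  fail_cr <- low_cr & !fail_mono & !fail_sex & !fail_maf
  keep <- !(fail_mono | fail_sex | fail_maf | fail_cr)
  if (!any(keep)) stop("empty panel: all SNPs removed by QC")
  report <- structure(list(
    n_snps_in = n_in,
    n_removed_monomorphic = sum(fail_mono),
    n_removed_sex_chrom = sum(fail_sex),
    n_removed_maf = sum(fail_maf),
    n_removed_snp_callrate = sum(fail_cr),
    n_samples_removed = n_samples_removed,
    n_snps_out = sum(keep),
    thresholds = list(maf_min = maf_min,
                      snp_callrate_min = snp_callrate_min,
                      sample_callrate_min = sample_callrate_min)),
    class = "qc_report")
  list(genotypes = subset_genotypes(g, snps = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_snps_in, "SNPs in ->", x$n_snps_out, "out\n")
  cat("  removed: monomorphic", x$n_removed_monomorphic,
      "| sex-chrom", x$n_removed_sex_chrom,
      "| MAF", x$n_removed_maf,
      "| call-rate", x$n_removed_snp_callrate, "\n")
  cat("  samples removed:", x$n_samples_removed, "\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a \code{qc_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Impute residual missing genotypes
#'
#' Replaces missing entries by the per-SNP mean dosage computed from the
#' observed entries, optionally rounded to the nearest of \{0,1,2\}. Observed
#' entries are never altered. Mean imputation preserves the per-SNP allele
#' frequency exactly.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param method \code{"snp_mean"} (default; fractional dosages) or
#'   \code{"snp_mean_rounded"}.
#' @return A complete \code{\link{genotype_matrix}}.
#' @export
impute_missing <- function(g, method = c("snp_mean", "snp_mean_rounded")) {
  stopifnot(inherits(g, "genotype_matrix"))
  method <- match.arg(method)
  V <- g$values
  if (!anyNA(V)) return(g)
  nobs <- colSums(!is.na(V))
  if (any(nobs == 0)) {
    stop("SNPs fully missing, cannot impute: ",
         paste(g$snp_ids[nobs == 0], collapse = ", "))
  }
  mu <- colMeans(V, na.rm = TRUE)
  if (method == "snp_mean_rounded") mu <- pmin(2, pmax(0, round(mu)))
  idx <- which(is.na(V), arr.ind = TRUE)
  V[idx] <- mu[idx[, 2]]
  genotype_matrix(V, sample_ids = g$sample_ids, snp_ids = g$snp_ids,
                  chromosome = g$chromosome, position = g$position,
                  counted_allele = g$counted_allele)
}
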