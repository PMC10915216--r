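#' Read a genotype panel from PLINK .raw or VCF
#'
#' \code{plink_raw} expects the whitespace table written by
#' \code{plink --recode A}: header \code{FID IID PAT MAT SEX PHENOTYPE}
#' followed by one column per SNP named \code{<id>_<counted allele>}, entries
#' in \{0,1,2,NA\}. VCF reading uses \pkg{vcfR}; the GT field is mapped to
#' alternate-allele dosage (the ALT allele is the counted allele) and missing
#' calls are kept missing.
#'
#' @param path file path.
#' @param format \code{"plink_raw"} or \code{"vcf"}.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("plink_raw", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "plink_raw") read_plink_raw(path) else read_vcf_gt(path)
}

read_plink_raw <- function(path) {
  d <- utils::read.table(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = c("NA", "-9"))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (ncol(d) < 6 || !identical(names(d)[1:6], fixed)) {
    stop("malformed .raw header: expected columns ",
         paste(fixed, collapse = " "), " (line 1)")
  }
  snpcols <- names(d)[-(1:6)]
  alle <- sub("^.*_", "", snpcols)
  ids <- sub("_[^_]*$", "", snpcols)
  vals <- as.matrix(d[, -(1:6), drop = FALSE])
  if (!all(is.na(vals) | vals %in% c(0, 1, 2))) {
    bad <- which(!apply(vals, 1, function(r) all(is.na(r) | r %in% 0:2)))[1]
    stop("malformed .raw record at data line ", bad,
         ": genotypes must be 0/1/2/NA")
  }
  genotype_matrix(vals, sample_ids = as.character(d$IID), snp_ids = ids,
                  counted_allele = alle)
}

read_vcf_gt <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- strsplit(gsub("\\|", "/", gt), "/")
  ploidy <- lengths(alleles)
  ploidy[is.na(gt)] <- 2L
  if (any(ploidy != 2L)) {
    stop("unsupported input: mixed or non-diploid ploidy in GT field")
  }
  dos <- vapply(alleles, function(a) {
    if (any(is.na(a)) || any(a == ".")) return(NA_real_)
    sum(a != "0")
  }, numeric(1))
  vals <- t(matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt)))
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop class
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(vals, sample_ids = colnames(gt), snp_ids = ids,
                  chromosome = fix[, "CHROM"],
                  position = as.integer(fix[, "POS"]),
                  counted_allele = fix[, "ALT"])
}

#' Write a genotype panel to PLINK .raw or minimal VCF
#'
#' The .raw writer emits the six standard leading columns (PAT/MAT/SEX 0,
#' PHENOTYPE -9) and dosage columns named \code{<snp>_<counted allele>}.
#' The VCF writer emits a minimal GT-only VCFv4.2 body; the counted allele is
#' written as ALT (REF fixed to \code{"A"}/\code{"G"} placeholders when the
#' panel carries no real alleles).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @param format \code{"plink_raw"} or \code{"vcf"}.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("plink_raw", "vcf")) {
  stopifnot(inherits(g, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "plink_raw") {
    d <- data.frame(FID = g$sample_ids, IID = g$sample_ids, PAT = 0L,
                    MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                    check.names = FALSE, stringsAsFactors = FALSE)
    vals <- g$values
    colnames(vals) <- paste0(g$snp_ids, "_", g$counted_allele)
    utils::write.table(cbind(d, as.data.frame(vals)), path,
                       quote = FALSE, row.names = FALSE)
  } else {
    ref <- ifelse(g$counted_allele == "A", "G", "A")
    gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    body <- apply(g$values, 2, function(col) {
      out <- rep("./.", length(col))
      obs <- !is.na(col)
      out[obs] <- gtmap[as.character(col[obs])]
      out
    })
    pos <- ifelse(g$position > 0, g$position,
                  seq_along(g$snp_ids))  # VCF POS must be >= 1
    chrom <- ifelse(g$chromosome == "0", "1", g$chromosome)
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$sample_ids), collapse = "\t"),
               paste(chrom, pos, g$snp_ids, ref, g$counted_allele, ".", ".",
                     ".", "GT", apply(t(body), 1, paste, collapse = "\t"),
                     sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write phenotypes and fixed effects to CSV
#'
#' @param y a \code{\link{bivariate_phenotypes}} object.
#' @param fx optional \code{\link{fixed_effects_table}} for the same samples;
#'   factor columns are appended.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(y, path, fx = NULL) {
  d <- as.data.frame(y)
  if (!is.null(fx)) {
    stopifnot(identical(fx$sample_ids, y$sample_ids))
    for (nm in names(fx$factors)) d[[nm]] <- as.character(fx$factors[[nm]])
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read phenotypes (and optional factor columns) from CSV
#'
#' @param path CSV with columns \code{sample_id}, two trait columns, and any
#'   further columns treated as categorical factors.
#' @return List with \code{phenotypes} and \code{factors} (\code{NULL} if the
#'   file has no factor columns).
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) < 3 || names(d)[1] != "sample_id") {
    stop("expected columns: sample_id, <trait1>, <trait2>[, factors...]")
  }
  y <- bivariate_phenotypes(d$sample_id, d[[2]], d[[3]],
                            trait_names = names(d)[2:3])
  fx <- NULL
  if (ncol(d) > 3) {
    fx <- fixed_effects_table(d$sample_id,
                              lapply(d[-(1:3)], identity))
  }
  list(phenotypes = y, factors = fx)
}

#' Save / load a simulation configuration as YAML
#'
#' @param config a \code{\link{sim_config}}.
#' @param path YAML file path.
#' @return \code{write_sim_config}: \code{path} invisibly;
#'   \code{read_sim_config}: a \code{sim_config}.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # named atomic vectors must become maps to keep their names in YAML
  x$fixed_effect_levels <- as.list(x$fixed_effect_levels)
  x$fixed_effect_sds <- as.list(x$fixed_effect_sds)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$fixed_effect_levels <- unlist(x$fixed_effect_levels)
  x$fixed_effect_sds <- unlist(x$fixed_effect_sds)
  do.call(sim_config, x)
}
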