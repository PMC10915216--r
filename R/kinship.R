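#' Per-SNP counted-allele frequencies
#'
#' @param g a complete \code{\link{genotype_matrix}}.
#' @return Object of class \code{allele_freqs}: list with \code{p} (counted
#'   allele) and \code{q = 1 - p}, one entry per SNP. Frequencies are column
#'   means of the dosage divided by 2, computed from the analyzed panel
#'   itself.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$values)) stop("genotypes must be complete; impute first")
  p <- colMeans(g$values) / 2
  mono <- p == 0 | p == 1
  if (any(mono)) {
    stop("monomorphic SNPs must be removed before frequency computation: ",
         paste(g$snp_ids[mono][seq_len(min(5, sum(mono)))], collapse = ", "))
  }
  structure(list(p = p, q = 1 - p, snp_ids = g$snp_ids),
            class = "allele_freqs")
}

#' Genomic relationship matrix container
#'
#' @param values n x n symmetric numeric matrix.
#' @param kind \code{"additive"}, \code{"dominance"} or \code{"epistatic"}.
#' @param denominator the normalizing scalar used in construction.
#' @param sample_ids character vector.
#' @return Object of class \code{grm}.
#' @export
relationship_matrix <- function(values, kind, denominator, sample_ids) {
  kind <- match.arg(kind, c("additive", "dominance", "epistatic"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values)))) {
    stop("relationship matrix must be symmetric")
  }
  values <- (values + t(values)) / 2
  if (denominator <= 0) stop("denominator must be positive")
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, kind = kind, denominator = denominator,
                 sample_ids = as.character(sample_ids)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm (", x$kind, "): ", nrow(x$values), " x ", ncol(x$values),
      ", denominator ", format(x$denominator), "\n", sep = "")
  cat("  mean diagonal:", round(mean(diag(x$values)), 4), "\n")
  invisible(x)
}

#' Additive genomic relationship matrix
#'
#' VanRaden-style first method: columns of the dosage matrix are centered by
#' twice the counted-allele frequency, \eqn{A = Z Z' / \sum_i 2 p_i q_i}.
#'
#' @param g a complete \code{\link{genotype_matrix}}.
#' @param freqs \code{\link{allele_frequencies}} output; computed from
#'   \code{g} when omitted.
#' @return A \code{grm} with \code{kind = "additive"}.
#' @export
additive_grm <- function(g, freqs = allele_frequencies(g)) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(freqs, "allele_freqs"))
  if (anyNA(g$values)) stop("genotypes must be complete; impute first")
  p <- freqs$p
  denom <- sum(2 * p * freqs$q)
  if (denom <= 0) stop("zero denominator: no polymorphic SNPs")
  Z <- sweep(g$values, 2, 2 * p)
  relationship_matrix(tcrossprod(Z) / denom, "additive", denom, g$sample_ids)
}

#' Dominance genomic relationship matrix
#'
#' Heterozygosity coding (default): the incidence entry is
#' \eqn{1 - 2 p_i q_i} when individual k is heterozygous at SNP i and
#' \eqn{-2 p_i q_i} otherwise (both homozygote classes alike), with
#' denominator \eqn{\sum_i 2 p_i q_i (1 - 2 p_i q_i)}. The
#' \code{"genotypic"} variant uses the classical dominance-deviation coding
#' \eqn{-2p_i^2} / \eqn{2 p_i q_i} / \eqn{-2q_i^2} for dosages 0/1/2 with
#' denominator \eqn{\sum_i (2 p_i q_i)^2}; the two codings differ and the
#' default follows the heterozygosity form used in the multi-kernel model
#' this package implements.
#'
#' @param g a complete \code{\link{genotype_matrix}} with integer dosages.
#' @param freqs \code{\link{allele_frequencies}} output.
#' @param coding \code{"heterozygosity"} (default) or \code{"genotypic"}.
#' @return A \code{grm} with \code{kind = "dominance"}.
#' @export
dominance_grm <- function(g, freqs = allele_frequencies(g),
                          coding = c("heterozygosity", "genotypic")) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(freqs, "allele_freqs"))
  coding <- match.arg(coding)
  V <- g$values
  if (anyNA(V)) stop("genotypes must be complete; impute first")
  p <- freqs$p; q <- freqs$q
  pq2 <- 2 * p * q
  if (coding == "heterozygosity") {
    H <- sweep(0 + (V == 1), 2, pq2, function(z, c) ifelse(z == 1, 1 - c, -c))
    denom <- sum(pq2 * (1 - pq2))
  } else {
    H <- matrix(0, nrow(V), ncol(V))
    for (j in seq_len(ncol(V))) {
      H[, j] <- c(-2 * p[j]^2, pq2[j], -2 * q[j]^2)[V[, j] + 1L]
    }
    denom <- sum(pq2^2)
  }
  if (denom <= 0) stop("zero denominator in dominance matrix")
  relationship_matrix(tcrossprod(H) / denom, "dominance", denom, g$sample_ids)
}

#' Additive-by-additive epistatic relationship matrix
#'
#' Normalized Hadamard square of the additive matrix:
#' \eqn{AA = (A \odot A) / (tr(A \odot A) / n)}, so the trace of the result
#' equals n exactly.
#'
#' @param a an additive \code{grm}.
#' @return A \code{grm} with \code{kind = "epistatic"}.
#' @export
epistatic_grm <- function(a) {
  stopifnot(inherits(a, "grm"))
  if (a$kind != "additive") stop("epistatic_grm expects an additive grm")
  AA <- a$values * a$values
  n <- nrow(AA)
  tr <- sum(diag(AA))
  if (tr <= 0) stop("zero trace in Hadamard square")
  relationship_matrix(AA / (tr / n), "epistatic", tr / n, a$sample_ids)
}

#' Write / read a relationship matrix as a whitespace table
#'
#' Plain-text format: a comment line carrying kind and denominator, a header
#' line of sample ids, then the matrix rows.
#'
#' @param x a \code{grm}.
#' @param path file path.
#' @return \code{write_grm}: \code{path} invisibly; \code{read_grm}: a
#'   \code{grm}.
#' @export
write_grm <- function(x, path) {
  stopifnot(inherits(x, "grm"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# kind=%s denominator=%.15g", x$kind, x$denominator),
             con)
  writeLines(paste(x$sample_ids, collapse = " "), con)
  utils::write.table(format(x$values, digits = 17), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  lines <- readLines(path, n = 2)
  meta <- regmatches(lines[1],
                     regexec("kind=(\\S+) denominator=(\\S+)", lines[1]))[[1]]
  ids <- strsplit(lines[2], " ")[[1]]
  vals <- as.matrix(utils::read.table(path, skip = 2))
  relationship_matrix(unname(vals), meta[2], as.numeric(meta[3]), ids)
}
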