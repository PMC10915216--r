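#' Simulation recipe for a bivariate genomic-prediction study
#'
#' Full configuration for simulating a SNP panel and two genetically
#' correlated traits with additive, dominance and additive-by-additive
#' epistatic architecture. Defaults emulate a sow lifetime-productivity
#' setting: two traits on litter-count and pig-production scales, low
#' narrow-sense but high broad-sense heritability driven by strong epistasis,
#' additive genetic correlation 0.74, and categorical environmental factors
#' (breed, birth year, herd-year-season).
#'
#' Variance fractions are fractions of the target phenotypic variance
#' (\code{trait_sds^2}); the residual fraction is \code{1 - sum(fracs)} and
#' must be non-negative. Each simulated component is rescaled so its realized
#' sample variance hits its requested fraction exactly, which keeps recovery
#' tests tight. Fixed-effect contributions add variance on top of the target
#' scale and are meant to be removed by \code{\link{adjust_phenotypes}}.
#'
#' @param n_samples,n_snps panel dimensions.
#' @param allele_freq_bounds length-2 numeric in (0,1): counted-allele
#'   frequencies are drawn uniformly between these bounds (equal bounds fix
#'   the frequency).
#' @param var_fracs_trait1,var_fracs_trait2 length-3 numeric
#'   (additive, dominance, epistatic) fractions of phenotypic variance.
#' @param genetic_corr additive-effect correlation between the traits.
#' @param dominance_corr,epistasis_corr analogous correlations; default
#'   (\code{NULL}) falls back to \code{genetic_corr}, since only the additive
#'   genetic correlation is typically reported.
#' @param residual_corr residual correlation; the default 0.69, combined with
#'   the default variance fractions, composes to a phenotypic correlation of
#'   about 0.70.
#' @param n_causal_additive,n_causal_dominance,n_epistatic_pairs causal
#'   counts (pairs for epistasis); single-SNP counts must be <=
#'   \code{n_snps}. Defaults (\code{NULL}) give a polygenic architecture:
#'   \code{min(500, n_snps)} causal SNPs per single-SNP component and
#'   \code{min(1000, 2 n_snps)} interacting pairs.
#' @param trait_means,trait_sds length-2 location/scale of the output traits.
#' @param fixed_effect_levels named integer vector: number of levels per
#'   categorical factor.
#' @param fixed_effect_sds named numeric vector: SD of the per-level effects,
#'   in units of the trait SD.
#' @param missing_rate fraction of genotypes set missing uniformly at random.
#' @param seed integer seed controlling all randomness.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 2000, n_snps = 5000,
                       allele_freq_bounds = c(0.05, 0.5),
                       var_fracs_trait1 = c(0.06, 0.11, 0.36),
                       var_fracs_trait2 = c(0.10, 0.12, 0.20),
                       genetic_corr = 0.74,
                       dominance_corr = NULL, epistasis_corr = NULL,
                       residual_corr = 0.69,
                       n_causal_additive = NULL, n_causal_dominance = NULL,
                       n_epistatic_pairs = NULL,
                       trait_means = c(4.5, 48),
                       trait_sds = c(sqrt(0.53), sqrt(153.7)),
                       fixed_effect_levels = c(breed = 2L, birth_year = 13L,
                                               herd_year_season = 27L),
                       fixed_effect_sds = c(breed = 0.3, birth_year = 0.3,
                                            herd_year_season = 0.3),
                       missing_rate = 0, seed = 1L) {
  if (n_samples < 1 || n_snps < 1) stop("n_samples and n_snps must be positive")
  if (length(allele_freq_bounds) != 2 ||
      any(allele_freq_bounds <= 0) || any(allele_freq_bounds >= 1) ||
      allele_freq_bounds[1] > allele_freq_bounds[2]) {
    stop("allele_freq_bounds must be ordered and inside (0, 1)")
  }
  chk_fracs <- function(f, nm) {
    if (length(f) != 3 || any(f < 0) || any(f > 1)) {
      stop(nm, " must be 3 fractions in [0, 1]")
    }
    if (sum(f) > 1) stop(nm, " must sum to <= 1 (residual fraction >= 0)")
    f
  }
  var_fracs_trait1 <- chk_fracs(var_fracs_trait1, "var_fracs_trait1")
  var_fracs_trait2 <- chk_fracs(var_fracs_trait2, "var_fracs_trait2")
  # polygenic defaults, capped by the panel width
  if (is.null(n_causal_additive)) n_causal_additive <- min(500, n_snps)
  if (is.null(n_causal_dominance)) n_causal_dominance <- min(500, n_snps)
  if (is.null(n_epistatic_pairs)) n_epistatic_pairs <- min(1000, 2 * n_snps)
  if (is.null(dominance_corr)) dominance_corr <- genetic_corr
  if (is.null(epistasis_corr)) epistasis_corr <- genetic_corr
  for (r in c(genetic_corr, dominance_corr, epistasis_corr, residual_corr)) {
    if (abs(r) > 1) stop("correlations must lie in [-1, 1]")
  }
  for (k in c(n_causal_additive, n_causal_dominance)) {
    if (k > n_snps) stop("causal counts must not exceed n_snps")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (!identical(names(fixed_effect_levels), names(fixed_effect_sds))) {
    stop("fixed_effect_levels and fixed_effect_sds must have the same names")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    allele_freq_bounds = allele_freq_bounds,
    var_fracs_trait1 = var_fracs_trait1, var_fracs_trait2 = var_fracs_trait2,
    genetic_corr = genetic_corr, dominance_corr = dominance_corr,
    epistasis_corr = epistasis_corr, residual_corr = residual_corr,
    n_causal_additive = as.integer(n_causal_additive),
    n_causal_dominance = as.integer(n_causal_dominance),
    n_epistatic_pairs = as.integer(n_epistatic_pairs),
    trait_means = trait_means, trait_sds = trait_sds,
    fixed_effect_levels = fixed_effect_levels,
    fixed_effect_sds = fixed_effect_sds,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples x", x$n_snps, "SNPs, seed",
      x$seed, "\n")
  cat("  fracs trait1 (a,d,aa):", paste(x$var_fracs_trait1, collapse = "/"),
      " trait2:", paste(x$var_fracs_trait2, collapse = "/"), "\n")
  cat("  r_g:", x$genetic_corr, " r_e:", x$residual_corr, "\n")
  invisible(x)
}

#' Simulate SNP genotypes under Hardy-Weinberg proportions
#'
#' Draws one counted-allele frequency per SNP from the configured uniform law
#' and samples genotypes as Binomial(2, p) dosages, i.e. Hardy-Weinberg
#' proportions at the drawn frequency. SNPs are assigned cyclically to 18
#' autosomes. Missingness, if requested, is inserted uniformly at random.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{\link{genotype_matrix}} with attribute
#'   \code{"drawn_freqs"} holding the per-SNP simulated frequencies.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples; m <- config$n_snps
  b <- config$allele_freq_bounds
  p <- if (b[1] == b[2]) rep(b[1], m) else stats::runif(m, b[1], b[2])
  vals <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(vals))
    vals[sample.int(length(vals), nmiss)] <- NA
  }
  g <- genotype_matrix(vals,
                       sample_ids = sprintf("S%04d", seq_len(n)),
                       snp_ids = sprintf("SNP%05d", seq_len(m)),
                       chromosome = as.character(rep_len(1:18, m)),
                       position = as.integer(seq_len(m) * 1000L))
  attr(g, "drawn_freqs") <- p
  g
}

#' True simulated genetic values
#'
#' Per-sample additive, dominance and epistatic genetic values for each trait,
#' plus their total. Serves as ground truth for recovery and benchmark tests.
#'
#' @param sample_ids character vector.
#' @param additive,dominance,epistatic n x 2 matrices (trait units).
#' @return Object of class \code{true_genetic_values}; \code{total} is the
#'   exact sum of the three components.
#' @export
true_genetic_values <- function(sample_ids, additive, dominance, epistatic) {
  n <- length(sample_ids)
  for (mm in list(additive, dominance, epistatic)) {
    stopifnot(is.matrix(mm), nrow(mm) == n, ncol(mm) == 2)
  }
  structure(list(sample_ids = as.character(sample_ids), additive = additive,
                 dominance = dominance, epistatic = epistatic,
                 total = additive + dominance + epistatic),
            class = "true_genetic_values")
}

#' @export
print.true_genetic_values <- function(x, ...) {
  cat("true_genetic_values:", length(x$sample_ids), "samples\n")
  v <- sapply(list(a = x$additive, d = x$dominance, aa = x$epistatic,
                   total = x$total), function(mm) apply(mm, 2, stats::var))
  print(round(v, 4))
  invisible(x)
}

# rescale a vector to an exact target sample variance (0 target -> zeros)
rescale_var <- function(v, target) {
  if (target == 0) return(v * 0)
  s <- stats::var(v)
  if (s == 0) stop("cannot rescale a constant component to nonzero variance")
  v * sqrt(target / s)
}

# draw k correlated bivariate-normal effect pairs
rmvn2 <- function(k, rho) {
  z1 <- stats::rnorm(k)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(k)
  cbind(z1, z2)
}

#' Simulate correlated additive, dominance and epistatic genetic values
#'
#' Additive values are centered genotype scores times bivariate-normal SNP
#' effects at the causal set; dominance values use the heterozygosity coding
#' of the dominance relationship matrix (1 - 2pq for heterozygotes, -2pq
#' otherwise); epistatic values are products of centered scores at random SNP
#' pairs (additive-by-additive, second order only). Each component is rescaled
#' after simulation so its realized sample variance equals its requested
#' fraction of the target phenotypic variance exactly.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genotypes a complete (no missing) \code{\link{genotype_matrix}}
#'   from \code{\link{simulate_genotypes}} or \code{\link{impute_missing}}.
#' @return A \code{\link{true_genetic_values}} object.
#' @export
simulate_effects <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  G <- genotypes$values
  if (anyNA(G)) stop("genotypes must be complete; impute first")
  n <- nrow(G); m <- ncol(G)
  set.seed(config$seed + 1L)
  tv <- config$trait_sds^2
  fr <- rbind(config$var_fracs_trait1, config$var_fracs_trait2)
  for (j in 1:3) {
    counts <- c(config$n_causal_additive, config$n_causal_dominance,
                config$n_epistatic_pairs)[j]
    if (any(fr[, j] > 0) && counts == 0) {
      stop("nonzero variance fraction requested with zero causal count for ",
           c("additive", "dominance", "epistatic")[j], " component")
    }
  }
  p <- colMeans(G) / 2
  W <- sweep(G, 2, 2 * p)                       # centered additive scores
  comp <- function(scores, k_causal, rho, fracs) {
    if (all(fracs == 0)) return(matrix(0, n, 2))
    eff <- rmvn2(ncol(scores), rho)
    raw <- scores %*% eff
    cbind(rescale_var(raw[, 1], fracs[1] * tv[1]),
          rescale_var(raw[, 2], fracs[2] * tv[2]))
  }
  idx_a <- sample.int(m, min(config$n_causal_additive, m))
  add <- comp(W[, idx_a, drop = FALSE], length(idx_a), config$genetic_corr,
              fr[, 1])
  # dominance scores: same coding as the D-matrix construction
  idx_d <- sample.int(m, min(config$n_causal_dominance, m))
  pq2 <- 2 * p[idx_d] * (1 - p[idx_d])
  H <- matrix(0, n, length(idx_d))
  for (j in seq_along(idx_d)) {
    het <- G[, idx_d[j]] == 1
    H[, j] <- ifelse(het, 1 - pq2[j], -pq2[j])
  }
  dom <- comp(H, length(idx_d), config$dominance_corr, fr[, 2])
  # epistatic scores: products of centered scores at random SNP pairs
  npair <- config$n_epistatic_pairs
  i1 <- sample.int(m, npair, replace = npair > m)
  i2 <- sample.int(m, npair, replace = npair > m)
  clash <- which(i1 == i2)
  if (length(clash)) i2[clash] <- 1L + (i2[clash] %% m)
  E <- W[, i1, drop = FALSE] * W[, i2, drop = FALSE]
  epi <- comp(E, npair, config$epistasis_corr, fr[, 3])
  true_genetic_values(genotypes$sample_ids, add, dom, epi)
}

#' Simulate bivariate phenotypes with fixed effects and residual noise
#'
#' Phenotype = trait mean + categorical fixed-effect contributions + total
#' genetic value + bivariate-normal residual. Residual variances are rescaled
#' so each trait's residual hits its fraction (1 - sum of genetic fractions)
#' of the target phenotypic variance exactly; the residual cross-trait
#' correlation is \code{residual_corr}. Fixed-effect level effects are drawn
#' independently per trait with SDs given in units of the trait SD.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genetic a \code{\link{true_genetic_values}} for the same samples.
#' @return List with \code{phenotypes} (\code{bivariate_phenotypes}),
#'   \code{factors} (\code{fixed_effects_table}), \code{fixed_contrib}
#'   (n x 2 matrix of fixed-effect contributions) and \code{residuals}
#'   (n x 2 matrix).
#' @export
simulate_bivariate_phenotypes <- function(config, genetic) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genetic, "true_genetic_values"))
  n <- length(genetic$sample_ids)
  if (n != config$n_samples) stop("genetic values do not match config samples")
  set.seed(config$seed + 2L)
  tv <- config$trait_sds^2
  fr_res <- c(1 - sum(config$var_fracs_trait1),
              1 - sum(config$var_fracs_trait2))
  facs <- list(); fixed <- matrix(0, n, 2)
  for (nm in names(config$fixed_effect_levels)) {
    L <- config$fixed_effect_levels[[nm]]
    lev <- sample.int(L, n, replace = TRUE)
    sdl <- config$fixed_effect_sds[[nm]] * config$trait_sds
    eff <- cbind(stats::rnorm(L, 0, sdl[1]), stats::rnorm(L, 0, sdl[2]))
    fixed <- fixed + eff[lev, , drop = FALSE]
    facs[[nm]] <- factor(paste0(substr(nm, 1, 1), lev))
  }
  if (any(fr_res > 0)) {
    E <- rmvn2(n, config$residual_corr)
    E <- cbind(rescale_var(E[, 1], fr_res[1] * tv[1]),
               rescale_var(E[, 2], fr_res[2] * tv[2]))
  } else {
    E <- matrix(0, n, 2)
  }
  Y <- sweep(fixed + genetic$total + E, 2, config$trait_means, "+")
  list(phenotypes = bivariate_phenotypes(genetic$sample_ids, Y[, 1], Y[, 2],
                                         trait_names = c("LNL", "LPP")),
       factors = fixed_effects_table(genetic$sample_ids, facs),
       fixed_contrib = fixed, residuals = E)
}

#' Run the full simulation pipeline
#'
#' Convenience wrapper: genotypes, genetic values, phenotypes and factors in
#' one call, fully determined by the configuration (including its seed).
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{genotypes}, \code{genetic}, \code{phenotypes},
#'   \code{factors}, \code{fixed_contrib}, \code{residuals}, \code{config}.
#' @export
simulate_study <- function(config) {
  g <- simulate_genotypes(config)
  if (config$missing_rate > 0) g <- impute_missing(g)
  gv <- simulate_effects(config, g)
  ph <- simulate_bivariate_phenotypes(config, gv)
  c(list(genotypes = g, genetic = gv), ph, list(config = config))
}
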