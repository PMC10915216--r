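#' Assemble a full run configuration
#'
#' Bundles the nested configurations of a complete study run. Everything is
#' plain lists/objects so a configuration round-trips through YAML.
#'
#' @param sim a \code{\link{sim_config}}.
#' @param qc list of QC thresholds
#'   (\code{maf_min}, \code{snp_callrate_min}, \code{sample_callrate_min}).
#' @param chain a \code{\link{chain_config}} for variance components.
#' @param pred_chain a \code{\link{chain_config}} for the prediction models.
#' @param cnn,lcnn \code{\link{network_spec}}s.
#' @param train a \code{\link{training_config}}.
#' @param n_folds CV folds.
#' @param dl_replicates network replicates per fold.
#' @param seed global seed (folds, orchestration).
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(sim = sim_config(),
                       qc = list(maf_min = 0.05, snp_callrate_min = 0.90,
                                 sample_callrate_min = 0.90),
                       chain = chain_config(),
                       pred_chain = chain_config(n_iter = 4000,
                                                 burn_in = 1000),
                       cnn = network_spec("cnn", 28, 86, 0.28),
                       lcnn = network_spec("lcnn", 25, 91, 0.34),
                       train = training_config(),
                       n_folds = 5, dl_replicates = 10, seed = 1L) {
  structure(list(sim = sim, qc = qc, chain = chain, pred_chain = pred_chain,
                 cnn = cnn, lcnn = lcnn, train = train,
                 n_folds = as.integer(n_folds),
                 dl_replicates = as.integer(dl_replicates),
                 seed = as.integer(seed)), class = "run_config")
}

#' Simulate a study and write its files
#'
#' Runs the simulator end to end and writes genotypes (PLINK .raw),
#' phenotypes + factors (CSV), true genetic values (CSV) and the resolved
#' simulation configuration (YAML) into \code{outdir}.
#'
#' @param config a \code{\link{run_config}} (its \code{sim} part is used).
#' @param outdir output directory (created if needed).
#' @return Invisibly, the \code{\link{simulate_study}} result.
#' @export
cmd_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(config$sim)
  write_genotypes(sim$genotypes, file.path(outdir, "genotypes.raw"))
  write_phenotypes(sim$phenotypes, file.path(outdir, "phenotypes.csv"),
                   fx = sim$factors)
  truth <- data.frame(sample_id = sim$genetic$sample_ids,
                      additive1 = sim$genetic$additive[, 1],
                      additive2 = sim$genetic$additive[, 2],
                      dominance1 = sim$genetic$dominance[, 1],
                      dominance2 = sim$genetic$dominance[, 2],
                      epistatic1 = sim$genetic$epistatic[, 1],
                      epistatic2 = sim$genetic$epistatic[, 2],
                      total1 = sim$genetic$total[, 1],
                      total2 = sim$genetic$total[, 2])
  utils::write.csv(truth, file.path(outdir, "true_genetic_values.csv"),
                   row.names = FALSE)
  write_sim_config(config$sim, file.path(outdir, "sim_config.yaml"))
  message("simulated ", config$sim$n_samples, " x ", config$sim$n_snps,
          " study into ", outdir)
  invisible(sim)
}

# Table-1-style report rows from a vc_fit
vc_report <- function(fit) {
  gp <- genetic_parameters(fit)
  get <- function(kind) {
    if (kind %in% fit$kinds) diag(fit$V[[kind]]) else c(0, 0)
  }
  getsd <- function(kind) {
    if (kind %in% fit$kinds) diag(fit$V_sd[[kind]]) else c(0, 0)
  }
  va <- get("a"); vd <- get("d"); vaa <- get("aa"); vr <- diag(fit$R0)
  rows <- list(
    V_a = va, V_d = vd, V_i = vaa,
    `V_a+V_d+V_i` = va + vd + vaa,
    V_R = vr, V_P = va + vd + vaa + vr,
    `h2_narrow` = gp$h2_narrow, `h2_broad` = gp$h2_broad)
  sds <- list(V_a = getsd("a"), V_d = getsd("d"), V_i = getsd("aa"))
  list(rows = rows, sds = sds, r_g = gp$r_g, r_p = gp$r_p,
       trait_names = fit$trait_names)
}

#' Estimate variance components from files and write a report
#'
#' Full variance-component stage: read genotypes and phenotypes, QC, impute,
#' adjust phenotypes for the factor columns, build the additive, dominance
#' and epistatic relationship matrices, run the bivariate multi-kernel Gibbs
#' sampler, and write a report (JSON + CSV) with the eight standard rows
#' (V_a, V_d, V_i, their sum, V_R, V_P, narrow- and broad-sense h2 per
#' trait) plus the genetic and phenotypic correlations.
#'
#' @param config a \code{\link{run_config}}.
#' @param genotype_file PLINK .raw genotype file.
#' @param phenotype_file CSV with sample_id, two traits, factor columns.
#' @param outdir output directory.
#' @return Invisibly, the \code{vc_fit}.
#' @export
cmd_varcomp <- function(config, genotype_file, phenotype_file, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- read_genotypes(genotype_file)
  qcres <- qc_filter(g, config$qc$maf_min, config$qc$snp_callrate_min,
                     config$qc$sample_callrate_min)
  g <- impute_missing(qcres$genotypes)
  write_qc_report(qcres$report, file.path(outdir, "qc_report.json"))
  ph <- read_phenotypes(phenotype_file)
  keep <- ph$phenotypes$sample_ids %in% g$sample_ids
  if (!all(keep)) {
    ids <- ph$phenotypes$sample_ids[keep]
    idx <- which(keep)
    ph$phenotypes <- bivariate_phenotypes(
      ids, ph$phenotypes$trait1[idx], ph$phenotypes$trait2[idx],
      trait_names = ph$phenotypes$trait_names)
    if (!is.null(ph$factors)) {
      ph$factors <- fixed_effects_table(
        ids, lapply(ph$factors$factors, function(f) f[idx]))
    }
  }
  g <- subset_genotypes(g, samples = match(ph$phenotypes$sample_ids,
                                           g$sample_ids))
  yadj <- adjust_phenotypes(ph$phenotypes, ph$factors)
  A <- additive_grm(g)
  kernels <- list(A, dominance_grm(g), epistatic_grm(A))
  fit <- gibbs_multikernel(yadj, kernels, config$chain)
  rep <- vc_report(fit)
  jsonlite::write_json(
    list(components = rep$rows, posterior_sd = rep$sds, r_g = rep$r_g,
         r_p = rep$r_p, traits = rep$trait_names,
         chain = unclass(config$chain)[c("n_iter", "burn_in", "thin",
                                         "seed")]),
    file.path(outdir, "variance_components.json"), auto_unbox = TRUE,
    digits = NA)
  tab <- do.call(rbind, rep$rows)
  utils::write.csv(data.frame(component = rownames(tab),
                              trait1 = tab[, 1], trait2 = tab[, 2]),
                   file.path(outdir, "variance_components.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$samples, file.path(outdir, "posterior_samples.csv"),
                   row.names = FALSE)
  message("variance components written to ", outdir)
  invisible(fit)
}

#' Run the cross-validated benchmark from files
#'
#' Reads genotypes and phenotypes, QCs and adjusts them, and runs the
#' shared-fold benchmark of the configured models, writing the tidy metrics
#' table (CSV) and a fold-mean summary (JSON).
#'
#' @param config a \code{\link{run_config}}.
#' @param genotype_file,phenotype_file input files as in
#'   \code{\link{cmd_varcomp}}.
#' @param outdir output directory.
#' @param models models to benchmark (default: all seven).
#' @return Invisibly, the \code{metrics_table}.
#' @export
cmd_benchmark <- function(config, genotype_file, phenotype_file, outdir,
                          models = c("GBLUP", "Broad", "BRR", "BayesA",
                                     "BayesB", "CNN", "LCNN")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- read_genotypes(genotype_file)
  qcres <- qc_filter(g, config$qc$maf_min, config$qc$snp_callrate_min,
                     config$qc$sample_callrate_min)
  g <- impute_missing(qcres$genotypes)
  ph <- read_phenotypes(phenotype_file)
  g <- subset_genotypes(g, samples = match(ph$phenotypes$sample_ids,
                                           g$sample_ids))
  yadj <- adjust_phenotypes(ph$phenotypes, ph$factors)
  cv <- kfold_split(yadj$sample_ids, config$n_folds, seed = config$seed)
  tab <- run_benchmark(g, yadj, models = models, cv = cv,
                       chain = config$pred_chain,
                       dl_replicates = config$dl_replicates,
                       cnn_spec = config$cnn, lcnn_spec = config$lcnn,
                       cnn_tc = config$train, lcnn_tc = config$train)
  utils::write.csv(as.data.frame(tab), file.path(outdir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary(tab), file.path(outdir, "metrics_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  message("benchmark written to ", outdir)
  invisible(tab)
}
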