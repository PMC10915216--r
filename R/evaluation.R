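#' K-fold cross-validation plan
#'
#' Seeded random permutation of the samples partitioned into near-equal
#' folds (sizes differ by at most one; the remainder goes to the first
#' folds).
#'
#' @param sample_ids character vector.
#' @param n_folds number of folds (default 5, the 80/20 train/test split).
#' @param seed integer seed.
#' @return Object of class \code{cv_plan}: \code{fold} is a named integer
#'   vector of per-sample fold assignments.
#' @export
kfold_split <- function(sample_ids, n_folds = 5, seed = 1L) {
  n <- length(sample_ids)
  if (n_folds > n) stop("n_folds exceeds the number of samples")
  if (n_folds < 2) stop("n_folds must be >= 2")
  set.seed(seed)
  perm <- sample(sample_ids)
  sizes <- rep(n %/% n_folds, n_folds)
  rem <- n %% n_folds
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  fold <- stats::setNames(rep(seq_len(n_folds), times = sizes), perm)
  structure(list(fold = fold[sample_ids], n_folds = as.integer(n_folds),
                 seed = as.integer(seed)), class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("cv_plan:", length(x$fold), "samples in", x$n_folds, "folds (sizes",
      paste(table(x$fold), collapse = "/"), ")\n")
  invisible(x)
}

#' Predictive Pearson correlation per trait
#'
#' @param pred a \code{\link{prediction_result}}.
#' @param obs a \code{\link{bivariate_phenotypes}} containing (at least) the
#'   predicted samples.
#' @return Numeric vector, one correlation per trait.
#' @export
predictive_correlation <- function(pred, obs) {
  stopifnot(inherits(pred, "prediction_result"),
            inherits(obs, "bivariate_phenotypes"))
  idx <- match(pred$sample_ids, obs$sample_ids)
  if (anyNA(idx)) stop("predicted samples missing from observations")
  Y <- phen_matrix(obs)[idx, , drop = FALSE]
  t <- ncol(pred$pred)
  vapply(seq_len(t), function(k) {
    ok <- !is.na(Y[, k])
    if (sum(ok) < 3) stop("need at least 3 paired observations")
    if (stats::sd(pred$pred[ok, k]) == 0 || stats::sd(Y[ok, k]) == 0) {
      stop("undefined metric: zero variance in predictions or observations")
    }
    stats::cor(pred$pred[ok, k], Y[ok, k])
  }, 0)
}

#' Mean squared error of prediction per trait
#'
#' @inheritParams predictive_correlation
#' @return Numeric vector, one MSE per trait (trait units squared).
#' @export
mse <- function(pred, obs) {
  stopifnot(inherits(pred, "prediction_result"),
            inherits(obs, "bivariate_phenotypes"))
  idx <- match(pred$sample_ids, obs$sample_ids)
  if (anyNA(idx)) stop("predicted samples missing from observations")
  Y <- phen_matrix(obs)[idx, , drop = FALSE]
  vapply(seq_len(ncol(pred$pred)), function(k) {
    ok <- !is.na(Y[, k])
    if (!any(ok)) stop("no paired observations")
    mean((pred$pred[ok, k] - Y[ok, k])^2)
  }, 0)
}

#' Cross-validated benchmark of linear and network predictors
#'
#' Runs the shared-fold five-fold benchmark: per fold, each requested model
#' is trained on the training split and scored on the test split by
#' predictive correlation and MSE per trait. Linear models: GBLUP (additive
#' kernel), Broad (additive + dominance + epistatic kernels), BRR, Bayes A
#' and Bayes B (univariate engines combined across traits by
#' eigen-rotation). Network models (CNN, LCNN) are trained
#' \code{dl_replicates} times with different seeds and ensemble-averaged.
#' Folds are shared across models so comparisons are paired. A model failure
#' in a fold is recorded and the benchmark continues.
#'
#' @param g complete \code{\link{genotype_matrix}}.
#' @param y adjusted \code{\link{bivariate_phenotypes}} (the observed values
#'   the predictions are scored against).
#' @param models character subset of
#'   \code{c("GBLUP","Broad","BRR","BayesA","BayesB","CNN","LCNN")}.
#' @param cv a \code{\link{cv_plan}} over the samples of \code{y}.
#' @param chain \code{\link{chain_config}} for the linear models.
#' @param dl_replicates network training replicates per fold (ensembled).
#' @param cnn_spec,lcnn_spec \code{\link{network_spec}}s for the two network
#'   models (defaults: the package's tuned configurations).
#' @param cnn_tc,lcnn_tc \code{\link{training_config}}s.
#' @param pi Bayes B zero-effect proportion.
#' @param extra_models optional named list of functions
#'   \code{function(train_ids, test_ids, fold)} returning a
#'   \code{prediction_result} -- hook for oracle or custom comparators.
#' @return Object of class \code{metrics_table}: data frame with columns
#'   model, trait, fold, correlation, mse; summary (means and standard
#'   errors across folds) via \code{summary()}; failures in
#'   \code{attr(, "failures")}.
#' @export
run_benchmark <- function(g, y,
                          models = c("GBLUP", "Broad", "BRR", "BayesA",
                                     "BayesB", "CNN", "LCNN"),
                          cv = kfold_split(y$sample_ids),
                          chain = chain_config(n_iter = 4000,
                                               burn_in = 1000),
                          dl_replicates = 10,
                          cnn_spec = network_spec("cnn", 28, 86, 0.28),
                          lcnn_spec = network_spec("lcnn", 25, 91, 0.34),
                          cnn_tc = training_config(),
                          lcnn_tc = training_config(),
                          pi = 0.95, extra_models = NULL) {
  stopifnot(inherits(g, "genotype_matrix"),
            inherits(y, "bivariate_phenotypes"), inherits(cv, "cv_plan"))
  models <- match.arg(models, several.ok = TRUE)
  if (!identical(names(cv$fold), y$sample_ids)) {
    stop("cv plan must cover the phenotype samples")
  }
  need_kernels <- any(models %in% c("GBLUP", "Broad"))
  if (need_kernels) {
    A <- additive_grm(g)
    kernels <- list(A)
    if ("Broad" %in% models) {
      kernels <- list(A, dominance_grm(g), epistatic_grm(A))
    }
  }
  rows <- list(); failures <- list()
  add_metrics <- function(pred, test_ids, fold) {
    # an undefined correlation (e.g. a constant predictor) is flagged as NA
    # while the MSE is still reported
    co <- tryCatch(predictive_correlation(pred, y),
                   error = function(e) c(NA_real_, NA_real_))
    ms <- mse(pred, y)
    lapply(1:2, function(k) {
      data.frame(model = pred$model, trait = y$trait_names[k], fold = fold,
                 correlation = co[k], mse = ms[k],
                 stringsAsFactors = FALSE)
    })
  }
  train_nets <- function(spec, tc, g_fold, Ytr, g_test, fold, label) {
    reps <- lapply(seq_len(dl_replicates), function(r) {
      net <- build_network(spec, ncol(g_fold$values),
                           seed = tc$seed + 1000L * fold + r)
      tcr <- tc; tcr$seed <- tc$seed + 1000L * fold + r
      net <- train_network(net, g_fold, Ytr, tcr)
      predict(net, g_test, fold = fold, model_label = label)
    })
    ensemble_average(reps)
  }
  Y <- phen_matrix(y)
  for (fold in seq_len(cv$n_folds)) {
    test_ids <- y$sample_ids[cv$fold == fold]
    train_ids <- y$sample_ids[cv$fold != fold]
    tr <- match(train_ids, y$sample_ids)
    y_tr <- bivariate_phenotypes(train_ids, Y[tr, 1], Y[tr, 2],
                                 trait_names = y$trait_names,
                                 adjusted = y$adjusted)
    g_tr <- subset_genotypes(g, samples = match(train_ids, g$sample_ids))
    g_te <- subset_genotypes(g, samples = match(test_ids, g$sample_ids))
    runs <- list()
    if ("GBLUP" %in% models) {
      runs$GBLUP <- function() {
        p <- predict_gblup_bivariate(y_tr, kernels[1], chain = chain,
                                     samples_test = test_ids)
        p$fold <- fold; p
      }
    }
    if ("Broad" %in% models) {
      runs$Broad <- function() {
        p <- predict_gblup_bivariate(y_tr, kernels, chain = chain,
                                     samples_test = test_ids)
        p$fold <- fold; p
      }
    }
    if ("BRR" %in% models) {
      runs$BRR <- function() {
        p <- predict_brr_bivariate(y_tr, g, chain = chain,
                                   samples_test = test_ids)
        p$fold <- fold; p
      }
    }
    if ("BayesA" %in% models) {
      runs$BayesA <- function() {
        p <- multitrait_svd_combine(y_tr, "bayes_a", g, chain, test_ids)
        p$fold <- fold; p
      }
    }
    if ("BayesB" %in% models) {
      runs$BayesB <- function() {
        p <- multitrait_svd_combine(y_tr, "bayes_b", g, chain, test_ids,
                                    pi = pi)
        p$fold <- fold; p
      }
    }
    if ("CNN" %in% models) {
      runs$CNN <- function() {
        train_nets(cnn_spec, cnn_tc, g_tr, Y[tr, , drop = FALSE], g_te,
                   fold, "CNN")
      }
    }
    if ("LCNN" %in% models) {
      runs$LCNN <- function() {
        train_nets(lcnn_spec, lcnn_tc, g_tr, Y[tr, , drop = FALSE], g_te,
                   fold, "LCNN")
      }
    }
    for (nm in names(extra_models)) {
      local({
        f <- extra_models[[nm]]
        runs[[nm]] <<- function() f(train_ids, test_ids, fold)
      })
    }
    for (nm in names(runs)) {
      res <- tryCatch(runs[[nm]](), error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(model = nm, fold = fold,
                     message = conditionMessage(res))
      } else {
        rows <- c(rows, add_metrics(res, test_ids, fold))
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, class = c("metrics_table", "data.frame"),
            failures = if (length(failures)) do.call(rbind, failures) else
              NULL)
}

#' Fold-mean and standard-error summary of a benchmark
#'
#' Standard error = SD of the per-fold metrics divided by the square root of
#' the number of folds.
#'
#' @param object a \code{metrics_table}.
#' @param ... unused.
#' @return Data frame with one row per model x trait: mean and SE of the
#'   predictive correlation and MSE across folds.
#' @export
summary.metrics_table <- function(object, ...) {
  d <- as.data.frame(object)
  sp <- split(d, list(d$model, d$trait), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(s) {
    data.frame(model = s$model[1], trait = s$trait[1],
               n_folds = nrow(s),
               correlation = mean(s$correlation),
               correlation_se = stats::sd(s$correlation) / sqrt(nrow(s)),
               mse = mean(s$mse),
               mse_se = stats::sd(s$mse) / sqrt(nrow(s)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$trait, -out$correlation), ]
}

#' @export
print.metrics_table <- function(x, ...) {
  cat("metrics_table:", nrow(x), "model x trait x fold rows\n")
  print(summary(x), digits = 3)
  fl <- attr(x, "failures")
  if (!is.null(fl)) {
    cat("failures:\n"); print(fl)
  }
  invisible(x)
}
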