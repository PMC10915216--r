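#' Per-sample genomic predictions
#'
#' @param sample_ids character vector of predicted (test) samples.
#' @param pred numeric matrix, one column per trait (or a vector for one
#'   trait).
#' @param model model label (e.g. \code{"GBLUP"}, \code{"CNN"}).
#' @param fold cross-validation fold id (\code{NA} outside CV).
#' @return Object of class \code{prediction_result}.
#' @export
prediction_result <- function(sample_ids, pred, model, fold = NA_integer_) {
  pred <- as.matrix(pred)
  if (nrow(pred) != length(sample_ids)) {
    stop("one prediction row per sample required")
  }
  structure(list(sample_ids = as.character(sample_ids), pred = pred,
                 model = as.character(model), fold = fold),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("prediction_result:", x$model, "-", length(x$sample_ids), "samples,",
      ncol(x$pred), "trait(s)",
      if (!is.na(x$fold)) paste0("(fold ", x$fold, ")") else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.prediction_result <- function(x, ...) {
  d <- data.frame(sample_id = x$sample_ids, model = x$model, fold = x$fold,
                  stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x$pred))) d[[paste0("pred", j)]] <- x$pred[, j]
  d
}

#' Average an ensemble of prediction replicates
#'
#' Element-wise mean of predictions across replicates of the same model on
#' the same samples. By convexity of squared error, the ensemble MSE never
#' exceeds the mean of the member MSEs.
#'
#' @param results list of \code{\link{prediction_result}} objects covering
#'   identical samples and traits.
#' @return A single \code{prediction_result}.
#' @export
ensemble_average <- function(results) {
  stopifnot(length(results) >= 1)
  r1 <- results[[1]]
  for (r in results) {
    stopifnot(inherits(r, "prediction_result"))
    if (!identical(r$sample_ids, r1$sample_ids) ||
        !identical(dim(r$pred), dim(r1$pred))) {
      stop("ensemble members must cover identical samples and traits")
    }
  }
  pred <- Reduce(`+`, lapply(results, `[[`, "pred")) / length(results)
  prediction_result(r1$sample_ids, pred, r1$model, r1$fold)
}

# closed-form BLUP of total genetic values given variance components.
# Y_train: n_tr x t complete; kernels: list of n x n matrices over
# train+test sample order; V: list of t x t blocks; R0: t x t.
blup_closed_form <- function(Y_train, train_idx, kernels, V, R0) {
  t <- ncol(Y_train)
  n_tr <- length(train_idx)
  Cg <- Reduce(`+`, lapply(seq_along(kernels), function(k) {
    kronecker(kernels[[k]][, train_idx, drop = FALSE], V[[k]])
  }))                                   # (n*t) x (n_tr*t), sample-major blocks
  Vy <- Cg[rep((train_idx - 1) * t, each = t) + rep(seq_len(t), n_tr), ,
           drop = FALSE] + kronecker(diag(n_tr), R0)
  ones <- kronecker(rep(1, n_tr), diag(t))
  yv <- as.vector(t(Y_train))           # sample-major stacking
  Vinv_y <- solve(Vy, cbind(yv, ones))
  mu <- solve(crossprod(ones, Vinv_y[, -1, drop = FALSE]),
              crossprod(ones, Vinv_y[, 1]))
  alpha <- solve(Vy, yv - ones %*% mu)
  ghat <- Cg %*% alpha                  # (n*t) stacked sample-major
  list(g = matrix(ghat, ncol = t, byrow = TRUE), mu = drop(mu))
}

#' Bivariate (or univariate) GBLUP prediction
#'
#' Mixed-model prediction of total genetic values for unphenotyped samples
#' from one or more genomic relationship matrices. With a
#' \code{\link{chain_config}}, prediction is fully Bayesian: test samples
#' enter the Gibbs run with missing phenotypes (data augmentation) and the
#' prediction is the posterior mean of their total genetic value. With
#' variance components supplied instead, the closed-form BLUP is returned.
#' Partially missing training phenotypes (e.g. one trait masked) are
#' supported on the Gibbs route.
#'
#' @param y_train phenotypes for the training samples: a
#'   \code{\link{bivariate_phenotypes}} object, or a named numeric vector
#'   for a univariate analysis.
#' @param kernels a \code{grm} or list of \code{grm}s spanning training and
#'   test samples.
#' @param chain a \code{\link{chain_config}} for the Gibbs route
#'   (default route).
#' @param vc for the closed-form route: list with \code{V} (list of t x t
#'   blocks, one per kernel, in kernel order) and \code{R0} (t x t); for one
#'   trait these are scalars.
#' @param samples_test character vector of test sample ids (must be in the
#'   kernels, not in \code{y_train}).
#' @return A \code{\link{prediction_result}} labelled \code{"GBLUP"} (one
#'   kernel) or \code{"Broad"} (several kernels).
#' @export
predict_gblup_bivariate <- function(y_train, kernels, chain = NULL,
                                    vc = NULL, samples_test) {
  if (inherits(kernels, "grm")) kernels <- list(kernels)
  label <- if (length(kernels) > 1) "Broad" else "GBLUP"
  ids_all <- kernels[[1]]$sample_ids
  for (k in kernels) stopifnot(identical(k$sample_ids, ids_all))
  if (inherits(y_train, "bivariate_phenotypes")) {
    ids_tr <- y_train$sample_ids
    Ytr <- phen_matrix(y_train)
  } else {
    ids_tr <- names(y_train)
    if (is.null(ids_tr)) stop("univariate y_train must be a named vector")
    Ytr <- cbind(as.numeric(y_train))
  }
  if (!all(ids_tr %in% ids_all)) stop("training samples missing from kernels")
  if (!all(samples_test %in% ids_all)) stop("test samples missing from kernels")
  if (any(samples_test %in% ids_tr)) stop("test samples overlap training set")
  t <- ncol(Ytr)
  n_all <- length(ids_all)
  tr_idx <- match(ids_tr, ids_all)
  te_idx <- match(samples_test, ids_all)
  kmats <- lapply(kernels, `[[`, "values")
  if (!is.null(vc)) {
    if (anyNA(Ytr)) stop("closed-form BLUP requires complete training data")
    V <- lapply(vc$V, function(v) matrix(as.numeric(v), t, t))
    R0 <- matrix(as.numeric(vc$R0), t, t)
    if (length(V) != length(kernels)) {
      stop("one variance block per kernel required")
    }
    sol <- blup_closed_form(Ytr, tr_idx, kmats, V, R0)
    pred <- sol$g[te_idx, , drop = FALSE]
  } else {
    if (is.null(chain)) chain <- chain_config()
    Y <- matrix(NA_real_, n_all, t)
    Y[tr_idx, ] <- Ytr
    res <- gibbs_kernel_sampler(Y, kmats, chain,
                                kinds = paste0("k", seq_along(kmats)))
    pred <- res$G_mean[te_idx, , drop = FALSE]
  }
  prediction_result(samples_test, pred, label)
}
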