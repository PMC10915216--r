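#' Hyperparameter search bounds
#'
#' Box bounds for the network hyperparameters. Integer dimensions
#' (\code{kernel_size}, \code{n_neurons}, \code{batch_size}) are rounded to
#' the nearest integer at evaluation time.
#'
#' @param kernel_size,n_neurons,dropout_rate,learning_rate,batch_size
#'   length-2 numeric \code{c(lower, upper)} per dimension.
#' @return Object of class \code{search_bounds}.
#' @export
search_bounds <- function(kernel_size = c(10, 50), n_neurons = c(20, 200),
                          dropout_rate = c(0, 0.5),
                          learning_rate = c(1e-5, 1e-3),
                          batch_size = c(16, 512)) {
  b <- list(kernel_size = kernel_size, n_neurons = n_neurons,
            dropout_rate = dropout_rate, learning_rate = learning_rate,
            batch_size = batch_size)
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2 || b[[nm]][1] > b[[nm]][2]) {
      stop("bounds for ", nm, " must be an ordered pair")
    }
  }
  structure(b, class = "search_bounds",
            integer_dims = c("kernel_size", "n_neurons", "batch_size"))
}

#' Nested split of a training fold for hyperparameter optimization
#'
#' Takes 80\% of the supplied training samples for the optimization stage,
#' then splits that subset 80/20 into optimization-training and validation
#' sets. Seeded and disjoint by construction.
#'
#' @param sample_ids training-fold sample ids (>= 25).
#' @param seed integer seed.
#' @return List with \code{opt_train}, \code{opt_valid} and \code{unused}
#'   (the held-out 20\% of the fold).
#' @export
bo_split <- function(sample_ids, seed = 1L) {
  n <- length(sample_ids)
  if (n < 25) stop("at least 25 samples are required for the nested split")
  set.seed(seed)
  used <- sample(sample_ids, floor(0.8 * n))
  tr <- sample(used, floor(0.8 * length(used)))
  list(opt_train = tr, opt_valid = setdiff(used, tr),
       unused = setdiff(sample_ids, used))
}

# squared-exponential GP fit on [0,1]^d coordinates with marginal-likelihood
# model selection over a small (length-scale, noise) grid
gp_fit <- function(X, y) {
  ys <- (y - mean(y)) / max(stats::sd(y), 1e-12)
  D2 <- as.matrix(stats::dist(X))^2
  best <- NULL
  for (ell in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    for (noise in c(1e-4, 1e-2, 1e-1)) {
      Kn <- exp(-D2 / (2 * ell^2)) + diag(noise + 1e-8, nrow(X))
      ch <- tryCatch(chol(Kn), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), ys))
      ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
      if (is.null(best) || ll > best$ll) {
        best <- list(ll = ll, ell = ell, noise = noise, chol = ch,
                     alpha = alpha)
      }
    }
  }
  best$X <- X; best$ym <- mean(y); best$ysd <- max(stats::sd(y), 1e-12)
  best
}

gp_predict <- function(fit, Xnew) {
  D2 <- outer(rowSums(Xnew^2), rowSums(fit$X^2), "+") -
    2 * Xnew %*% t(fit$X)
  Ks <- exp(-pmax(D2, 0) / (2 * fit$ell^2))
  mu <- drop(Ks %*% fit$alpha)
  var <- pmax(1 - colSums(forwardsolve(t(fit$chol), t(Ks))^2), 1e-12)
  list(mean = mu * fit$ysd + fit$ym, sd = sqrt(var) * fit$ysd)
}

round_point <- function(p, bounds) {
  for (nm in attr(bounds, "integer_dims")) p[[nm]] <- round(p[[nm]])
  p
}

unit_to_point <- function(u, bounds) {
  p <- stats::setNames(as.list(
    vapply(seq_along(bounds), function(d) {
      bounds[[d]][1] + u[d] * (bounds[[d]][2] - bounds[[d]][1])
    }, 0)), names(bounds))
  round_point(p, bounds)
}

#' One replicate of Gaussian-process Bayesian optimization with UCB
#'
#' Evaluates \code{n_init} seeded random points, then repeats: fit a
#' squared-exponential GP surrogate (with jitter and a small
#' length-scale/noise grid selected by marginal likelihood) to all trials on
#' bounds-normalized coordinates, maximize the upper confidence bound
#' (mean + kappa sd) over a seeded Latin-hypercube candidate set, and
#' evaluate the winner. Maximization; higher objective is better.
#'
#' @param objective function taking a named list of hyperparameters (integer
#'   dimensions already rounded) and returning a finite scalar.
#' @param bounds a \code{\link{search_bounds}}.
#' @param n_init random initial evaluations (default 20).
#' @param n_acq acquisition rounds (default 50, for a 70-evaluation budget).
#' @param kappa UCB exploration weight.
#' @param n_candidates candidate points per acquisition round.
#' @param seed integer seed.
#' @return Object of class \code{bo_result}: \code{trials} data frame
#'   (iteration, phase, point, score), \code{best} (point and score).
#' @export
bayes_opt_loop <- function(objective, bounds, n_init = 20, n_acq = 50,
                           kappa = 2, n_candidates = 2048, seed = 1L) {
  stopifnot(inherits(bounds, "search_bounds"))
  d <- length(bounds)
  set.seed(seed)
  U <- matrix(stats::runif(n_init * d), n_init, d)
  trials <- list(); Upts <- NULL
  evaluate <- function(u, it, phase) {
    p <- unit_to_point(u, bounds)
    val <- tryCatch(objective(p), error = function(e) NaN)
    if (!is.finite(val)) {
      warning("objective returned a non-finite value at iteration ", it,
              "; trial skipped")
      val <- NA_real_
    }
    c(list(iteration = it, phase = phase, score = val), p)
  }
  for (i in seq_len(n_init)) {
    trials[[i]] <- evaluate(U[i, ], i, "random_init")
    Upts <- rbind(Upts, U[i, ])
  }
  for (j in seq_len(n_acq)) {
    scores <- vapply(trials, `[[`, 0, "score")
    ok <- is.finite(scores)
    if (!any(ok)) stop("all trials returned non-finite objective values")
    fit <- gp_fit(Upts[ok, , drop = FALSE], scores[ok])
    cand <- as.matrix(lhs::randomLHS(n_candidates, d))
    pr <- gp_predict(fit, cand)
    u <- cand[which.max(pr$mean + kappa * pr$sd), ]
    it <- n_init + j
    trials[[it]] <- evaluate(u, it, "acquisition")
    Upts <- rbind(Upts, u)
  }
  tr <- do.call(rbind, lapply(trials, function(x) as.data.frame(x)))
  okr <- tr[is.finite(tr$score), ]
  best <- okr[which.max(okr$score), ]
  structure(list(trials = tr, best = best, bounds = bounds, seed = seed),
            class = "bo_result")
}

#' @export
print.bo_result <- function(x, ...) {
  cat("bo_result:", nrow(x$trials), "trials; best score",
      round(x$best$score, 4), "\n")
  print(x$best[setdiff(names(x$best), c("iteration", "phase", "score"))],
        row.names = FALSE)
  invisible(x)
}

#' Replicated Bayesian optimization with ensemble-averaged optimum
#'
#' Runs \code{\link{bayes_opt_loop}} once per replicate seed, extracts each
#' replicate's best hyperparameter point, and reports the per-dimension mean
#' across replicate bests (integer dimensions rounded to nearest) as the
#' model-averaged configuration.
#'
#' @param objective,bounds,n_init,n_acq,kappa as in
#'   \code{\link{bayes_opt_loop}}.
#' @param n_replicates number of replicates (>= 1).
#' @param seeds integer seeds, one per replicate (default \code{1:n}).
#' @return Object of class \code{bo_ensemble}: per-replicate results,
#'   \code{replicate_bests} data frame, and the \code{averaged}
#'   configuration (named list).
#' @export
replicate_and_average <- function(objective, bounds, n_replicates = 20,
                                  seeds = seq_len(n_replicates),
                                  n_init = 20, n_acq = 50, kappa = 2) {
  stopifnot(n_replicates >= 1, length(seeds) == n_replicates)
  reps <- lapply(seeds, function(s) {
    bayes_opt_loop(objective, bounds, n_init = n_init, n_acq = n_acq,
                   kappa = kappa, seed = s)
  })
  bests <- do.call(rbind, lapply(reps, function(r) r$best))
  dims <- names(bounds)
  avg <- stats::setNames(as.list(colMeans(bests[, dims, drop = FALSE])),
                         dims)
  avg <- round_point(avg, bounds)
  structure(list(replicates = reps, replicate_bests = bests,
                 averaged = avg), class = "bo_ensemble")
}

#' @export
print.bo_ensemble <- function(x, ...) {
  cat("bo_ensemble:", length(x$replicates), "replicates\n")
  cat("averaged configuration:\n")
  utils::str(x$averaged, give.head = FALSE)
  invisible(x)
}

#' Validation-correlation objective for network hyperparameters
#'
#' Builds the objective used during hyperparameter optimization: train a
#' network with the candidate hyperparameters on the optimization-training
#' samples for a fixed 50 epochs and return the mean over traits of the
#' Pearson correlation between predictions and observed phenotypes on the
#' validation samples.
#'
#' @param g \code{\link{genotype_matrix}} covering the split samples.
#' @param y \code{\link{bivariate_phenotypes}} covering the split samples.
#' @param model_kind \code{"cnn"} or \code{"lcnn"}.
#' @param split output of \code{\link{bo_split}}.
#' @param n_epochs training epochs per evaluation (fixed at 50 by default).
#' @param seed seed for initialization and training.
#' @return A function mapping a named hyperparameter list to a scalar score.
#' @export
make_dl_objective <- function(g, y, model_kind, split, n_epochs = 50,
                              seed = 1L) {
  tr <- match(split$opt_train, g$sample_ids)
  va <- match(split$opt_valid, g$sample_ids)
  ytr_idx <- match(split$opt_train, y$sample_ids)
  yva_idx <- match(split$opt_valid, y$sample_ids)
  stopifnot(!anyNA(tr), !anyNA(va), !anyNA(ytr_idx), !anyNA(yva_idx))
  Y <- phen_matrix(y)
  g_tr <- subset_genotypes(g, samples = tr)
  g_va <- subset_genotypes(g, samples = va)
  function(p) {
    spec <- network_spec(model_kind, kernel_size = p$kernel_size,
                         n_neurons = p$n_neurons,
                         dropout_rate = p$dropout_rate)
    net <- build_network(spec, ncol(g_tr$values), seed = seed)
    tc <- training_config(learning_rate = p$learning_rate,
                          batch_size = min(p$batch_size,
                                           length(split$opt_train)),
                          n_epochs = n_epochs, seed = seed)
    net <- train_network(net, g_tr, Y[ytr_idx, , drop = FALSE], tc)
    pred <- predict(net, g_va)$pred
    mean(vapply(1:2, function(k) {
      stats::cor(pred[, k], Y[yva_idx, k])
    }, 0))
  }
}
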