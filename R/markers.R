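#' @useDynLib bivargp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Posterior summary of marker effects
#'
#' @param snp_ids character vector of SNP ids.
#' @param effects numeric matrix of posterior-mean effects, one column per
#'   trait (trait units per allele dose).
#' @param inclusion per-SNP posterior inclusion probability (Bayes B), or
#'   \code{NULL}.
#' @param pi assumed proportion of SNPs with no effect.
#' @param mu per-trait intercept(s).
#' @param center per-SNP training column means used for centering.
#' @param model model label.
#' @return Object of class \code{marker_effects_posterior}.
#' @export
marker_effects_posterior <- function(snp_ids, effects, inclusion = NULL,
                                     pi = 0, mu, center, model) {
  effects <- as.matrix(effects)
  if (!is.null(inclusion) &&
      (any(inclusion < 0) || any(inclusion > 1))) {
    stop("inclusion probabilities must lie in [0, 1]")
  }
  structure(list(snp_ids = as.character(snp_ids), effects = effects,
                 inclusion = inclusion, pi = pi, mu = mu, center = center,
                 model = model), class = "marker_effects_posterior")
}

#' @export
print.marker_effects_posterior <- function(x, ...) {
  cat("marker_effects_posterior:", x$model, "-", nrow(x$effects), "SNPs x",
      ncol(x$effects), "trait(s)")
  if (!is.null(x$inclusion)) cat(", pi =", x$pi)
  cat("\n")
  invisible(x)
}

#' Predict genomic values from marker effects
#'
#' @param object a \code{marker_effects_posterior}.
#' @param g_test \code{\link{genotype_matrix}} of test samples (same SNPs as
#'   training).
#' @param fold optional fold id carried into the result.
#' @param ... unused.
#' @return A \code{\link{prediction_result}} of genomic values (without the
#'   intercept, which cancels in correlation metrics; it is stored in the
#'   posterior object for completeness).
#' @export
predict.marker_effects_posterior <- function(object, g_test,
                                             fold = NA_integer_, ...) {
  stopifnot(inherits(g_test, "genotype_matrix"))
  if (!identical(g_test$snp_ids, object$snp_ids)) {
    stop("test SNPs do not match the training panel")
  }
  Xc <- sweep(g_test$values, 2, object$center)
  prediction_result(g_test$sample_ids, Xc %*% object$effects, object$model,
                    fold)
}

# shared prior setup: fraction r2 of phenotypic variance to markers
marker_priors <- function(vy, m_eff, r2 = 0.5, nu = 5, nue = 5) {
  list(S = vy * r2 * (nu - 2) / (nu * m_eff),
       Se = vy * (1 - r2) * (nue - 2) / nue, nu = nu, nue = nue)
}

#' Bivariate Bayesian ridge regression
#'
#' Gibbs sampler for \eqn{Y = 1\mu' + X B + E} where rows of the marker
#' effect matrix share one 2 x 2 covariance \eqn{V_b} (a common variance per
#' trait, correlated between traits), giving every SNP the same shrinkage --
#' the marker-space counterpart of GBLUP. Covariances get inverse-Wishart
#' full conditionals.
#'
#' @param y_train a complete \code{\link{bivariate_phenotypes}} for the
#'   training samples.
#' @param g training \code{\link{genotype_matrix}} (training + test samples;
#'   training rows are matched by id).
#' @param chain a \code{\link{chain_config}} (its \code{n_iter},
#'   \code{burn_in} and \code{seed} are used).
#' @param samples_test ids of samples to predict.
#' @param r2 prior fraction of phenotypic variance attributed to markers.
#' @return A \code{\link{prediction_result}} labelled \code{"BRR"}, with the
#'   fitted \code{marker_effects_posterior} attached as attribute
#'   \code{"posterior"}.
#' @export
predict_brr_bivariate <- function(y_train, g, chain = chain_config(),
                                  samples_test, r2 = 0.5) {
  stopifnot(inherits(y_train, "bivariate_phenotypes"),
            inherits(g, "genotype_matrix"))
  Y <- phen_matrix(y_train)
  if (anyNA(Y)) stop("BRR requires complete training phenotypes")
  tr <- match(y_train$sample_ids, g$sample_ids)
  te <- match(samples_test, g$sample_ids)
  if (anyNA(tr) || anyNA(te)) stop("samples missing from genotype panel")
  ctr <- colMeans(g$values[tr, , drop = FALSE])
  X <- sweep(g$values[tr, , drop = FALSE], 2, ctr)
  if (all(diag(stats::cov(Y)) < 1e-12)) {
    # constant training phenotypes: all marker effects are exactly zero
    post <- marker_effects_posterior(g$snp_ids, matrix(0, ncol(X), 2),
                                     NULL, 0, colMeans(Y), ctr, "BRR")
    pred <- predict(post, subset_genotypes(g, samples = te))
    attr(pred, "posterior") <- post
    return(pred)
  }
  msx <- sum(apply(X, 2, stats::var))
  nu0 <- 4; nue <- 4
  S0 <- stats::cov(Y) * r2 / msx          # IW(4, S) has mean S for 2 x 2
  Se <- stats::cov(Y) * (1 - r2)
  set.seed(chain$seed)
  fit <- brr_biv_gibbs(X, Y, chain$n_iter, chain$burn_in, nu0,
                       c(S0[1, 1], S0[1, 2], S0[2, 2]), nue,
                       c(Se[1, 1], Se[1, 2], Se[2, 2]))
  post <- marker_effects_posterior(g$snp_ids, fit$b, NULL, 0, fit$mu, ctr,
                                   "BRR")
  pred <- predict(post, subset_genotypes(g, samples = te))
  attr(pred, "posterior") <- post
  pred
}

bayes_ab_engine <- function(y, X, chain, pi, r2 = 0.5) {
  msx <- sum(apply(X, 2, stats::var))
  pri <- marker_priors(stats::var(y), msx * max(1 - pi, 0.01), r2 = r2)
  bayes_ab_gibbs(X, y, chain$n_iter, chain$burn_in, pi, pri$nu, pri$S,
                 pri$nue, pri$Se)
}

#' Univariate Bayes A marker model
#'
#' Every SNP has its own effect variance with a scaled-inverse-chi-square
#' prior (df 5), so marker effects follow a scaled-t prior marginally and
#' shrinkage is heavier on small effects than in ridge regression.
#'
#' @param y_train named numeric vector of training phenotypes.
#' @param g \code{\link{genotype_matrix}} containing the training samples.
#' @param chain a \code{\link{chain_config}}.
#' @param r2 prior fraction of phenotypic variance attributed to markers.
#' @return A \code{marker_effects_posterior} labelled \code{"BayesA"}.
#' @export
bayes_a_univariate <- function(y_train, g, chain = chain_config(), r2 = 0.5) {
  fit_bayes_ab(y_train, g, chain, pi = 0, label = "BayesA", r2 = r2)
}

#' Univariate Bayes B marker model
#'
#' Spike-and-slab extension of Bayes A: with probability \code{pi} a SNP has
#' exactly zero effect; otherwise its effect variance follows the Bayes A
#' scaled-inverse-chi-square prior. Inclusion indicators are sampled each
#' cycle with the effect integrated out. \code{pi = 0} reduces to Bayes A.
#'
#' @inheritParams bayes_a_univariate
#' @param pi proportion of SNPs assumed to have no effect, in [0, 1).
#' @return A \code{marker_effects_posterior} labelled \code{"BayesB"} with
#'   per-SNP inclusion probabilities.
#' @export
bayes_b_univariate <- function(y_train, g, chain = chain_config(), pi = 0.95,
                               r2 = 0.5) {
  if (pi < 0 || pi >= 1) stop("pi must lie in [0, 1)")
  fit_bayes_ab(y_train, g, chain, pi = pi, label = "BayesB", r2 = r2)
}

fit_bayes_ab <- function(y_train, g, chain, pi, label, r2) {
  stopifnot(inherits(g, "genotype_matrix"), is.numeric(y_train))
  ids <- names(y_train)
  if (is.null(ids)) stop("y_train must be a named vector")
  tr <- match(ids, g$sample_ids)
  if (anyNA(tr)) stop("training samples missing from genotype panel")
  ctr <- colMeans(g$values[tr, , drop = FALSE])
  X <- sweep(g$values[tr, , drop = FALSE], 2, ctr)
  if (stats::var(y_train) < 1e-12) {
    # degenerate constant response: all effects are exactly zero
    return(marker_effects_posterior(
      g$snp_ids, cbind(rep(0, ncol(X))),
      inclusion = if (pi > 0) rep(0, ncol(X)) else NULL, pi = pi,
      mu = mean(y_train), center = ctr, model = label))
  }
  set.seed(chain$seed)
  fit <- bayes_ab_engine(unname(y_train), X, chain, pi, r2)
  marker_effects_posterior(g$snp_ids, cbind(fit$b),
                           inclusion = if (pi > 0) fit$inclusion else NULL,
                           pi = pi, mu = fit$mu, center = ctr, model = label)
}

#' Bivariate prediction from a univariate engine via eigen-rotation
#'
#' Combines two traits for a univariate marker model: the 2 x 2 sample
#' covariance of the training traits is eigen-decomposed, traits are rotated
#' onto the orthogonal component scores, the univariate engine (Bayes A or
#' Bayes B) is fitted to each component, and component predictions are
#' back-rotated to the trait scale. With uncorrelated equal-variance traits
#' the rotation is trivial and the result matches two independent univariate
#' fits.
#'
#' @param y_train complete \code{\link{bivariate_phenotypes}} for training
#'   samples.
#' @param engine \code{"bayes_a"} or \code{"bayes_b"}.
#' @param g \code{\link{genotype_matrix}} spanning training and test samples.
#' @param chain a \code{\link{chain_config}}.
#' @param samples_test ids of samples to predict.
#' @param pi Bayes B zero-effect proportion.
#' @return A \code{\link{prediction_result}} labelled \code{"BayesA"} or
#'   \code{"BayesB"}.
#' @export
multitrait_svd_combine <- function(y_train, engine = c("bayes_a", "bayes_b"),
                                   g, chain = chain_config(), samples_test,
                                   pi = 0.95) {
  engine <- match.arg(engine)
  stopifnot(inherits(y_train, "bivariate_phenotypes"))
  Y <- phen_matrix(y_train)
  if (anyNA(Y)) stop("both traits must be observed on all training samples")
  if (any(apply(Y, 2, stats::var) <= 0)) {
    stop("degenerate trait covariance: a trait has zero variance")
  }
  ctrY <- colMeans(Y)
  E <- eigen(stats::cov(Y), symmetric = TRUE)
  scores <- sweep(Y, 2, ctrY) %*% E$vectors
  te <- match(samples_test, g$sample_ids)
  if (anyNA(te)) stop("test samples missing from genotype panel")
  g_test <- subset_genotypes(g, samples = te)
  preds <- matrix(0, length(samples_test), 2)
  for (k in 1:2) {
    yk <- stats::setNames(scores[, k], y_train$sample_ids)
    ck <- chain
    ck$seed <- chain$seed + (k - 1L)
    post <- if (engine == "bayes_a") {
      bayes_a_univariate(yk, g, ck)
    } else {
      bayes_b_univariate(yk, g, ck, pi = pi)
    }
    preds[, k] <- predict(post, g_test)$pred[, 1]
  }
  back <- preds %*% t(E$vectors)
  prediction_result(samples_test, back,
                    if (engine == "bayes_a") "BayesA" else "BayesB")
}
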