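#' Gibbs chain configuration
#'
#' Settings for the Gibbs samplers. Defaults (20,000 iterations, 5,000
#' burn-in) are desk-scale; production-scale runs of the variance-component
#' model (110,000 / 10,000) and prediction models (10,000 / 5,000) are a
#' matter of raising \code{n_iter}/\code{burn_in}.
#'
#' @param n_iter total Gibbs cycles.
#' @param burn_in cycles discarded (must be < \code{n_iter}).
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param seed integer RNG seed.
#' @param prior_df inverse-Wishart prior degrees of freedom for each
#'   covariance block; \code{NULL} means number of traits + 2 (the smallest
#'   value with a finite prior mean at unit multiplier).
#' @param prior_scale_fraction fraction of the observed phenotypic
#'   (co)variance assigned to each random term's prior scale; \code{NULL}
#'   splits equally among the kernels and the residual.
#' @param fix_residual optional fixed residual covariance (t x t matrix or
#'   scalar for one trait); when supplied the residual block is not sampled.
#' @return Object of class \code{chain_config}.
#' @export
chain_config <- function(n_iter = 20000, burn_in = 5000, thin = 10, seed = 1L,
                         prior_df = NULL, prior_scale_fraction = NULL,
                         fix_residual = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df = prior_df,
                 prior_scale_fraction = prior_scale_fraction,
                 fix_residual = fix_residual),
            class = "chain_config")
}

# eigendecompose a kernel, validating PSD-ness; returns vectors/values with
# near-null components dropped (effects in the null space are identically 0)
kernel_eigen <- function(K, label) {
  e <- eigen(K, symmetric = TRUE)
  mx <- max(e$values)
  if (min(e$values) < -1e-6 * max(1, mx)) {
    stop("kernel '", label, "' is not positive semi-definite ",
         "(min eigenvalue ", format(min(e$values)),
         "); add a small diagonal jitter")
  }
  keep <- e$values > 1e-10 * max(1, mx)
  list(vectors = e$vectors[, keep, drop = FALSE],
       values = pmax(e$values[keep], 1e-12))
}

# draw from an inverse-Wishart with df nu and scale S (t x t)
riwish1 <- function(nu, S) {
  W <- stats::rWishart(1, nu, solve(S))[, , 1]
  solve((W + t(W)) / 2)
}

# vectorized per-eigencomponent bivariate-normal full-conditional draw:
# precision_j = Vinv/lambda_j + Rinv, rhs_j = Rinv %*% W[j, ]
draw_components_2t <- function(W, lam, Vinv, Rinv) {
  P11 <- Vinv[1, 1] / lam + Rinv[1, 1]
  P12 <- Vinv[1, 2] / lam + Rinv[1, 2]
  P22 <- Vinv[2, 2] / lam + Rinv[2, 2]
  det <- P11 * P22 - P12^2
  C11 <- P22 / det; C22 <- P11 / det; C12 <- -P12 / det
  b1 <- Rinv[1, 1] * W[, 1] + Rinv[1, 2] * W[, 2]
  b2 <- Rinv[1, 2] * W[, 1] + Rinv[2, 2] * W[, 2]
  m1 <- C11 * b1 + C12 * b2
  m2 <- C12 * b1 + C22 * b2
  L11 <- sqrt(C11)
  L21 <- C12 / L11
  L22 <- sqrt(pmax(C22 - L21^2, 0))
  z1 <- stats::rnorm(length(lam)); z2 <- stats::rnorm(length(lam))
  cbind(m1 + L11 * z1, m2 + L21 * z1 + L22 * z2)
}

draw_components_1t <- function(W, lam, Vinv, Rinv) {
  vi <- as.numeric(Vinv); ri <- as.numeric(Rinv)
  v <- 1 / (vi / lam + ri)
  m <- v * ri * W[, 1]
  cbind(m + sqrt(v) * stats::rnorm(length(lam)))
}

# core sampler over t in {1, 2} traits; Y is n x t with NA allowed
gibbs_kernel_sampler <- function(Y, kernels, chain, kinds = NULL) {
  n <- nrow(Y); t <- ncol(Y)
  stopifnot(t %in% c(1L, 2L))
  K <- length(kernels)
  if (is.null(kinds)) kinds <- paste0("k", seq_len(K))
  eigs <- lapply(seq_len(K), function(k) {
    kernel_eigen(kernels[[k]], kinds[k])
  })
  nu0 <- if (is.null(chain$prior_df)) t + 2 else chain$prior_df
  frac <- chain$prior_scale_fraction
  if (is.null(frac)) frac <- 1 / (K + 1)
  cc <- stats::complete.cases(Y)
  Sp <- if (sum(cc) > t) stats::cov(Y[cc, , drop = FALSE]) else
    diag(apply(Y, 2, stats::var, na.rm = TRUE), t)
  Sp <- Sp + diag(1e-8 * max(diag(Sp)), t)
  S0 <- frac * Sp * max(nu0 - t - 1, 1)

  fixR <- chain$fix_residual
  if (!is.null(fixR)) fixR <- matrix(as.numeric(fixR), t, t)

  set.seed(chain$seed)
  miss <- is.na(Y)
  any_miss <- any(miss)
  Yimp <- Y
  for (j in seq_len(t)) {
    Yimp[miss[, j], j] <- mean(Y[, j], na.rm = TRUE)
  }
  mu <- colMeans(Yimp)
  V <- lapply(seq_len(K), function(k) frac * Sp)
  R0 <- if (is.null(fixR)) frac * Sp else fixR
  Ustar <- lapply(eigs, function(e) matrix(0, length(e$values), t))
  U <- lapply(seq_len(K), function(k) matrix(0, n, t))
  G <- matrix(0, n, t)

  draw_fun <- if (t == 2L) draw_components_2t else draw_components_1t
  n_keep <- (chain$n_iter - chain$burn_in) %/% chain$thin
  arch <- matrix(NA_real_, n_keep,
                 K * t * (t + 1) / 2 + t * (t + 1) / 2)
  cn <- character(0)
  pairs <- if (t == 2L) list(c(1, 1), c(1, 2), c(2, 2)) else list(c(1, 1))
  for (k in seq_len(K)) {
    cn <- c(cn, paste0("V_", kinds[k], "_",
                       vapply(pairs, function(p) paste0(p[1], p[2]), "")))
  }
  cn <- c(cn, paste0("R0_", vapply(pairs, function(p) paste0(p[1], p[2]), "")))
  colnames(arch) <- cn
  Gsum <- matrix(0, n, t)
  Usum <- lapply(seq_len(K), function(k) matrix(0, n, t))
  musum <- numeric(t)
  kept <- 0L

  for (it in seq_len(chain$n_iter)) {
    # 1. impute missing phenotypes from the residual conditional
    if (any_miss) {
      M <- sweep(G, 2, mu, "+")
      if (t == 1L) {
        idx <- miss[, 1]
        Yimp[idx, 1] <- M[idx, 1] + stats::rnorm(sum(idx), 0, sqrt(R0[1, 1]))
      } else {
        m1 <- miss[, 1] & !miss[, 2]
        m2 <- miss[, 2] & !miss[, 1]
        mb <- miss[, 1] & miss[, 2]
        if (any(m1)) {
          cvar <- R0[1, 1] - R0[1, 2]^2 / R0[2, 2]
          Yimp[m1, 1] <- M[m1, 1] +
            R0[1, 2] / R0[2, 2] * (Yimp[m1, 2] - M[m1, 2]) +
            stats::rnorm(sum(m1), 0, sqrt(max(cvar, 0)))
        }
        if (any(m2)) {
          cvar <- R0[2, 2] - R0[1, 2]^2 / R0[1, 1]
          Yimp[m2, 2] <- M[m2, 2] +
            R0[1, 2] / R0[1, 1] * (Yimp[m2, 1] - M[m2, 1]) +
            stats::rnorm(sum(m2), 0, sqrt(max(cvar, 0)))
        }
        if (any(mb)) {
          Lr <- chol(R0)
          Yimp[mb, ] <- M[mb, , drop = FALSE] +
            matrix(stats::rnorm(2 * sum(mb)), ncol = 2) %*% Lr
        }
      }
    }
    # 2. overall means (flat prior)
    e <- Yimp - G
    mu <- colMeans(e) +
      drop(matrix(stats::rnorm(t), 1) %*% chol(R0 / n))
    Rinv <- solve(R0)
    # 3. per-kernel effects in the kernel eigenbasis, then covariance blocks
    for (k in seq_len(K)) {
      r <- Yimp - sweep(G - U[[k]], 2, mu, "+")
      W <- crossprod(eigs[[k]]$vectors, r)
      Vinv <- solve(V[[k]])
      Ustar[[k]] <- draw_fun(W, eigs[[k]]$values, Vinv, Rinv)
      Unew <- eigs[[k]]$vectors %*% Ustar[[k]]
      G <- G - U[[k]] + Unew
      U[[k]] <- Unew
      Su <- crossprod(Ustar[[k]] / sqrt(eigs[[k]]$values))
      V[[k]] <- riwish1(nu0 + length(eigs[[k]]$values), S0 + Su)
    }
    # 4. residual covariance
    if (is.null(fixR)) {
      e <- Yimp - sweep(G, 2, mu, "+")
      R0 <- riwish1(nu0 + n, S0 + crossprod(e))
    }
    if (!all(is.finite(unlist(V))) || !all(is.finite(R0))) {
      stop("divergent chain: non-finite draw at iteration ", it)
    }
    # 5. archive
    if (it > chain$burn_in && (it - chain$burn_in) %% chain$thin == 0L) {
      kept <- kept + 1L
      row <- numeric(0)
      for (k in seq_len(K)) {
        row <- c(row, vapply(pairs, function(p) V[[k]][p[1], p[2]], 0))
      }
      row <- c(row, vapply(pairs, function(p) R0[p[1], p[2]], 0))
      arch[kept, ] <- row
      Gsum <- Gsum + G
      for (k in seq_len(K)) Usum[[k]] <- Usum[[k]] + U[[k]]
      musum <- musum + mu
    }
  }
  list(samples = as.data.frame(arch[seq_len(kept), , drop = FALSE]),
       G_mean = Gsum / kept,
       U_mean = lapply(Usum, function(u) u / kept),
       mu_mean = musum / kept, kinds = kinds, n = n, t = t)
}

kernel_short <- c(additive = "a", dominance = "d", epistatic = "aa")

#' Univariate multi-kernel Gibbs sampler
#'
#' Single-trait counterpart of \code{\link{gibbs_multikernel}}: variance
#' components get scaled-inverse-chi-square (inverse-Wishart with t = 1) full
#' conditionals and effects are drawn in each kernel's eigenbasis. Missing
#' phenotypes are imputed by data augmentation, which is also how test-set
#' samples are predicted (set their phenotype to \code{NA}).
#'
#' @param y numeric vector (one trait), \code{NA} allowed.
#' @param kernels a \code{grm} or list of \code{grm}s covering the samples of
#'   \code{y} in order.
#' @param chain a \code{\link{chain_config}}.
#' @return List with \code{samples} (thinned variance draws), \code{var}
#'   (posterior-mean variance per kernel), \code{resid_var},
#'   \code{genetic_values} (posterior-mean total genetic value per sample)
#'   and \code{mu}.
#' @export
gibbs_univariate <- function(y, kernels, chain = chain_config()) {
  stopifnot(is.numeric(y), inherits(chain, "chain_config"))
  if (inherits(kernels, "grm")) kernels <- list(kernels)
  kinds <- vapply(kernels, function(k) k$kind, "")
  kmats <- lapply(kernels, `[[`, "values")
  for (k in kmats) stopifnot(nrow(k) == length(y))
  res <- gibbs_kernel_sampler(cbind(y), kmats, chain,
                              kinds = unname(kernel_short[kinds]))
  vcols <- grep("^V_", names(res$samples))
  list(samples = res$samples,
       var = colMeans(res$samples[, vcols, drop = FALSE]),
       resid_var = mean(res$samples$R0_11),
       genetic_values = drop(res$G_mean), mu = res$mu_mean,
       kinds = kinds)
}

#' Bivariate multi-kernel variance-component model
#'
#' Gibbs sampler for the bivariate mixed model
#' \eqn{y = \mu + u_a + u_d + u_{aa} + e} where each random term has
#' covariance \eqn{K \otimes V_k} for its relationship matrix \eqn{K} and an
#' unstructured 2 x 2 trait-covariance block \eqn{V_k}, and
#' \eqn{e \sim N(0, I \otimes R_0)}. Covariance blocks get inverse-Wishart
#' full conditionals; per-kernel effects are drawn in the kernel eigenbasis
#' where the full conditional factorizes into independent 2 x 2 problems.
#' Missing phenotypes are imputed from their residual conditional each cycle
#' (data augmentation), so partially recorded samples are handled exactly.
#'
#' @param y a \code{\link{bivariate_phenotypes}} object (typically adjusted).
#' @param kernels list of \code{grm} objects (additive first by convention;
#'   any subset of additive/dominance/epistatic), all indexed by the samples
#'   of \code{y}.
#' @param chain a \code{\link{chain_config}}.
#' @return Object of class \code{vc_fit}: posterior means and SDs of each
#'   covariance block (\code{V} / \code{V_sd}, \code{R0} / \code{R0_sd}),
#'   the thinned \code{samples} archive, posterior-mean genetic values
#'   (\code{genetic_values}, total and per kernel), and the chain settings.
#' @seealso \code{\link{genetic_parameters}} for heritabilities and
#'   correlations derived from the fit.
#' @export
gibbs_multikernel <- function(y, kernels, chain = chain_config()) {
  stopifnot(inherits(y, "bivariate_phenotypes"), inherits(chain, "chain_config"))
  if (inherits(kernels, "grm")) kernels <- list(kernels)
  kinds <- vapply(kernels, function(k) k$kind, "")
  if (!"additive" %in% kinds) stop("kernels must include an additive grm")
  if (anyDuplicated(kinds)) stop("duplicate kernel kinds")
  for (k in kernels) {
    if (!identical(k$sample_ids, y$sample_ids)) {
      stop("all kernels must be indexed by the phenotype samples, in order")
    }
  }
  Y <- phen_matrix(y)
  res <- gibbs_kernel_sampler(Y, lapply(kernels, `[[`, "values"), chain,
                              kinds = kernel_short[kinds])
  post <- function(block) {
    cols <- grep(paste0("^", block, "_"), names(res$samples))
    s <- res$samples[, cols, drop = FALSE]
    mk <- function(v) matrix(c(v[1], v[2], v[2], v[3]), 2, 2)
    list(mean = mk(colMeans(s)), sd = mk(apply(s, 2, stats::sd)))
  }
  Vs <- lapply(paste0("V_", res$kinds), post)
  R0 <- post("R0")
  names(Vs) <- res$kinds
  structure(list(
    V = lapply(Vs, `[[`, "mean"), V_sd = lapply(Vs, `[[`, "sd"),
    R0 = R0$mean, R0_sd = R0$sd,
    samples = res$samples,
    genetic_values = res$G_mean, kernel_values = res$U_mean,
    mu = res$mu_mean, kinds = res$kinds, kernel_labels = kinds,
    sample_ids = y$sample_ids, trait_names = y$trait_names,
    chain = chain), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Bivariate multi-kernel fit:", length(x$kinds), "kernel(s) (",
      paste(x$kernel_labels, collapse = " + "), "),",
      nrow(x$samples), "retained draws\n")
  for (k in seq_along(x$V)) {
    cat(sprintf("  V_%s diag: %.4g / %.4g\n", x$kinds[k],
                x$V[[k]][1, 1], x$V[[k]][2, 2]))
  }
  cat(sprintf("  R0   diag: %.4g / %.4g\n", x$R0[1, 1], x$R0[2, 2]))
  invisible(x)
}

#' @export
summary.vc_fit <- function(object, ...) {
  gp <- genetic_parameters(object)
  out <- list(fit = object, params = gp)
  class(out) <- "summary.vc_fit"
  out
}

#' @export
print.summary.vc_fit <- function(x, ...) {
  print(x$fit)
  print(x$params)
  invisible(x)
}

#' Variance-component container for two traits
#'
#' Plain container for the four 2 x 2 covariance blocks of the bivariate
#' multi-kernel model, for use when components come from a source other than
#' \code{\link{gibbs_multikernel}} (e.g. published tables).
#'
#' @param V_a,V_d,V_aa,R0 2 x 2 symmetric matrices (dominance/epistatic may
#'   be \code{NULL} for reduced models).
#' @return Object of class \code{variance_components}.
#' @export
variance_components <- function(V_a, V_d = NULL, V_aa = NULL, R0) {
  chk <- function(M, nm) {
    if (is.null(M)) return(NULL)
    M <- as.matrix(M)
    if (!isTRUE(all.equal(M, t(M)))) stop(nm, " must be symmetric")
    if (any(diag(M) < 0)) stop(nm, " must have non-negative diagonal")
    M
  }
  structure(list(V_a = chk(V_a, "V_a"), V_d = chk(V_d, "V_d"),
                 V_aa = chk(V_aa, "V_aa"), R0 = chk(R0, "R0")),
            class = "variance_components")
}

#' Heritabilities and genetic/phenotypic correlations
#'
#' Computes, per trait, narrow-sense heritability
#' \eqn{h^2 = V_a / V_P}, broad-sense heritability
#' \eqn{H^2 = (V_a + V_d + V_{aa}) / V_P}, the additive genetic correlation
#' \eqn{r_g = V_a[1,2] / \sqrt{V_a[1,1] V_a[2,2]}} and the phenotypic
#' correlation from \eqn{V_P = V_a + V_d + V_{aa} + R_0}.
#'
#' @param vc a \code{vc_fit} or \code{\link{variance_components}} object.
#' @param mode \code{"ratio_of_means"} (default): ratios of posterior-mean
#'   components; \code{"mean_of_ratios"}: posterior mean of the per-draw
#'   ratios (only for \code{vc_fit}, where the draw archive is available).
#'   The two differ slightly because the ratio is a nonlinear functional.
#' @return Object of class \code{genetic_parameters} with fields
#'   \code{h2_narrow}, \code{h2_broad} (length 2), \code{r_g}, \code{r_p},
#'   and posterior SDs when a draw archive is available.
#' @export
genetic_parameters <- function(vc, mode = c("ratio_of_means",
                                            "mean_of_ratios")) {
  mode <- match.arg(mode)
  ratios_from <- function(Va, Vd, Vaa, R0) {
    if (is.null(Vd)) Vd <- matrix(0, 2, 2)
    if (is.null(Vaa)) Vaa <- matrix(0, 2, 2)
    Vg <- Va + Vd + Vaa
    Vp <- Vg + R0
    if (any(diag(Vp) <= 0)) stop("phenotypic variance must be positive")
    list(h2_narrow = diag(Va) / diag(Vp),
         h2_broad = diag(Vg) / diag(Vp),
         r_g = Va[1, 2] / sqrt(Va[1, 1] * Va[2, 2]),
         r_p = Vp[1, 2] / sqrt(Vp[1, 1] * Vp[2, 2]))
  }
  if (inherits(vc, "variance_components")) {
    out <- ratios_from(vc$V_a, vc$V_d, vc$V_aa, vc$R0)
    sds <- NULL
  } else if (inherits(vc, "vc_fit")) {
    S <- as.matrix(vc$samples)
    col <- function(nm) if (nm %in% colnames(S)) S[, nm] else 0
    g11 <- col("V_a_11") + col("V_d_11") + col("V_aa_11")
    g12 <- col("V_a_12") + col("V_d_12") + col("V_aa_12")
    g22 <- col("V_a_22") + col("V_d_22") + col("V_aa_22")
    p11 <- g11 + col("R0_11"); p12 <- g12 + col("R0_12")
    p22 <- g22 + col("R0_22")
    M <- cbind(h2_narrow1 = col("V_a_11") / p11,
               h2_narrow2 = col("V_a_22") / p22,
               h2_broad1 = g11 / p11, h2_broad2 = g22 / p22,
               r_g = col("V_a_12") / sqrt(col("V_a_11") * col("V_a_22")),
               r_p = p12 / sqrt(p11 * p22))
    sds <- apply(M, 2, stats::sd)
    if (mode == "mean_of_ratios") {
      m <- colMeans(M)
      out <- list(h2_narrow = unname(m[1:2]), h2_broad = unname(m[3:4]),
                  r_g = unname(m[5]), r_p = unname(m[6]))
    } else {
      Vd <- if ("d" %in% vc$kinds) vc$V[["d"]] else NULL
      Vaa <- if ("aa" %in% vc$kinds) vc$V[["aa"]] else NULL
      out <- ratios_from(vc$V[["a"]], Vd, Vaa, vc$R0)
    }
  } else {
    stop("vc must be a vc_fit or variance_components object")
  }
  structure(c(out, list(sd = sds, mode = mode)),
            class = "genetic_parameters")
}

#' @export
print.genetic_parameters <- function(x, digits = 3, ...) {
  cat("genetic parameters (", x$mode, "):\n", sep = "")
  cat("  h2 narrow:", paste(round(x$h2_narrow, digits), collapse = " / "),
      "\n")
  cat("  h2 broad: ", paste(round(x$h2_broad, digits), collapse = " / "),
      "\n")
  cat("  r_g:", round(x$r_g, digits), "  r_p:", round(x$r_p, digits), "\n")
  invisible(x)
}
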