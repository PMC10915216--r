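# deterministic 1-D quadrature of the exact marginal posterior of the
# genetic variance for y ~ N(mu 1, (s2u + s2e) I) with flat mu, known s2e
# and an inverse-gamma (scaled-inv-chi2) prior on s2u: the independent
# oracle for the single-identity-kernel sampler
quad_posterior_mean <- function(y, s2e, nu0, S0) {
  n <- length(y)
  ss <- sum((y - mean(y))^2)
  logpost <- function(v) {
    -(nu0 / 2 + 1) * log(v) - S0 / (2 * v) -
      (n - 1) / 2 * log(v + s2e) - ss / (2 * (v + s2e))
  }
  grid <- seq(1e-4, 15, length.out = 40000)
  lp <- logpost(grid)
  w <- exp(lp - max(lp))
  sum(grid * w) / sum(w)
}

test_that("single-kernel univariate chain matches the quadrature posterior", {
  set.seed(101)
  n <- 250
  s2u_true <- 1.0; s2e <- 0.5
  y <- rnorm(n, 2, sqrt(s2u_true + s2e))
  K <- relationship_matrix(diag(n), "additive", 1, paste0("S", 1:n))
  ch <- chain_config(n_iter = 20000, burn_in = 2000, thin = 1, seed = 5,
                     fix_residual = s2e)
  fit <- gibbs_univariate(y, K, ch)
  # replicate the sampler's own prior (half the phenotypic variance, df 3)
  S0 <- 0.5 * (var(y) + 1e-8 * var(y))
  oracle <- quad_posterior_mean(y, s2e, nu0 = 3, S0 = S0)
  draws <- fit$samples$V_a_11
  # Monte-Carlo SE by batch means (50 batches) to respect autocorrelation
  bm <- tapply(draws, rep(1:50, each = length(draws) / 50), mean)
  mcse <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(draws) - oracle), 3 * mcse + 0.01 * oracle)
})

test_that("a duplicated trait yields a genetic correlation near one", {
  cfg <- sim_config(n_samples = 150, n_snps = 300, seed = 31,
                    var_fracs_trait1 = c(0.5, 0, 0),
                    var_fracs_trait2 = c(0.5, 0, 0), genetic_corr = 1)
  s <- simulate_study(cfg)
  y2 <- s$phenotypes$trait1 + rnorm(150, 0, 0.02 * sd(s$phenotypes$trait1))
  y <- bivariate_phenotypes(s$phenotypes$sample_ids, s$phenotypes$trait1, y2)
  A <- additive_grm(s$genotypes)
  fit <- gibbs_multikernel(adjust_phenotypes(y), A,
                           chain_config(n_iter = 3000, burn_in = 1000,
                                        seed = 2))
  expect_gt(genetic_parameters(fit)$r_g, 0.95)
})

test_that("chains are bit-reproducible given the seed", {
  cfg <- sim_config(n_samples = 80, n_snps = 100, seed = 12)
  s <- simulate_study(cfg)
  # singleton herd-year-season levels are expected at this tiny n
  yadj <- suppressWarnings(adjust_phenotypes(s$phenotypes, s$factors))
  A <- additive_grm(s$genotypes)
  ch <- chain_config(n_iter = 800, burn_in = 200, seed = 77)
  f1 <- gibbs_multikernel(yadj, A, ch)
  f2 <- gibbs_multikernel(yadj, A, ch)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$genetic_values, f2$genetic_values)
  # diagonals of retained variance draws are positive throughout
  expect_true(all(f1$samples$V_a_11 > 0))
  expect_true(all(f1$samples$R0_22 > 0))
})

test_that("variance components are recovered when kernels are informative", {
  # two group-structured kernels over independent random partitions: the
  # within-group covariances identify each component separately from the
  # residual, unlike the near-identity kernels of an unrelated population
  set.seed(55)
  n <- 400; fam <- 8
  block_kernel <- function(groups, rho) {
    K <- outer(groups, groups, "==") * rho
    diag(K) <- 1
    K
  }
  g1 <- sample(rep(seq_len(n / fam), fam))
  g2 <- sample(rep(seq_len(n / fam), fam))
  K1 <- block_kernel(g1, 0.5)
  K2 <- block_kernel(g2, 0.5)
  v1 <- 0.3; v2 <- 0.5; ve <- 0.2
  u1 <- drop(crossprod(chol(K1), rnorm(n))) * sqrt(v1)
  u2 <- drop(crossprod(chol(K2), rnorm(n))) * sqrt(v2)
  y <- u1 + u2 + rnorm(n, 0, sqrt(ve))
  ids <- paste0("S", seq_len(n))
  kerns <- list(relationship_matrix(K1, "additive", 1, ids),
                relationship_matrix(K2, "dominance", 1, ids))
  fit <- gibbs_univariate(y, kerns, chain_config(6000, 2000, seed = 3))
  expect_lt(abs(fit$var[["V_a_11"]] - v1), 0.15)
  expect_lt(abs(fit$var[["V_d_11"]] - v2), 0.15)
  expect_lt(abs(fit$resid_var - ve), 0.12)
})

test_that("non-PSD kernels are rejected with advice", {
  M <- diag(5); M[1, 5] <- M[5, 1] <- 2
  ids <- paste0("S", 1:5)
  K <- structure(list(values = M, kind = "additive", denominator = 1,
                      sample_ids = ids), class = "grm")
  y <- bivariate_phenotypes(ids, rnorm(5), rnorm(5))
  expect_error(gibbs_multikernel(y, K, chain_config(10, 1, seed = 1)),
               "jitter")
})

test_that("genetic parameters agree with direct arithmetic on random components", {
  set.seed(6)
  for (rep in 1:5) {
    rnd_psd <- function() {
      L <- matrix(rnorm(4), 2); crossprod(L) + diag(0.1, 2)
    }
    Va <- rnd_psd(); Vd <- rnd_psd(); Vaa <- rnd_psd(); R0 <- rnd_psd()
    gp <- genetic_parameters(variance_components(Va, Vd, Vaa, R0))
    Vp <- Va + Vd + Vaa + R0
    expect_equal(gp$h2_narrow, diag(Va) / diag(Vp), tolerance = 1e-12)
    expect_equal(gp$h2_broad, diag(Va + Vd + Vaa) / diag(Vp),
                 tolerance = 1e-12)
    expect_equal(gp$r_g, Va[1, 2] / sqrt(Va[1, 1] * Va[2, 2]),
                 tolerance = 1e-12)
    expect_equal(gp$r_p, Vp[1, 2] / sqrt(Vp[1, 1] * Vp[2, 2]),
                 tolerance = 1e-12)
  }
  # no non-additive components: broad equals narrow exactly
  Va <- diag(c(1, 2)); R0 <- diag(c(3, 4))
  gp <- genetic_parameters(variance_components(Va, R0 = R0))
  expect_identical(gp$h2_narrow, gp$h2_broad)
  expect_error(genetic_parameters(
    variance_components(matrix(0, 2, 2), R0 = matrix(0, 2, 2))), "positive")
})

test_that("closed-form GBLUP is linear: zero training data gives zero predictions", {
  g <- toy_panel(n = 30, m = 50, seed = 8)
  A <- additive_grm(g)
  ids <- g$sample_ids
  ytr <- bivariate_phenotypes(ids[1:20], rep(0, 20), rep(0, 20))
  p <- predict_gblup_bivariate(ytr, A, vc = list(V = list(diag(2)),
                                                 R0 = diag(2)),
                               samples_test = ids[21:30])
  expect_equal(unname(p$pred), matrix(0, 10, 2), tolerance = 1e-10)
  expect_equal(p$model, "GBLUP")
})

test_that("BRR and GBLUP agree on additive-only data; BRR trivia hold", {
  cfg <- sim_config(n_samples = 250, n_snps = 300, seed = 44,
                    var_fracs_trait1 = c(0.5, 0, 0),
                    var_fracs_trait2 = c(0.5, 0, 0),
                    fixed_effect_sds = c(breed = 0, birth_year = 0,
                                         herd_year_season = 0))
  s <- simulate_study(cfg)
  yadj <- adjust_phenotypes(s$phenotypes)
  ids <- yadj$sample_ids
  tr <- ids[1:200]; te <- ids[201:250]
  ytr <- bivariate_phenotypes(tr, yadj$trait1[1:200], yadj$trait2[1:200])
  A <- additive_grm(s$genotypes)
  ch <- chain_config(n_iter = 2500, burn_in = 500, seed = 9)
  pg <- predict_gblup_bivariate(ytr, A, chain = ch, samples_test = te)
  pb <- predict_brr_bivariate(ytr, s$genotypes, ch, samples_test = te)
  expect_gt(cor(pg$pred[, 1], pb$pred[, 1]), 0.98)
  expect_gt(cor(pg$pred[, 2], pb$pred[, 2]), 0.98)
  # zero-variance phenotypes produce near-zero effects
  y0 <- bivariate_phenotypes(tr, rep(0, 200), rep(0, 200))
  p0 <- predict_brr_bivariate(y0, s$genotypes,
                              chain_config(600, 200, seed = 3),
                              samples_test = te)
  expect_lt(max(abs(p0$pred)), 1e-6 * sd(yadj$trait1))
})

test_that("shrinkage grows as the prior effect-variance scale shrinks", {
  cfg <- sim_config(n_samples = 60, n_snps = 30, seed = 3,
                    var_fracs_trait1 = c(0.4, 0, 0),
                    var_fracs_trait2 = c(0.4, 0, 0))
  s <- simulate_study(cfg)
  y <- adjust_phenotypes(s$phenotypes)
  ytr <- bivariate_phenotypes(y$sample_ids[1:50], y$trait1[1:50],
                              y$trait2[1:50])
  ch <- chain_config(n_iter = 1500, burn_in = 500, seed = 4)
  te <- y$sample_ids[51:60]
  big <- attr(predict_brr_bivariate(ytr, s$genotypes, ch, te, r2 = 0.9),
              "posterior")
  tiny <- attr(predict_brr_bivariate(ytr, s$genotypes, ch, te, r2 = 1e-4),
               "posterior")
  expect_lt(sum(tiny$effects^2), sum(big$effects^2))
})

test_that("Bayes A flags a single large-effect SNP among nulls", {
  set.seed(15)
  n <- 300; m <- 500
  g <- toy_panel(n = n, m = m, seed = 15)
  causal <- 137
  x <- g$values[, causal]
  y <- 2 * (x - mean(x)) + rnorm(n, 0, 1)
  names(y) <- g$sample_ids
  post <- bayes_a_univariate(y, g, chain_config(2000, 500, seed = 1))
  expect_equal(which.max(abs(post$effects[, 1])), causal)
  # training fit beats the null model
  pred <- predict(post, g)
  expect_lt(mean((y - pred$pred[, 1] - post$mu)^2), var(y))
  # all-zero phenotypes give essentially zero effects
  y0 <- setNames(rep(0, n), g$sample_ids)
  p0 <- bayes_a_univariate(y0, g, chain_config(500, 100, seed = 2))
  expect_lt(max(abs(p0$effects)), 1e-8)
})

test_that("Bayes B nests Bayes A at pi = 0 and ranks causal SNPs by inclusion", {
  set.seed(16)
  g <- toy_panel(n = 250, m = 400, seed = 16)
  yv <- g$values[, 50] - g$values[, 200] + rnorm(250, 0, 1)
  y <- setNames(yv, g$sample_ids)
  ch <- chain_config(2000, 500, seed = 7)
  pa <- bayes_a_univariate(y, g, ch)
  pb0 <- bayes_b_univariate(y, g, ch, pi = 0)
  expect_gt(cor(pa$effects[, 1], pb0$effects[, 1]), 0.98)
  expect_null(pa$inclusion)
  # sparse architecture: causal SNPs get higher inclusion than nulls
  set.seed(17)
  g2 <- toy_panel(n = 300, m = 1000, seed = 17)
  causal <- c(31, 250, 444, 720, 901)
  Z <- scale(g2$values[, causal])
  y2v <- drop(Z %*% rep(0.8, 5)) + rnorm(300, 0, 1)
  y2 <- setNames(y2v, g2$sample_ids)
  pb <- bayes_b_univariate(y2, g2, chain_config(2000, 500, seed = 8),
                           pi = 0.95)
  expect_gt(mean(pb$inclusion[causal]), mean(pb$inclusion[-causal]))
  # no signal and pi near one: effects vanish
  y3 <- setNames(rnorm(300), g2$sample_ids)
  pb3 <- bayes_b_univariate(y3, g2, chain_config(800, 200, seed = 9),
                            pi = 0.99)
  expect_lt(mean(abs(pb3$effects)), 0.02 * sd(y3))
  expect_lt(mean(pb3$inclusion), 0.05)
})

test_that("eigen-rotation combine reduces to univariate fits and handles rank-1", {
  set.seed(18)
  g <- toy_panel(n = 150, m = 200, seed = 18)
  ids <- g$sample_ids
  tr <- ids[1:120]; te <- ids[121:150]
  # exactly uncorrelated training traits with well-separated variances, so
  # the eigen-rotation is (a signed permutation of) the identity
  a <- rnorm(120); b <- rnorm(120)
  b <- resid(lm(b ~ a)); b <- 2 * b / sd(b); a <- a / sd(a)
  y <- bivariate_phenotypes(tr, a, b)
  ch <- chain_config(800, 200, seed = 11)
  comb <- multitrait_svd_combine(y, "bayes_a", g, ch, te)
  u2 <- predict(bayes_a_univariate(setNames(b, tr), g, ch),
                subset_genotypes(g, samples = match(te, ids)))
  # trait-2 predictions come from the trait-2 component alone
  expect_gt(abs(cor(comb$pred[, 2], u2$pred[, 1])), 0.95)
  # duplicated trait: both back-rotated predictions coincide
  ydup <- bivariate_phenotypes(tr, a, a)
  cd <- multitrait_svd_combine(ydup, "bayes_a", g, ch, te)
  expect_equal(cd$pred[, 1], cd$pred[, 2], tolerance = 1e-8)
  expect_equal(cd$model, "BayesA")
  # zero-variance trait is rejected
  yz <- bivariate_phenotypes(tr, a, rep(1, 120))
  expect_error(multitrait_svd_combine(yz, "bayes_a", g, ch, te),
               "degenerate|zero variance")
})
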