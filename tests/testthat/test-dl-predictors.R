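test_that("window and parameter counts follow the closed forms", {
  expect_equal(n_windows(100, 10), 10L)
  expect_equal(n_windows(47335, 28), 1690L)
  expect_error(n_windows(10, 20), "exceeds")
  cnn <- build_network(network_spec("cnn", 10, 16, 0), 100, seed = 1)
  expect_equal(cnn$L, 10L)
  expect_equal(count_parameters(cnn)$conv, 11)     # 10 weights + 1 bias
  lcnn <- build_network(network_spec("lcnn", 10, 16, 0), 100, seed = 1)
  expect_equal(count_parameters(lcnn)$conv, 110)   # (10 + 1) x 10 windows
  # closed forms across a grid of shapes
  for (k in c(3, 7)) for (m in c(30, 64)) for (h in c(5, 12)) {
    L <- (m - k) %/% k + 1
    net <- build_network(network_spec("cnn", k, h, 0), m, seed = 2)
    expect_equal(count_parameters(net)$total,
                 (k + 1) + (L * h + h) + (h * h + h) + (h * 2 + 2))
    netl <- build_network(network_spec("lcnn", k, h, 0), m, seed = 2)
    expect_equal(count_parameters(netl)$total,
                 (k + 1) * L + (L * h + h) + (h * h + h) + (h * 2 + 2))
  }
})

test_that("forward output has one row per sample and two columns", {
  g <- toy_panel(n = 17, m = 60, seed = 2)
  for (kind in c("cnn", "lcnn")) {
    net <- build_network(network_spec(kind, 7, 9, 0.2), 60, seed = 3)
    net <- train_network(net, g, matrix(rnorm(34), 17, 2),
                         training_config(n_epochs = 1, batch_size = 8,
                                         seed = 1))
    p <- predict(net, g)
    expect_equal(dim(p$pred), c(17L, 2L))
  }
})

test_that("training reduces the loss on a learnable linear trait", {
  set.seed(5)
  n <- 200; m <- 80
  g <- toy_panel(n = n, m = m, seed = 5)
  beta <- rnorm(m, 0, 1)
  gv <- scale(g$values %*% beta)
  y <- cbind(gv + rnorm(n, 0, sqrt(1 / 9)),          # h2 = 0.9
             gv + rnorm(n, 0, sqrt(1 / 9)))
  for (kind in c("cnn", "lcnn")) {
    net <- build_network(network_spec(kind, 8, 24, 0), m, seed = 6)
    net <- train_network(net, g, y, training_config(
      learning_rate = 2e-3, n_epochs = 25, batch_size = 16, seed = 6))
    expect_lt(net$loss_trace[25], net$loss_trace[1])
  }
})

test_that("training and inference are deterministic given the seed", {
  g <- toy_panel(n = 60, m = 50, seed = 7)
  y <- matrix(rnorm(120), 60, 2)
  tc <- training_config(n_epochs = 4, batch_size = 16, seed = 11)
  sp <- network_spec("cnn", 5, 10, 0.3)
  n1 <- train_network(build_network(sp, 50, seed = 9), g, y, tc)
  n2 <- train_network(build_network(sp, 50, seed = 9), g, y, tc)
  expect_identical(n1$loss_trace, n2$loss_trace)
  expect_identical(n1$par, n2$par)
  # dropout is off at inference: repeated prediction is identical
  p1 <- predict(n1, g); p2 <- predict(n1, g)
  expect_identical(p1$pred, p2$pred)
  # constant input rows give identical predictions
  const <- matrix(1, 4, 50)
  pc <- predict(n1, const)
  expect_equal(pc$pred[1, ], pc$pred[3, ], tolerance = 1e-12)
  # SNP-count mismatch is rejected
  expect_error(predict(n1, toy_panel(5, 40, seed = 1)), "SNP count")
})

test_that("a tiny problem can be memorized", {
  set.seed(8)
  g <- toy_panel(n = 25, m = 30, seed = 8)
  y <- matrix(rnorm(50), 25, 2)
  net <- build_network(network_spec("cnn", 3, 40, 0), 30, seed = 4)
  net <- train_network(net, g, y, training_config(
    learning_rate = 5e-3, n_epochs = 300, batch_size = 25, seed = 4))
  p <- predict(net, g)
  expect_gt(cor(p$pred[, 1], y[, 1]), 0.95)
  expect_gt(cor(p$pred[, 2], y[, 2]), 0.95)
})

test_that("ensemble averaging is exact and never hurts MSE", {
  ids <- paste0("S", 1:12)
  obs <- bivariate_phenotypes(ids, rnorm(12), rnorm(12))
  r1 <- prediction_result(ids, matrix(rnorm(24), 12, 2), "CNN")
  expect_identical(ensemble_average(list(r1))$pred, r1$pred)
  rneg <- prediction_result(ids, -r1$pred, "CNN")
  expect_equal(unname(ensemble_average(list(r1, rneg))$pred),
               matrix(0, 12, 2))
  set.seed(9)
  members <- lapply(1:10, function(i) {
    prediction_result(ids, r1$pred + matrix(rnorm(24, 0, 0.5), 12, 2),
                      "CNN")
  })
  ens <- ensemble_average(members)
  mem_mse <- sapply(members, function(m) mean(mse(m, obs)))
  expect_lte(mean(mse(ens, obs)), mean(mem_mse))
  # variance reduction: across repeated draws of the training noise, the
  # ensemble prediction varies less per sample than individual members do
  draw_member <- function() {
    prediction_result(ids, r1$pred + matrix(rnorm(24, 0, 0.5), 12, 2), "CNN")
  }
  ens3 <- replicate(3, ensemble_average(replicate(5, draw_member(),
                                                  simplify = FALSE)),
                    simplify = FALSE)
  mem3 <- replicate(3, draw_member(), simplify = FALSE)
  sd_ens <- apply(sapply(ens3, function(e) e$pred[, 1]), 1, sd)
  sd_mem <- apply(sapply(mem3, function(m) m$pred[, 1]), 1, sd)
  expect_lt(mean(sd_ens), mean(sd_mem))
  # mismatched samples are rejected
  bad <- prediction_result(rev(ids), r1$pred, "CNN")
  expect_error(ensemble_average(list(r1, bad)), "identical samples")
})

test_that("network ensembles extract additive signal held by GBLUP", {
  # cross-model consistency on purely additive data: at this sample size a
  # one-filter network undertrains relative to the linear optimum, so the
  # checks are that it captures real signal and that the gap to GBLUP stays
  # bounded; the at-scale comparison lives in the acceptance suite
  for (i in 1:2) {
    cfg <- sim_config(n_samples = 400, n_snps = 600, seed = 300 + i,
                      var_fracs_trait1 = c(0.5, 0, 0),
                      var_fracs_trait2 = c(0.5, 0, 0),
                      fixed_effect_sds = c(breed = 0, birth_year = 0,
                                           herd_year_season = 0))
    s <- simulate_study(cfg)
    y <- adjust_phenotypes(s$phenotypes)
    ids <- y$sample_ids
    tr <- ids[1:320]; te <- ids[321:400]
    ytr <- bivariate_phenotypes(tr, y$trait1[1:320], y$trait2[1:320])
    A <- additive_grm(s$genotypes)
    pg <- predict_gblup_bivariate(ytr, A,
                                  chain_config(2000, 500, seed = i),
                                  samples_test = te)
    gtr <- subset_genotypes(s$genotypes, samples = 1:320)
    gte <- subset_genotypes(s$genotypes, samples = 321:400)
    preds <- lapply(1:3, function(r) {
      net <- build_network(network_spec("cnn", 28, 86, 0.28), 600,
                           seed = 10 * i + r)
      net <- train_network(net, gtr, phen_matrix(ytr),
                           training_config(seed = 10 * i + r))
      predict(net, gte)
    })
    pc <- ensemble_average(preds)
    cg <- mean(predictive_correlation(pg, y))
    cc <- mean(predictive_correlation(pc, y))
    expect_gt(cc, 0.05)          # the network learns genuine signal
    expect_lt(cg - cc, 0.35)     # and stays within a bounded gap of GBLUP
  }
})
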