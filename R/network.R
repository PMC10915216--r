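#' Network architecture specification
#'
#' Architecture of the bivariate SNP regression networks: one convolutional
#' (CNN) or locally connected (LCNN) layer with a single filter whose stride
#' equals its kernel size (non-overlapping SNP windows; trailing SNPs beyond
#' the last full window are dropped), a flatten step, two fully connected
#' ReLU layers of equal width, dropout after the flatten and after each
#' fully connected layer, and a 2-unit linear output head. The CNN shares
#' one weight vector across all windows; the LCNN fits an independent weight
#' vector per window.
#'
#' @param model_kind \code{"cnn"} or \code{"lcnn"}.
#' @param kernel_size window width = stride, >= 1.
#' @param n_neurons width of both fully connected layers.
#' @param dropout_rate dropout probability in [0, 1).
#' @return Object of class \code{network_spec}.
#' @export
network_spec <- function(model_kind = c("cnn", "lcnn"), kernel_size = 28,
                         n_neurons = 86, dropout_rate = 0.28) {
  model_kind <- match.arg(model_kind)
  if (kernel_size < 1) stop("kernel_size must be >= 1")
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)")
  }
  structure(list(model_kind = model_kind,
                 kernel_size = as.integer(round(kernel_size)),
                 n_filters = 1L, n_fc_layers = 2L,
                 n_neurons = as.integer(round(n_neurons)),
                 dropout_rate = dropout_rate, activation = "relu",
                 n_outputs = 2L), class = "network_spec")
}

#' Training configuration for the networks
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param n_epochs training epochs (50 by default, matching the fixed
#'   training-session length used during hyperparameter optimization).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return Object of class \code{training_config}; loss is mean squared
#'   error and the optimizer is Adam, both fixed.
#' @export
training_config <- function(learning_rate = 4e-4, batch_size = 32,
                            n_epochs = 50, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (n_epochs < 1) stop("n_epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), loss = "mse",
                 optimizer = "adam", seed = as.integer(seed)),
            class = "training_config")
}

#' Number of SNP windows of the convolutional layer
#'
#' \code{floor((n_snps - k) / k) + 1} non-overlapping windows of width k.
#'
#' @param n_snps panel width.
#' @param kernel_size window width = stride.
#' @return Integer window count.
#' @export
n_windows <- function(n_snps, kernel_size) {
  if (kernel_size > n_snps) stop("kernel_size exceeds n_snps")
  as.integer((n_snps - kernel_size) %/% kernel_size + 1L)
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

#' Build an initialized SNP regression network
#'
#' @param spec a \code{\link{network_spec}}.
#' @param n_snps number of SNPs the network will see.
#' @param seed integer seed for weight initialization.
#' @return Object of class \code{snp_network} holding the parameter list,
#'   the window count \code{L}, and the spec.
#' @export
build_network <- function(spec, n_snps, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  k <- spec$kernel_size
  L <- n_windows(n_snps, k)
  h <- spec$n_neurons
  set.seed(seed)
  par <- list(
    conv_w = if (spec$model_kind == "cnn") init_mat(k, 1, k) else
      init_mat(k, L, k),
    conv_b = if (spec$model_kind == "cnn") 0 else numeric(L),
    W1 = init_mat(L, h, L), b1 = numeric(h),
    W2 = init_mat(h, h, h), b2 = numeric(h),
    W3 = init_mat(h, 2, h), b3 = numeric(2))
  structure(list(par = par, spec = spec, n_snps = as.integer(n_snps),
                 L = L, trained = FALSE, x_center = NULL, x_scale = NULL,
                 y_center = NULL, y_scale = NULL),
            class = "snp_network")
}

#' @export
print.snp_network <- function(x, ...) {
  np <- sum(vapply(x$par, length, 0L))
  cat("snp_network (", toupper(x$spec$model_kind), "): ", x$n_snps,
      " SNPs -> ", x$L, " windows (k=", x$spec$kernel_size, ") -> FC ",
      x$spec$n_neurons, "x2 -> 2 outputs; ", np, " parameters; ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Parameter count of a network
#'
#' Closed forms: the CNN convolutional stage has \code{k + 1} parameters
#' (one shared weight vector plus bias); the LCNN has \code{(k + 1) * L}
#' (an independent vector and bias per window).
#'
#' @param net a \code{snp_network}.
#' @return Named list with \code{conv} and \code{total} parameter counts.
#' @export
count_parameters <- function(net) {
  conv <- length(net$par$conv_w) + length(net$par$conv_b)
  total <- conv + sum(lengths(net$par[c("W1", "b1", "W2", "b2", "W3", "b3")]))
  list(conv = conv, total = total)
}

# reshape a batch into the k x (L*b) window-column layout; column order is
# window-fastest within sample
window_cols <- function(Xb, k, L) {
  matrix(t(Xb[, seq_len(k * L), drop = FALSE]), nrow = k)
}

# forward pass; when train = TRUE, dropout masks are sampled and cached
net_forward <- function(net, Xb, train = FALSE) {
  net_forward_M(net, window_cols(Xb, net$spec$kernel_size, net$L),
                nrow(Xb), train)
}

# forward from the k x (L*b) window-column layout (precomputed in training)
net_forward_M <- function(net, M, b, train = FALSE) {
  par <- net$par
  k <- net$spec$kernel_size; L <- net$L
  if (net$spec$model_kind == "cnn") {
    cv <- matrix(crossprod(M, par$conv_w), nrow = L)   # L x b
    conv <- t(cv) + par$conv_b
  } else {
    Wrep <- matrix(par$conv_w, k, L * b)
    conv <- t(matrix(colSums(M * Wrep), L, b)) +
      matrix(par$conv_b, b, L, byrow = TRUE)
  }
  a0 <- conv                 # linear conv stage; nonlinearity lives in the FCs
  p <- net$spec$dropout_rate
  drop_mask <- function(nr, nc) {
    if (!train || p == 0) return(NULL)
    matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
  }
  d0 <- drop_mask(b, L); if (!is.null(d0)) a0 <- a0 * d0
  z1 <- a0 %*% par$W1 + matrix(par$b1, b, length(par$b1), byrow = TRUE)
  a1 <- z1 * (z1 > 0)
  d1 <- drop_mask(b, ncol(a1)); if (!is.null(d1)) a1 <- a1 * d1
  z2 <- a1 %*% par$W2 + matrix(par$b2, b, length(par$b2), byrow = TRUE)
  a2 <- z2 * (z2 > 0)
  d2 <- drop_mask(b, ncol(a2)); if (!is.null(d2)) a2 <- a2 * d2
  out <- a2 %*% par$W3 + matrix(par$b3, b, 2, byrow = TRUE)
  list(out = out, cache = list(M = M, conv = conv, a0 = a0, z1 = z1, a1 = a1,
                               z2 = z2, a2 = a2, d0 = d0, d1 = d1, d2 = d2,
                               b = b))
}

# gradients of the mean-over-all-entries squared error
net_backward <- function(net, cache, dout) {
  par <- net$par
  k <- net$spec$kernel_size; L <- net$L; b <- cache$b
  g <- list()
  g$W3 <- crossprod(cache$a2, dout); g$b3 <- colSums(dout)
  da2 <- dout %*% t(par$W3)
  if (!is.null(cache$d2)) da2 <- da2 * cache$d2
  dz2 <- da2 * (cache$z2 > 0)
  g$W2 <- crossprod(cache$a1, dz2); g$b2 <- colSums(dz2)
  da1 <- dz2 %*% t(par$W2)
  if (!is.null(cache$d1)) da1 <- da1 * cache$d1
  dz1 <- da1 * (cache$z1 > 0)
  g$W1 <- crossprod(cache$a0, dz1); g$b1 <- colSums(dz1)
  da0 <- dz1 %*% t(par$W1)
  if (!is.null(cache$d0)) da0 <- da0 * cache$d0
  dconv <- da0
  dvec <- as.vector(t(dconv))                       # window-fastest order
  if (net$spec$model_kind == "cnn") {
    g$conv_w <- cbind(as.vector(cache$M %*% dvec))
    g$conv_b <- sum(dconv)
  } else {
    tmp <- cache$M * matrix(dvec, k, L * b, byrow = TRUE)
    g$conv_w <- rowSums(array(tmp, dim = c(k, L, b)), dims = 2)
    g$conv_b <- colSums(dconv)
  }
  g
}

#' Train a network by mini-batch Adam on the joint MSE
#'
#' Inputs are standardized per SNP and targets per trait with training
#' statistics (stored in the network and re-applied at prediction). The loss
#' is the mean squared error over both standardized outputs; per-trait loss
#' weights are equal. Training is deterministic given the configuration
#' seed.
#'
#' @param net an initialized \code{snp_network}.
#' @param g_train a \code{\link{genotype_matrix}} or plain numeric matrix of
#'   training inputs.
#' @param y_train a complete \code{\link{bivariate_phenotypes}} or n x 2
#'   matrix of training targets.
#' @param tc a \code{\link{training_config}}.
#' @return The trained network, with per-epoch mean training loss in
#'   \code{$loss_trace}.
#' @export
train_network <- function(net, g_train, y_train, tc = training_config()) {
  stopifnot(inherits(net, "snp_network"), inherits(tc, "training_config"))
  X <- if (inherits(g_train, "genotype_matrix")) g_train$values else
    as.matrix(g_train)
  Y <- if (inherits(y_train, "bivariate_phenotypes")) phen_matrix(y_train)
  else as.matrix(y_train)
  if (nrow(X) != nrow(Y)) stop("inputs and targets must align")
  if (anyNA(Y)) stop("training phenotypes must be complete")
  if (ncol(X) != net$n_snps) stop("SNP count does not match the network")
  net$x_center <- colMeans(X)
  net$x_scale <- apply(X, 2, stats::sd)
  net$x_scale[net$x_scale == 0] <- 1
  net$y_center <- colMeans(Y)
  net$y_scale <- apply(Y, 2, stats::sd)
  net$y_scale[net$y_scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, net$x_center), 2, net$x_scale, "/")
  Ys <- sweep(sweep(Y, 2, net$y_center), 2, net$y_scale, "/")
  n <- nrow(Xs)
  k <- net$spec$kernel_size; L <- net$L
  Mfull <- window_cols(Xs, k, L)      # window columns, grouped by sample
  lr <- tc$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  # Adam runs on a flat parameter vector; matrices are refreshed in place
  pnames <- names(net$par)
  lens <- vapply(net$par, length, 0L)
  hi <- cumsum(lens); lo <- hi - lens + 1L
  pv <- unlist(net$par, use.names = FALSE)
  mstate <- numeric(length(pv)); vstate <- numeric(length(pv))
  tstep <- 0
  set.seed(tc$seed)
  trace <- numeric(tc$n_epochs)
  for (ep in seq_len(tc$n_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = tc$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + tc$batch_size - 1L, n)]
      cols <- rep((idx - 1L) * L, each = L) + seq_len(L)
      Yb <- Ys[idx, , drop = FALSE]
      fw <- net_forward_M(net, Mfull[, cols, drop = FALSE], length(idx),
                          train = TRUE)
      err <- fw$out - Yb
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep, ", batch ",
             which(starts == s))
      }
      ep_loss <- ep_loss + loss * length(idx)
      dout <- 2 * err / length(err)
      grads <- net_backward(net, fw$cache, dout)
      gv <- unlist(grads[pnames], use.names = FALSE)
      tstep <- tstep + 1
      mstate <- beta1 * mstate + (1 - beta1) * gv
      vstate <- beta2 * vstate + (1 - beta2) * gv^2
      pv <- pv - lr * (mstate / (1 - beta1^tstep)) /
        (sqrt(vstate / (1 - beta2^tstep)) + eps)
      for (j in seq_along(pnames)) {
        net$par[[j]][] <- pv[lo[j]:hi[j]]
      }
    }
    trace[ep] <- ep_loss / n
  }
  net$trained <- TRUE
  net$loss_trace <- trace
  net
}

#' Predict trait values with a trained network
#'
#' Dropout is disabled at inference; inputs are standardized with the
#' training statistics and predictions are back-transformed to trait scale.
#'
#' @param object a trained \code{snp_network}.
#' @param g_test a \code{\link{genotype_matrix}} or numeric matrix with the
#'   training panel's SNPs.
#' @param fold optional fold id carried into the result.
#' @param model_label label for the result (default: upper-case model kind).
#' @param ... unused.
#' @return A \code{\link{prediction_result}} with b x 2 predictions.
#' @export
predict.snp_network <- function(object, g_test, fold = NA_integer_,
                                model_label = NULL, ...) {
  if (!object$trained) stop("network is not trained")
  ids <- if (inherits(g_test, "genotype_matrix")) g_test$sample_ids else
    rownames(g_test)
  X <- if (inherits(g_test, "genotype_matrix")) g_test$values else
    as.matrix(g_test)
  if (ncol(X) != object$n_snps) {
    stop("SNP count does not match the trained network")
  }
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(X)))
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  out <- net_forward(object, Xs, train = FALSE)$out
  pred <- sweep(sweep(out, 2, object$y_scale, "*"), 2, object$y_center, "+")
  if (is.null(model_label)) model_label <- toupper(object$spec$model_kind)
  prediction_result(ids, pred, model_label, fold)
}
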