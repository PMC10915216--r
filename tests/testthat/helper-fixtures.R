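# shared fixture builders; everything is generated in code at test time

# small complete integer panel with controllable dimensions
toy_panel <- function(n = 10, m = 20, seed = 42, p = NULL,
                      chromosome = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  vals <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  # guard against monomorphic columns in tiny panels
  for (j in which(apply(vals, 2, function(v) length(unique(v))) == 1)) {
    vals[1, j] <- (vals[1, j] + 1) %% 3
  }
  genotype_matrix(vals, chromosome = chromosome)
}

# brute-force relationship-matrix oracles (double loops, no linear algebra)
loop_additive <- function(vals, p) {
  n <- nrow(vals); m <- ncol(vals)
  denom <- sum(2 * p * (1 - p))
  A <- matrix(0, n, n)
  for (k in seq_len(n)) for (l in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) {
      s <- s + (vals[k, i] - 2 * p[i]) * (vals[l, i] - 2 * p[i])
    }
    A[k, l] <- s / denom
  }
  A
}

loop_dominance <- function(vals, p) {
  n <- nrow(vals); m <- ncol(vals)
  q <- 1 - p
  denom <- sum(2 * p * q * (1 - 2 * p * q))
  D <- matrix(0, n, n)
  hval <- function(g, i) if (g == 1) 1 - 2 * p[i] * q[i] else -2 * p[i] * q[i]
  for (k in seq_len(n)) for (l in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) s <- s + hval(vals[k, i], i) * hval(vals[l, i], i)
    D[k, l] <- s / denom
  }
  D
}

loop_epistatic <- function(A) {
  n <- nrow(A)
  tr <- sum(diag(A)^2)
  AA <- matrix(0, n, n)
  for (k in seq_len(n)) for (l in seq_len(n)) AA[k, l] <- A[k, l]^2
  AA / (tr / n)
}

# phenotypes with known structure
toy_phen <- function(n = 20, seed = 1, r = 0.5) {
  set.seed(seed)
  y1 <- rnorm(n)
  y2 <- r * y1 + sqrt(1 - r^2) * rnorm(n)
  bivariate_phenotypes(sprintf("S%03d", seq_len(n)), y1, y2)
}
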