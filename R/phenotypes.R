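#' Bivariate phenotype table
#'
#' Holds the two correlated trait records (by convention trait 1 is the
#' litter-count-scale trait, trait 2 the pig-production-scale trait) for a set
#' of samples. Missing values are allowed; each retained sample must have at
#' least one observed trait.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param trait1,trait2 numeric vectors (trait units), \code{NA} allowed.
#' @param trait_names length-2 character, display names for the traits.
#' @param adjusted logical flag: have fixed effects been removed?
#' @return Object of class \code{bivariate_phenotypes}.
#' @export
bivariate_phenotypes <- function(sample_ids, trait1, trait2,
                                 trait_names = c("trait1", "trait2"),
                                 adjusted = FALSE) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  n <- length(sample_ids)
  trait1 <- as.numeric(trait1); trait2 <- as.numeric(trait2)
  if (length(trait1) != n || length(trait2) != n) {
    stop("trait vectors must match sample_ids in length")
  }
  if (any(is.na(trait1) & is.na(trait2))) {
    stop("every sample must have at least one observed trait")
  }
  structure(list(sample_ids = sample_ids, trait1 = trait1, trait2 = trait2,
                 trait_names = trait_names, adjusted = isTRUE(adjusted)),
            class = "bivariate_phenotypes")
}

#' @export
print.bivariate_phenotypes <- function(x, ...) {
  cat("bivariate_phenotypes:", length(x$sample_ids), "samples,",
      if (x$adjusted) "adjusted" else "raw", "\n")
  for (k in 1:2) {
    v <- x[[paste0("trait", k)]]
    cat(sprintf("  %s: mean %.3f sd %.3f (%d missing)\n", x$trait_names[k],
                mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE),
                sum(is.na(v))))
  }
  invisible(x)
}

#' @export
as.data.frame.bivariate_phenotypes <- function(x, ...) {
  d <- data.frame(sample_id = x$sample_ids, t1 = x$trait1, t2 = x$trait2,
                  stringsAsFactors = FALSE)
  names(d)[2:3] <- x$trait_names
  d
}

# internal: n x 2 numeric matrix view
phen_matrix <- function(y) {
  stopifnot(inherits(y, "bivariate_phenotypes"))
  cbind(y$trait1, y$trait2)
}

#' Categorical fixed-effects table
#'
#' Per-sample levels of categorical environmental factors (breed, birth year,
#' herd-year-season, and any extra factors). Every sample must have a level
#' for every factor.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param ... named factors (character/factor vectors of per-sample levels).
#' @return Object of class \code{fixed_effects_table}.
#' @export
fixed_effects_table <- function(sample_ids, ...) {
  sample_ids <- as.character(sample_ids)
  facs <- list(...)
  if (length(facs) == 1L && is.list(facs[[1]]) && is.null(names(facs)[1])) {
    facs <- facs[[1]]
  }
  if (length(facs) && (is.null(names(facs)) || any(names(facs) == ""))) {
    stop("all factors must be named")
  }
  facs <- lapply(facs, function(f) {
    f <- as.factor(f)
    if (length(f) != length(sample_ids)) {
      stop("each factor must have one level per sample")
    }
    if (anyNA(f)) stop("factor levels may not be missing")
    f
  })
  structure(list(sample_ids = sample_ids, factors = facs),
            class = "fixed_effects_table")
}

#' @export
print.fixed_effects_table <- function(x, ...) {
  cat("fixed_effects_table:", length(x$sample_ids), "samples,",
      length(x$factors), "factors\n")
  for (nm in names(x$factors)) {
    cat("  ", nm, ": ", nlevels(x$factors[[nm]]), " levels\n", sep = "")
  }
  invisible(x)
}

#' Remove categorical fixed effects from phenotypes
#'
#' Fits, per trait, an ordinary least-squares regression of the phenotype on
#' the dummy-coded categorical design (all factors jointly, intercept
#' included) and returns the residuals as adjusted phenotypes. The joint fit
#' is order-invariant, unlike sequential one-factor residualization; a
#' sequential mode is provided for comparison with pipelines that adjust one
#' factor at a time.
#'
#' @param y a \code{bivariate_phenotypes} object.
#' @param fx a \code{fixed_effects_table} for the same samples, or \code{NULL}
#'   for intercept-only centering.
#' @param method \code{"joint"} (default) fits all factors at once;
#'   \code{"sequential"} residualizes on one factor at a time in the order
#'   given.
#' @return A \code{bivariate_phenotypes} object with \code{adjusted = TRUE};
#'   missing trait values stay missing.
#' @export
adjust_phenotypes <- function(y, fx = NULL, method = c("joint", "sequential")) {
  stopifnot(inherits(y, "bivariate_phenotypes"))
  method <- match.arg(method)
  Y <- phen_matrix(y)
  n <- nrow(Y)
  if (!is.null(fx)) {
    stopifnot(inherits(fx, "fixed_effects_table"))
    if (!identical(fx$sample_ids, y$sample_ids)) {
      stop("fixed-effects table and phenotypes must index the same samples")
    }
    for (nm in names(fx$factors)) {
      tb <- table(fx$factors[[nm]])
      if (any(tb == 1L)) {
        warning("factor '", nm, "' has levels observed in only one sample: ",
                paste(names(tb)[tb == 1L], collapse = ", "))
      }
    }
  }
  design <- function(facs) {
    df <- as.data.frame(facs)
    X <- stats::model.matrix(~ ., data = df)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("rank-deficient fixed-effect design; aliased columns: ",
           paste(aliased, collapse = ", "))
    }
    X
  }
  resid_on <- function(v, D) {
    out <- rep(NA_real_, length(v))
    obs <- !is.na(v)
    fit <- stats::lm.fit(D[obs, , drop = FALSE], v[obs])
    out[obs] <- fit$residuals
    out
  }
  if (is.null(fx) || !length(fx$factors)) {
    Z <- apply(Y, 2, function(v) v - mean(v, na.rm = TRUE))
  } else if (method == "joint") {
    D <- design(fx$factors)
    Z <- apply(Y, 2, resid_on, D = D)
  } else {
    Z <- Y
    for (nm in names(fx$factors)) {
      D <- design(fx$factors[nm])
      Z <- apply(Z, 2, resid_on, D = D)
    }
  }
  bivariate_phenotypes(y$sample_ids, Z[, 1], Z[, 2],
                       trait_names = y$trait_names, adjusted = TRUE)
}
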