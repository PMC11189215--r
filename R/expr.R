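## Expression preparation: low-count filtering, normalization/transform,
## covariate residualization, inverse normal transform, hidden factors.

#' CPM threshold corresponding to a read count in the median library
#'
#' Helper used to pick the low-expression CPM cutoff the way the cohort
#' filter was defined: the CPM value that corresponds to \code{reads} reads in
#' the median-sized library (e.g. 10 reads in a ~22.7M-read median library
#' gives 0.44 CPM).
#'
#' @param reads read count to convert (default 10)
#' @param library_size per-sample library sizes (the median is used)
#' @return CPM threshold
#' @export
cpm_for_reads <- function(reads = 10, library_size) {
  reads * 1e6 / stats::median(library_size)
}

#' Filter lowly expressed features
#'
#' Keeps a feature iff its counts-per-million exceed \code{cpm_min}
#' (strictly; "did not have over" is the removal rule) in at least
#' \code{ceiling(min_fraction * n_samples)} samples — e.g. 323 of 358 samples
#' at the default 90\%. CPM uses the library sizes recorded at load.
#'
#' @param c a \code{\link{count_matrix}}
#' @param cpm_min CPM threshold (strict inequality)
#' @param min_fraction fraction of samples that must pass (default 0.9)
#' @return filtered \code{count_matrix} (library sizes preserved)
#' @export
filter_low_expression <- function(c, cpm_min, min_fraction = 0.9) {
  stopifnot(inherits(c, "count_matrix"))
  if (cpm_min < 0) stop("cpm_min must be nonnegative")
  if (any(c$library_size <= 0)) stop("library_size must be positive")
  need <- ceiling(min_fraction * ncol(c$counts))
  cpm <- sweep(c$counts, 2, c$library_size / 1e6, "/")
  keep <- rowSums(cpm > cpm_min) >= need
  count_matrix(c$counts[keep, , drop = FALSE], c$features$kind[keep],
               c$library_size)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample, the median over
#' all-positive features of the ratio of its count to that feature's
#' geometric mean across samples, rescaled so the factors themselves have
#' geometric mean 1.
#'
#' @param c a \code{\link{count_matrix}}
#' @return positive per-sample factor vector
#' @export
size_factors_median_ratio <- function(c) {
  stopifnot(inherits(c, "count_matrix"))
  pos <- rowSums(c$counts > 0) == ncol(c$counts)
  if (!any(pos))
    stop("no feature has positive counts in all samples; consider a pseudocount")
  lg <- log(c$counts[pos, , drop = FALSE])
  logratio <- lg - rowMeans(lg)
  f <- exp(apply(logratio, 2, stats::median))
  f / exp(mean(log(f)))
}

#' Variance-stabilizing transform (log2 of normalized counts)
#'
#' Transforms counts to \code{log2(count / size_factor + 1)} using
#' median-of-ratios size factors. Monotone in counts within each sample; the
#' transform name is recorded in the provenance metadata.
#'
#' @param c a \code{\link{count_matrix}}
#' @param size_factors optional precomputed factors; defaults to
#'   \code{\link{size_factors_median_ratio}}
#' @return \code{\link{expression_matrix}} in state \code{transformed}
#' @export
vst_transform <- function(c, size_factors = NULL) {
  stopifnot(inherits(c, "count_matrix"))
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(c)
  v <- log2(sweep(c$counts, 2, size_factors, "/") + 1)
  expression_matrix(v, c$features$kind, "transformed",
                    provenance = list(transform = "log2_median_ratio_plus1",
                                      size_factors = unname(size_factors)))
}

# one-hot design from a covariate data.frame: intercept + numeric columns +
# dummies with the first (lexicographic) level as reference
.covariate_design <- function(cov) {
  stopifnot(is.data.frame(cov), !anyNA(cov))
  cols <- list("(Intercept)" = rep(1, nrow(cov)))
  for (nm in names(cov)) {
    v <- cov[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      lev <- sort(unique(as.character(v)))
      for (l in lev[-1])
        cols[[paste0(nm, l)]] <- as.numeric(as.character(v) == l)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(cov)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  X
}

#' Regress covariates out of expression
#'
#' Per feature, fits least squares of expression on the covariate design
#' (categoricals one-hot encoded with the first level as reference, intercept
#' included) and keeps the residuals plus the feature mean, so each feature's
#' location is preserved. Mirrors batch-removal of known covariates before
#' the association scans.
#'
#' @param e \code{\link{expression_matrix}} in state \code{transformed}
#' @param cov data.frame of per-sample covariates (rows in sample order)
#' @return \code{expression_matrix} in state \code{residualized}
#' @export
residualize_covariates <- function(e, cov) {
  stopifnot(inherits(e, "expression_matrix"))
  if (!e$state %in% c("transformed", "residualized"))
    stop("residualization expects a transformed expression matrix")
  stopifnot(nrow(cov) == ncol(e$values))
  X <- .covariate_design(cov)
  Y <- t(e$values)                       # samples x features
  fit <- stats::lm.fit(X, Y)
  res <- t(as.matrix(fit$residuals)) + rowMeans(e$values)
  dimnames(res) <- dimnames(e$values)
  expression_matrix(res, e$features$kind, "residualized",
                    provenance = c(e$provenance,
                                   list(covariates = colnames(X)[-1])))
}

#' Rank-based inverse normal transform
#'
#' Maps each feature row to normal scores
#' \eqn{\Phi^{-1}((r_i - c)/(n - 2c + 1))} with the Blom offset c = 3/8; ties
#' share their average rank. After this step every feature is exactly
#' normally scored, which is the form consumed by the association scans.
#'
#' @param e \code{\link{expression_matrix}} in state \code{residualized}
#'   (or \code{transformed} with \code{allow_transformed = TRUE})
#' @param allow_transformed accept state \code{transformed} input
#' @return \code{expression_matrix} in state \code{inverse_normal}
#' @export
inverse_normal_transform <- function(e, allow_transformed = FALSE) {
  stopifnot(inherits(e, "expression_matrix"))
  ok <- e$state == "residualized" ||
    (allow_transformed && e$state == "transformed")
  if (!ok) stop("inverse normal transform expects residualized expression")
  n <- ncol(e$values)
  v <- t(apply(e$values, 1, function(y) {
    if (max(y) == min(y)) stop("cannot rank constant row")
    stats::qnorm((rank(y, ties.method = "average") - 0.375) / (n + 0.25))
  }))
  dimnames(v) <- dimnames(e$values)
  expression_matrix(v, e$features$kind, "inverse_normal",
                    provenance = c(e$provenance, list(int = "blom_3_8")))
}

#' Estimate hidden expression factors
#'
#' Principal components of the feature-standardized residual matrix, returned
#' as additional numeric covariates — a PCA stand-in for hidden-factor
#' (PEER-style) estimation, used to absorb unmodelled technical variation in
#' sensitivity analyses.
#'
#' @param e \code{\link{expression_matrix}} in state \code{residualized}
#' @param k number of factors; \code{k = 0} returns an empty data.frame
#' @return data.frame of factor scores (samples x k), columns HF1..HFk
#' @export
estimate_hidden_factors <- function(e, k) {
  stopifnot(inherits(e, "expression_matrix"))
  if (e$state != "residualized") stop("hidden factors expect residualized input")
  out <- data.frame(row.names = colnames(e$values))
  if (k == 0) return(out)
  Z <- t(scale(t(e$values)))             # standardize features
  Z <- Z[apply(Z, 1, function(r) all(is.finite(r))), , drop = FALSE]
  pc <- stats::prcomp(t(Z), center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  out <- as.data.frame(pc$x[, seq_len(k), drop = FALSE])
  names(out) <- paste0("HF", seq_len(k))
  rownames(out) <- colnames(e$values)
  out
}
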