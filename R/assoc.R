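## cis- and trans-association scans with BH FDR and the permutation-averaged
## empirical FDR. Covariates are removed upstream (residualization + INT), so
## the scan model is bivariate OLS per (SNV, feature) pair.

.P_FLOOR <- .Machine$double.xmin

# Vectorized bivariate OLS over column pairs. G: n x m dosage, E: n x k
# expression; pair_i/pair_j select columns (NULL -> full m x k grid).
# Returns beta, se, t and two-sided p (df = n - 2) per pair.
.pair_ols <- function(G, E, pair_i = NULL, pair_j = NULL) {
  n <- nrow(G)
  Gc <- sweep(G, 2, colMeans(G))
  Ec <- sweep(E, 2, colMeans(E))
  Sxx <- colSums(Gc^2)
  Syy <- colSums(Ec^2)
  if (any(Sxx == 0)) stop("constant dosage column in scan")
  if (is.null(pair_i)) {                     # full grid
    Sxy <- crossprod(Gc, Ec)                 # m x k
    beta <- Sxy / Sxx
    rss <- pmax(0, matrix(Syy, nrow(Sxy), ncol(Sxy), byrow = TRUE) - beta * Sxy)
    se <- sqrt(rss / (n - 2) / Sxx)
  } else {
    Sxy <- colSums(Gc[, pair_i, drop = FALSE] * Ec[, pair_j, drop = FALSE])
    beta <- Sxy / Sxx[pair_i]
    rss <- pmax(0, Syy[pair_j] - beta * Sxy)
    se <- sqrt(rss / (n - 2) / Sxx[pair_i])
  }
  # perfect fits (rss = 0 with a nonzero slope) get an infinite t and the
  # floored p rather than a spurious p = 1
  t <- ifelse(se > 0, beta / se, ifelse(beta != 0, sign(beta) * Inf, 0))
  p <- pmax(2 * stats::pt(-abs(t), df = n - 2), .P_FLOOR)
  constant_y <- if (is.null(pair_i)) {
    matrix(Syy == 0, nrow(as.matrix(beta)), length(Syy), byrow = TRUE)
  } else Syy[pair_j] == 0
  beta[constant_y] <- 0; t[constant_y] <- 0; p[constant_y] <- 1
  list(beta = beta, se = se, t = t, p = p)
}

#' Marginal SNV-expression regression
#'
#' OLS of expression on additive dosage with intercept and a two-sided t test
#' on the slope (df = n - 2). This is the per-pair model of both scans:
#' covariates are assumed to have been residualized out of the expression
#' beforehand.
#'
#' @param dosage numeric dosage vector (non-constant, length >= 4)
#' @param expression numeric expression vector of equal length
#' @return list with \code{beta}, \code{se}, \code{t_stat}, \code{p}
#' @export
marginal_regression <- function(dosage, expression) {
  stopifnot(length(dosage) == length(expression), length(dosage) >= 4)
  if (stats::var(dosage) == 0) stop("constant dosage")
  st <- .pair_ols(cbind(dosage), cbind(expression), 1L, 1L)
  list(beta = unname(st$beta), se = unname(st$se),
       t_stat = unname(st$t), p = unname(st$p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, order-preserving with the input.
#'
#' @param p vector of p-values in (0, 1]
#' @return adjusted values
#' @export
bh_fdr <- function(p) {
  if (any(p <= 0 | p > 1 | is.na(p))) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# p-value threshold corresponding to BH FDR < alpha: the largest p called
# significant (0 when nothing passes)
bh_threshold_p <- function(p, alpha = 0.05) {
  fdr <- bh_fdr(p)
  if (!any(fdr < alpha)) return(0)
  max(p[fdr < alpha])
}

.align_samples <- function(g, e) {
  if (!identical(rownames(g$dosage), colnames(e$values)))
    stop("sample order differs between genotypes and expression")
}

#' Gene cis-eQTL scan
#'
#' Tests every SNV against every expressed gene whose nearest boundary lies
#' within \code{window_bp} (1 Mb default) of the SNV position, with BH FDR
#' computed jointly over all cis tests.
#'
#' @param g \code{\link{genotype_matrix}}
#' @param e \code{\link{expression_matrix}} in state \code{inverse_normal},
#'   gene features
#' @param genes \code{\link{gene_models}} (only genes present in \code{e} are
#'   scanned)
#' @param window_bp cis window (default 1e6)
#' @return data.frame with \code{snv_id}, \code{feature_id}, \code{beta},
#'   \code{se}, \code{t_stat}, \code{p}, \code{fdr_bh}
#' @export
cis_scan <- function(g, e, genes, window_bp = 1e6) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(e, "expression_matrix"))
  if (e$state != "inverse_normal")
    stop("scan expects inverse-normal expression")
  .align_samples(g, e)
  gn <- genes$genes[genes$genes$gene_id %in% rownames(e$values), , drop = FALSE]
  empty <- data.frame(snv_id = character(0), feature_id = character(0),
                      beta = numeric(0), se = numeric(0), t_stat = numeric(0),
                      p = numeric(0), fdr_bh = numeric(0))
  if (nrow(gn) == 0) { warning("no genes to scan"); return(empty) }
  lev <- unique(c(g$variants$chrom, gn$chrom))
  snv_gr <- GenomicRanges::GRanges(
    factor(g$variants$chrom, lev),
    IRanges::IRanges(g$variants$pos, g$variants$pos))
  gene_gr <- GenomicRanges::GRanges(
    factor(gn$chrom, lev),
    IRanges::IRanges(pmax(1, gn$start - window_bp), gn$end + window_bp))
  ov <- GenomicRanges::findOverlaps(snv_gr, gene_gr)
  if (length(ov) == 0) { warning("no SNV-gene pairs within window"); return(empty) }
  pi <- S4Vectors::queryHits(ov)
  pj_gene <- S4Vectors::subjectHits(ov)
  pj <- match(gn$gene_id[pj_gene], rownames(e$values))
  st <- .pair_ols(g$dosage, t(e$values), pi, pj)
  data.frame(snv_id = g$variants$id[pi],
             feature_id = gn$gene_id[pj_gene],
             beta = st$beta, se = st$se, t_stat = st$t, p = st$p,
             fdr_bh = bh_fdr(st$p),
             stringsAsFactors = FALSE)
}

#' TE-subfamily trans-eQTL scan
#'
#' Tests every SNV against the genome-aggregated RNA level of every TE
#' subfamily (all m x k pairs). Optionally repeats the scan on \code{n_perm}
#' permuted expression datasets in which the sample labels are scrambled (one
#' shared permutation per round across all subfamilies, preserving their
#' correlation), yielding the null p-value sets used by
#' \code{\link{empirical_fdr}}.
#'
#' @param g \code{\link{genotype_matrix}}
#' @param e \code{\link{expression_matrix}} in state \code{inverse_normal},
#'   TE-subfamily features
#' @param n_perm number of permutation rounds (default 0: none)
#' @param seed integer seed for the permutations
#' @return list of class \code{trans_scan}: \code{results} (data.frame as in
#'   \code{\link{cis_scan}}, plus \code{fdr_emp} when permutations were run)
#'   and \code{perm_p} (list of null p-value vectors, one per round)
#' @export
trans_scan <- function(g, e, n_perm = 0, seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(e, "expression_matrix"))
  if (e$state != "inverse_normal")
    stop("scan expects inverse-normal expression")
  .align_samples(g, e)
  Et <- t(e$values)
  st <- .pair_ols(g$dosage, Et)
  res <- data.frame(
    snv_id = rep(g$variants$id, times = ncol(Et)),
    feature_id = rep(colnames(Et), each = ncol(g$dosage)),
    beta = as.vector(st$beta), se = as.vector(st$se),
    t_stat = as.vector(st$t), p = as.vector(st$p),
    stringsAsFactors = FALSE)
  res$fdr_bh <- bh_fdr(res$p)
  perm_p <- list()
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(Et)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      stp <- .pair_ols(g$dosage, Et[idx, , drop = FALSE])
      perm_p[[b]] <- as.vector(stp$p)
    }
    ef <- empirical_fdr(res$p, perm_p)
    res$fdr_emp <- ef$efdr_at(res$p)
  }
  structure(list(results = res, perm_p = perm_p), class = "trans_scan")
}

#' @export
print.trans_scan <- function(x, ...) {
  cat(sprintf("trans_scan: %d tests, %d permutation rounds\n",
              nrow(x$results), length(x$perm_p)))
  invisible(x)
}

#' Permutation-averaged empirical FDR
#'
#' At a p-value \eqn{p_i}, the empirical FDR is the average number of null
#' points with \eqn{p \le p_i} across permutation rounds, divided by the
#' number of real points with \eqn{p \le p_i}, capped at 1. The threshold at
#' level \eqn{\alpha} is the largest observed real p with eFDR < \eqn{\alpha}
#' (0 when none qualifies).
#'
#' @param p_real vector of real-scan p-values
#' @param p_null list of null p-value vectors, one per permutation round
#' @return list with \code{efdr_at(p)} (vectorized evaluator),
#'   \code{table} (real p with eFDR, sorted), and \code{threshold(alpha)}
#' @export
empirical_fdr <- function(p_real, p_null) {
  stopifnot(length(p_null) >= 1, length(p_real) >= 1)
  n_perm <- length(p_null)
  null_sorted <- sort(unlist(p_null, use.names = FALSE))
  real_sorted <- sort(p_real)
  efdr_at <- function(p) {
    n_null <- findInterval(p, null_sorted) / n_perm
    n_real <- findInterval(p, real_sorted)
    out <- ifelse(n_real > 0, pmin(1, n_null / n_real), NA_real_)
    out
  }
  tab <- data.frame(p = real_sorted, efdr = efdr_at(real_sorted))
  threshold <- function(alpha) {
    ok <- tab$efdr < alpha
    if (!any(ok)) return(0)
    max(tab$p[ok])
  }
  list(efdr_at = efdr_at, table = tab, threshold = threshold)
}

#' Combine the BH and empirical-FDR significance thresholds
#'
#' Associations are called significant when they pass the stricter of the two
#' p-value thresholds: the p at BH FDR < alpha and the p at average empirical
#' FDR < alpha.
#'
#' @param p_bh_alpha p-value threshold from the BH criterion
#' @param p_emp_alpha p-value threshold from the empirical-FDR criterion
#' @param alpha nominal level (annotation only; default 0.05)
#' @param n_permutations number of permutation rounds behind \code{p_emp_alpha}
#' @return list with \code{p_bh}, \code{p_emp}, \code{p_final} (the minimum),
#'   \code{alpha}, \code{n_permutations}
#' @export
significance_threshold <- function(p_bh_alpha, p_emp_alpha, alpha = 0.05,
                                   n_permutations = NA_integer_) {
  stopifnot(p_bh_alpha >= 0, p_emp_alpha >= 0)
  list(p_bh = p_bh_alpha, p_emp = p_emp_alpha,
       p_final = min(p_bh_alpha, p_emp_alpha),
       alpha = alpha, n_permutations = n_permutations)
}

#' Targeted replication scan
#'
#' Re-tests a fixed list of (SNV, feature) pairs — e.g. associations
#' significant in a discovery cohort — in another cohort, with BH FDR over
#' the targeted set only.
#'
#' @param pairs data.frame with columns \code{snv_id}, \code{feature_id}
#' @param g \code{\link{genotype_matrix}} of the replication cohort
#' @param e \code{\link{expression_matrix}} (inverse normal) of the
#'   replication cohort
#' @return data.frame as in \code{\link{cis_scan}}
#' @export
targeted_scan <- function(pairs, g, e) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(e, "expression_matrix"))
  .align_samples(g, e)
  if (nrow(pairs) == 0)
    return(data.frame(snv_id = character(0), feature_id = character(0),
                      beta = numeric(0), se = numeric(0), t_stat = numeric(0),
                      p = numeric(0), fdr_bh = numeric(0)))
  pi <- match(pairs$snv_id, g$variants$id)
  pj <- match(pairs$feature_id, rownames(e$values))
  if (anyNA(pi))
    stop("unknown SNV: ", paste(unique(pairs$snv_id[is.na(pi)]), collapse = ", "))
  if (anyNA(pj))
    stop("unknown feature: ",
         paste(unique(pairs$feature_id[is.na(pj)]), collapse = ", "))
  st <- .pair_ols(g$dosage, t(e$values), pi, pj)
  data.frame(snv_id = pairs$snv_id, feature_id = pairs$feature_id,
             beta = st$beta, se = st$se, t_stat = st$t, p = st$p,
             fdr_bh = bh_fdr(st$p), stringsAsFactors = FALSE)
}
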