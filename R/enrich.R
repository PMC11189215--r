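## Genotype-stratified differential expression (OLS proxy on transformed
## counts), weighted-KS gene-set enrichment over TE family / age / region and
## pathway sets, the one-sample Wilcoxon family-shift alternative, and
## Fisher's-method meta-ranking of shared sets.

#' Genotype- or condition-stratified differential expression
#'
#' Per feature, ordinary least squares of variance-stabilized normalized
#' counts on the grouping term (additively coded 0/1/2 SNV genotype, or a
#' 0/1 condition contrast) plus covariates. The group coefficient is the
#' log2 fold change per allele/contrast unit and the Wald statistic
#' (coefficient / SE) supplies the combined gene + TE ranking consumed by
#' GSEA.
#'
#' @param c a \code{\link{count_matrix}} (filtered)
#' @param group per-sample numeric grouping (non-constant)
#' @param cov optional data.frame of per-sample covariates
#' @return data.frame: \code{feature_id}, \code{log2fc}, \code{wald_stat},
#'   \code{p}, \code{fdr}, sorted as the input features
#' @export
stratified_dge <- function(c, group, cov = NULL) {
  stopifnot(inherits(c, "count_matrix"), length(group) == ncol(c$counts))
  if (stats::var(group) == 0) stop("grouping variable is constant")
  e <- vst_transform(c)
  X <- if (is.null(cov) || ncol(as.data.frame(cov)) == 0) {
    cbind("(Intercept)" = rep(1, length(group)))
  } else .covariate_design(as.data.frame(cov))
  X <- cbind(X, group = group)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient (group collinear with covariates?)")
  Y <- t(e$values)
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv_gg <- chol2inv(qr.R(qrX))[ncol(X), ncol(X)]
  coef_g <- as.matrix(fit$coefficients)["group", ]
  se <- sqrt(sigma2 * XtXinv_gg)
  wald <- ifelse(se > 0, coef_g / se, 0)
  p <- pmax(2 * stats::pt(-abs(wald), df = df), .P_FLOOR)
  data.frame(feature_id = rownames(e$values),
             log2fc = unname(coef_g), wald_stat = unname(wald),
             p = unname(p), fdr = bh_fdr(unname(p)),
             stringsAsFactors = FALSE)
}

# deterministic ranking of a named statistic vector: decreasing stat,
# ties broken by feature ID
.rank_stats <- function(stats_named) {
  ord <- order(-stats_named, names(stats_named))
  stats_named[ord]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running sum over a ranked feature list: set members ("hits")
#' increment by |stat|^\code{weight_exp} normalized by the total over hits;
#' non-members decrement by 1/(N - N_hits). The enrichment score is the
#' running-sum value of largest magnitude (signed). With
#' \code{weight_exp = 0} this reduces to the unweighted KS statistic.
#'
#' @param ranked named numeric vector of ranking statistics, sorted
#'   decreasing (use \code{sort(..., decreasing = TRUE)}; ties by name)
#' @param set character vector of member feature IDs; must hit some but not
#'   all of \code{ranked}
#' @param weight_exp weighting exponent (default 1)
#' @return list with \code{es} and \code{running} (the N-length profile)
#' @export
gsea_es <- function(ranked, set, weight_exp = 1) {
  n <- length(ranked)
  hit <- names(ranked) %in% set
  n_hit <- sum(hit)
  if (n_hit == 0 || n_hit == n)
    stop("set must cover some but not all of the ranked list")
  w <- abs(ranked)^weight_exp
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - n_hit)
  running <- cumsum(inc)
  # signed maximum deviation; a tie in magnitude (within rounding) resolves
  # positive so the sign does not depend on accumulation order
  pos <- max(running); neg <- min(running)
  tol <- 1e-9 * max(pos, -neg, 1e-300)
  es <- if (pos + neg >= -tol) pos else neg
  list(es = es, running = running)
}

#' Gene-set enrichment analysis with a permutation null
#'
#' Runs \code{\link{gsea_es}} for every set, builds a feature-label
#' permutation null per set (random same-size sets from the ranked list),
#' normalizes the score against the mean |null ES| of matching sign, computes
#' an add-one tail p against the matching-sign null, and BH-adjusts across
#' sets. The leading edge contains the set members at or before (after, for
#' negative scores) the running-sum extremum.
#'
#' @param ranked named statistic vector (any order; ranked internally,
#'   decreasing with ties broken by feature ID)
#' @param sets a \code{\link{gene_set_collection}} or named list
#' @param n_perm permutations per set (default 1000; < 100 warns)
#' @param seed integer seed
#' @param weight_exp weighting exponent (default 1)
#' @param min_size minimum members present in the ranked list (default 3)
#' @return data.frame: \code{set_name}, \code{size}, \code{es}, \code{nes},
#'   \code{p}, \code{fdr}, \code{leading_edge} (comma-separated)
#' @export
gsea_run <- function(ranked, sets, n_perm = 1000, seed = 1L, weight_exp = 1,
                     min_size = 3) {
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  ranked <- .rank_stats(ranked)
  set.seed(seed)
  keep <- vapply(sets, function(s) {
    k <- sum(names(ranked) %in% s)
    k >= min_size && k < length(ranked)
  }, logical(1))
  sets <- sets[keep]
  if (length(sets) == 0)
    return(data.frame(set_name = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      fdr = numeric(0), leading_edge = character(0)))
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(names(ranked), sets[[nm]])
    r <- gsea_es(ranked, members, weight_exp)
    null_es <- vapply(seq_len(n_perm), function(b) {
      gsea_es(ranked, sample(names(ranked), length(members)), weight_exp)$es
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(r$es)]
    nes <- if (length(same)) r$es / mean(abs(same)) else sign(r$es) * Inf
    p <- (1 + sum(abs(same) >= abs(r$es))) / (1 + length(same))
    hit_pos <- which(names(ranked) %in% members)
    peak <- which.max(abs(r$running))
    le <- if (r$es >= 0) names(ranked)[hit_pos[hit_pos <= peak]]
          else names(ranked)[hit_pos[hit_pos >= peak]]
    data.frame(set_name = nm, size = length(members), es = r$es, nes = nes,
               p = p, leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out[, c("set_name", "size", "es", "nes", "p", "fdr", "leading_edge")]
}

#' One-sample Wilcoxon family-shift test
#'
#' For each TE family, tests whether its subfamily log2 fold changes are
#' shifted away from zero: exact signed-rank two-sided p for n <= 25 nonzero
#' changes, normal approximation above, BH FDR across families. An
#' alternative to GSEA for detecting subtle family-wide shifts.
#'
#' @param log2fc numeric vector of per-subfamily log2 fold changes
#' @param family character vector of family labels, parallel to \code{log2fc}
#' @return data.frame: \code{family}, \code{n}, \code{median_log2fc},
#'   \code{wilcoxon_V}, \code{p}, \code{fdr}
#' @export
family_wilcoxon <- function(log2fc, family) {
  stopifnot(length(log2fc) == length(family))
  rows <- lapply(split(log2fc, family), function(x) {
    nz <- x[x != 0]
    if (length(nz) == 0) stop("no nonzero changes in family")
    wt <- suppressWarnings(
      stats::wilcox.test(nz, mu = 0, exact = length(nz) <= 25,
                         correct = length(nz) > 25))
    data.frame(n = length(nz), median_log2fc = stats::median(x),
               wilcoxon_V = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(family = names(rows), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (any(out$n < 2))
    warning("families with fewer than 2 nonzero changes give degenerate tests")
  out$fdr <- bh_fdr(out$p)
  out
}

#' Fisher's method for combining p-values
#'
#' \eqn{\chi^2 = -2 \sum \ln p} on 2k degrees of freedom, upper tail. Used to
#' meta-rank gene sets shared between analyses and to combine per-sex
#' analyses.
#'
#' @param p_list numeric vector of p-values in (0, 1]
#' @return list with \code{chi2}, \code{df}, \code{p_combined}
#' @export
fisher_combine <- function(p_list) {
  if (any(p_list <= 0 | p_list > 1)) stop("p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(p_list))
  df <- 2 * length(p_list)
  list(chi2 = chi2, df = df,
       p_combined = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Meta-rank gene sets shared across analyses
#'
#' Keeps sets that are significant (\code{fdr < alpha}) with the required NES
#' sign in every analysis, then ranks them by the Fisher's-method combination
#' of their per-analysis p-values.
#'
#' @param results list (length >= 2) of \code{\link{gsea_run}} data.frames
#' @param sign_pattern numeric vector of required NES signs (+1 / -1), one
#'   per analysis; a single value is recycled
#' @param alpha per-analysis significance level (default 0.05)
#' @return data.frame: \code{set_name}, per-analysis p columns, \code{chi2},
#'   \code{p_combined}, sorted by \code{p_combined}
#' @export
shared_set_meta_rank <- function(results, sign_pattern, alpha = 0.05) {
  stopifnot(length(results) >= 2)
  sign_pattern <- rep_len(sign_pattern, length(results))
  ok_sets <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    r$set_name[r$fdr < alpha & sign(r$nes) == sign_pattern[i]]
  })
  shared <- Reduce(intersect, ok_sets)
  if (length(shared) == 0) {
    message("no shared significant sets with the requested sign pattern")
    return(data.frame(set_name = character(0), chi2 = numeric(0),
                      p_combined = numeric(0)))
  }
  pm <- vapply(results, function(r) r$p[match(shared, r$set_name)],
               numeric(length(shared)))
  pm <- matrix(pm, nrow = length(shared))
  comb <- lapply(seq_along(shared), function(i) fisher_combine(pm[i, ]))
  out <- data.frame(set_name = shared, stringsAsFactors = FALSE)
  for (i in seq_along(results)) out[[paste0("p_", i)]] <- pm[, i]
  out$chi2 <- vapply(comb, `[[`, numeric(1), "chi2")
  out$p_combined <- vapply(comb, `[[`, numeric(1), "p_combined")
  out[order(out$p_combined, out$set_name), , drop = FALSE]
}
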