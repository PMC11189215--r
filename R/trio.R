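## Three-part integration: intersect cis- and trans-significant SNVs, regress
## TE-subfamily expression on gene expression, emit SNV-gene-TE trios, and
## tier candidate genes via LD clumping.

#' Gene vs TE-subfamily expression regression
#'
#' OLS of TE-subfamily expression on gene expression with intercept and a
#' two-sided slope test. For this bivariate model the slope p-value is
#' identical in either regression direction, so the choice of TE-on-gene is
#' inconsequential.
#'
#' @param e_gene,e_te equal-length inverse-normal expression vectors
#' @return list with \code{beta} and \code{p}
#' @export
gene_te_regression <- function(e_gene, e_te) {
  stopifnot(length(e_gene) == length(e_te))
  if (stats::var(e_gene) == 0 || stats::var(e_te) == 0)
    return(list(beta = 0, p = 1))
  st <- .pair_ols(cbind(e_gene), cbind(e_te), 1L, 1L)
  list(beta = unname(st$beta), p = unname(st$p))
}

#' Integrate cis, trans and expression evidence into SNV-gene-TE trios
#'
#' A SNV qualifies when it is significant in the cis scan (\code{fdr_bh <
#' alpha}) and in the trans scan (\code{fdr_bh < alpha}, and additionally
#' \code{p <= p_final} when a stricter-of-two threshold is supplied). For each
#' qualifying SNV, every (cis gene, trans TE subfamily) combination becomes a
#' candidate; gene-TE expression regressions are fitted once per unique
#' (gene, TE) pair and BH-adjusted over all candidate pairs. Trios whose
#' three FDRs are all strictly below \code{alpha} are emitted. Trans-significant
#' SNVs with no cis gene are reported separately as orphans, never dropped.
#'
#' @param cis cis-scan result data.frame (with \code{fdr_bh})
#' @param trans trans-scan result data.frame (with \code{fdr_bh}, \code{p})
#' @param e \code{\link{expression_matrix}} (inverse normal) containing both
#'   the genes and the TE subfamilies referenced by the scans
#' @param alpha significance level (default 0.05, strict \code{<})
#' @param p_final optional trans p-value ceiling from
#'   \code{\link{significance_threshold}}
#' @return list with \code{trios} (data.frame: \code{snv_id}, \code{gene_id},
#'   \code{te_subfamily}, \code{fdr_cis}, \code{fdr_trans},
#'   \code{fdr_regression}) and \code{orphans} (data.frame of orphan SNV
#'   trans hits)
#' @export
integrate_trios <- function(cis, trans, e, alpha = 0.05, p_final = NULL) {
  stopifnot(inherits(e, "expression_matrix"))
  need <- unique(c(cis$feature_id[cis$fdr_bh < alpha],
                   trans$feature_id[trans$fdr_bh < alpha]))
  missing_feat <- setdiff(need, rownames(e$values))
  if (length(missing_feat))
    stop("expression matrix lacks feature(s): ",
         paste(missing_feat, collapse = ", "))
  trans_sig <- trans$fdr_bh < alpha
  if (!is.null(p_final)) trans_sig <- trans_sig & trans$p <= p_final
  trans_hit <- trans[trans_sig, , drop = FALSE]
  cis_hit <- cis[cis$fdr_bh < alpha, , drop = FALSE]
  snv_both <- intersect(unique(trans_hit$snv_id), unique(cis_hit$snv_id))
  orphans <- trans_hit[!trans_hit$snv_id %in% unique(cis_hit$snv_id), ,
                       drop = FALSE]
  empty <- data.frame(snv_id = character(0), gene_id = character(0),
                      te_subfamily = character(0), fdr_cis = numeric(0),
                      fdr_trans = numeric(0), fdr_regression = numeric(0))
  if (length(snv_both) == 0)
    return(list(trios = empty, orphans = orphans))
  cand <- merge(
    cis_hit[cis_hit$snv_id %in% snv_both, c("snv_id", "feature_id", "fdr_bh")],
    trans_hit[trans_hit$snv_id %in% snv_both,
              c("snv_id", "feature_id", "fdr_bh")],
    by = "snv_id", suffixes = c("_cis", "_trans"))
  names(cand) <- c("snv_id", "gene_id", "fdr_cis", "te_subfamily", "fdr_trans")
  pairs <- unique(cand[, c("gene_id", "te_subfamily")])
  pairs$p_reg <- vapply(seq_len(nrow(pairs)), function(i) {
    gene_te_regression(e$values[pairs$gene_id[i], ],
                       e$values[pairs$te_subfamily[i], ])$p
  }, numeric(1))
  pairs$fdr_regression <- bh_fdr(pairs$p_reg)
  cand <- merge(cand, pairs, by = c("gene_id", "te_subfamily"))
  trios <- cand[cand$fdr_cis < alpha & cand$fdr_trans < alpha &
                  cand$fdr_regression < alpha,
                c("snv_id", "gene_id", "te_subfamily", "fdr_cis", "fdr_trans",
                  "fdr_regression")]
  trios <- trios[order(trios$snv_id, trios$gene_id, trios$te_subfamily), ]
  rownames(trios) <- NULL
  list(trios = trios, orphans = orphans)
}

#' Tier trios by LD-clump index status
#'
#' A trio is tier 1 when its SNV is the index (lowest trans-eQTL p) of its LD
#' clump, tier 2 otherwise; a gene is a tier-1 candidate if any of its trios
#' uses an index SNV. Clumping is run on the trans-eQTL p-values of the trio
#' SNVs (see \code{\link{clump_by_pvalue}}).
#'
#' @param trios trio data.frame from \code{\link{integrate_trios}}
#' @param clumps clump assignment data.frame from
#'   \code{\link{clump_by_pvalue}}
#' @return \code{trios} with added \code{is_index_snv}, \code{tier} (trio
#'   level) and \code{gene_tier} (1 if the gene has any index-SNV trio)
#' @export
assign_tiers <- function(trios, clumps) {
  if (nrow(trios) == 0) {
    trios$is_index_snv <- logical(0); trios$tier <- integer(0)
    trios$gene_tier <- integer(0)
    return(trios)
  }
  m <- match(trios$snv_id, clumps$member)
  if (anyNA(m))
    stop("trio SNV absent from clump assignment: ",
         paste(unique(trios$snv_id[is.na(m)]), collapse = ", "))
  trios$is_index_snv <- clumps$is_index[m]
  trios$tier <- ifelse(trios$is_index_snv, 1L, 2L)
  gene_t1 <- unique(trios$gene_id[trios$is_index_snv])
  trios$gene_tier <- ifelse(trios$gene_id %in% gene_t1, 1L, 2L)
  trios
}
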