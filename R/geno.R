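## Genotype QC, LD utilities (pruning, r2, clumping), genotype PCA, and
## SV-derived copy-number covariates.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided HWE p-value for a biallelic site: conditional on the
#' observed allele counts, the probabilities of all heterozygote
#' configurations no more likely than the observed one are summed
#' (Wigginton-style exact test, no mid-p correction). Used for the variant QC
#' threshold p < 1e-6; an exact tail is preferred over the chi-square
#' approximation because that threshold sits deep in the tail.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts
#' @return exact two-sided p-value in (0, 1]
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("empty genotype vector")
  rare <- min(2L * n_hom_alt + n_het, 2L * n_hom_ref + n_het)
  if (rare == 0L) return(1.0)  # monomorphic
  # admissible het counts share the parity of the rare-allele total
  hets <- seq.int(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  # unnormalized log-probabilities of P(het | n, rare):
  #   log[ n! 2^het / (hom_r! het! hom_a!) ]
  logp <- vapply(hets, function(h) {
    hr <- (2L * n - rare - h) / 2L
    ha <- (rare - h) / 2L
    h * log(2) + lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(ha + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  # small relative guard so exactly-tied configurations are always included
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

.variant_maf <- function(dos) {
  af <- mean(dos) / 2
  min(af, 1 - af)
}

.variant_hwe <- function(dos) {
  hwe_exact_test(sum(dos == 0L), sum(dos == 1L), sum(dos == 2L))
}

#' Variant quality-control filter
#'
#' Retains biallelic variants with minor allele frequency (MAF) at least
#' \code{maf_min} and exact-test HWE p at least \code{hwe_p_min}; matches the
#' SNV preparation filter (MAF >= 1\%, HWE p >= 1e-6, complete sites only —
#' completeness is enforced at construction). Survivors are annotated with
#' their computed \code{maf} and \code{hwe_p}.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param maf_min minimum minor allele frequency (default 0.01)
#' @param hwe_p_min minimum HWE exact p (default 1e-6)
#' @return filtered \code{genotype_matrix}; empty (with a warning) if nothing
#'   survives
#' @export
qc_filter_variants <- function(g, maf_min = 0.01, hwe_p_min = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  maf <- apply(g$dosage, 2, .variant_maf)
  hwe <- apply(g$dosage, 2, .variant_hwe)
  biallelic <- !grepl(",", g$variants$alt, fixed = TRUE) &
    nzchar(g$variants$alt) & g$variants$alt != g$variants$ref
  keep <- maf >= maf_min & hwe >= hwe_p_min & biallelic
  if (!any(keep)) warning("no variants pass QC; returning empty matrix")
  v <- g$variants[keep, , drop = FALSE]
  v$maf <- maf[keep]
  v$hwe_p <- hwe[keep]
  genotype_matrix(g$dosage[, keep, drop = FALSE], v)
}

#' Squared dosage correlation (LD r^2)
#'
#' @param a,b equal-length dosage vectors (length >= 3, non-constant)
#' @return squared Pearson correlation in [0, 1]
#' @export
ld_r2 <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::var(a) == 0 || stats::var(b) == 0) stop("zero variance")
  stats::cor(a, b)^2
}

# pairwise r2 among columns; constant columns yield 0 against everything
.r2_matrix <- function(dos) {
  sds <- apply(dos, 2, stats::sd)
  r <- suppressWarnings(stats::cor(dos))
  r[is.na(r)] <- 0
  r[sds == 0, ] <- 0
  r[, sds == 0] <- 0
  r^2
}

.check_sorted <- function(variants) {
  o <- order(variants$chrom, variants$pos)
  if (!identical(o, seq_len(nrow(variants))))
    stop("variants must be sorted by (chrom, pos)")
}

#' Sliding-window LD pruning
#'
#' Greedy pruning in the spirit of the \code{indep-pairwise 50 10 0.1} rule:
#' within each window of \code{window} variants (per chromosome), while any
#' retained pair has r^2 > \code{r2_max}, the member with the lower MAF is
#' removed (ties broken by removing the later position); the window then
#' advances by \code{step} variants. Deterministic for a fixed input.
#'
#' @param g a \code{\link{genotype_matrix}} sorted by (chrom, pos)
#' @param window window size in variants (default 50)
#' @param step window increment in variants (default 10)
#' @param r2_max r^2 ceiling (default 0.1)
#' @return pruned \code{genotype_matrix}
#' @export
prune_ld <- function(g, window = 50, step = 10, r2_max = 0.1) {
  stopifnot(inherits(g, "genotype_matrix"))
  .check_sorted(g$variants)
  maf <- apply(g$dosage, 2, .variant_maf)
  keep <- rep(TRUE, ncol(g$dosage))
  for (chr in unique(g$variants$chrom)) {
    cidx <- which(g$variants$chrom == chr)
    nc <- length(cidx)
    for (s in seq(1, max(nc - 1, 1), by = step)) {
      widx <- cidx[s:min(s + window - 1, nc)]
      widx <- widx[keep[widx]]
      if (length(widx) < 2) next
      r2 <- .r2_matrix(g$dosage[, widx, drop = FALSE])
      alive <- rep(TRUE, length(widx))
      repeat {
        off <- which(r2 > r2_max & upper.tri(r2), arr.ind = TRUE)
        off <- off[alive[off[, 1]] & alive[off[, 2]], , drop = FALSE]
        if (nrow(off) == 0) break
        i <- off[1, 1]; j <- off[1, 2]
        vi <- widx[i]; vj <- widx[j]
        # lower MAF loses; tie -> later position loses
        drop_j <- maf[vj] < maf[vi] || (maf[vj] == maf[vi])
        victim <- if (drop_j) j else i
        alive[victim] <- FALSE
        r2[victim, ] <- 0
        r2[, victim] <- 0
      }
      keep[widx[!alive]] <- FALSE
    }
  }
  genotype_matrix(g$dosage[, keep, drop = FALSE],
                  g$variants[keep, , drop = FALSE])
}

#' Principal components of genotype dosages
#'
#' PCA of the column-standardized dosage matrix (per-variant mean-centering
#' and unit-variance scaling; zero-variance columns are dropped with a
#' warning). Components are ordered by explained variance; each component's
#' sign is fixed so that its largest-magnitude variant loading is positive.
#' Callers should prune the panel first so the leading components reflect
#' genome-wide ancestry rather than a single LD block.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param n_pcs number of components to return
#' @return data.frame of PC scores (samples x PCs) with attribute
#'   \code{"explained_variance"}
#' @export
genotype_pca <- function(g, n_pcs) {
  stopifnot(inherits(g, "genotype_matrix"),
            nrow(g$dosage) >= 2, ncol(g$dosage) >= 2)
  sds <- apply(g$dosage, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance variant(s) before PCA",
                    sum(sds == 0)))
  }
  X <- scale(g$dosage[, sds > 0, drop = FALSE])
  if (n_pcs > min(dim(X))) stop("n_pcs exceeds min(samples, variants)")
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  for (k in seq_len(n_pcs)) {
    peak <- which.max(abs(rot[, k]))
    if (rot[peak, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  out <- as.data.frame(scores)
  names(out) <- paste0("PC", seq_len(n_pcs))
  rownames(out) <- rownames(g$dosage)
  attr(out, "explained_variance") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pcs)]
  out
}

#' Greedy LD clumping by p-value
#'
#' Repeatedly takes the unassigned variant with the smallest p-value as an
#' index SNV and assigns to its clump every unassigned variant on the same
#' chromosome within \code{window_bp} of it and with r^2 > \code{r2_min} to
#' it (500 kb / r^2 > 0.10 by default, the clumping rule used to tier
#' trans-eQTL hits). Ties in p are broken by (chrom, pos).
#'
#' @param p named numeric vector of p-values (names are variant IDs)
#' @param g a \code{\link{genotype_matrix}} containing all named variants
#' @param window_bp clumping window in bp (default 5e5)
#' @param r2_min r^2 floor for joining a clump (default 0.1)
#' @return data.frame with columns \code{index_snv}, \code{member},
#'   \code{member_p}, \code{is_index}; every input variant appears exactly once
#' @export
clump_by_pvalue <- function(p, g, window_bp = 5e5, r2_min = 0.1) {
  stopifnot(inherits(g, "genotype_matrix"), length(p) > 0, !is.null(names(p)))
  miss <- setdiff(names(p), g$variants$id)
  if (length(miss))
    stop("variant(s) absent from genotype matrix: ", paste(miss, collapse = ", "))
  vm <- g$variants[match(names(p), g$variants$id), ]
  ord <- order(p, vm$chrom, vm$pos)
  ids <- names(p)
  assigned <- rep(NA_character_, length(p))
  names(assigned) <- ids
  for (k in ord) {
    id <- ids[k]
    if (!is.na(assigned[id])) next
    assigned[id] <- id
    near <- which(is.na(assigned) &
                    vm$chrom == vm$chrom[k] &
                    abs(vm$pos - vm$pos[k]) <= window_bp)
    if (length(near)) {
      a <- g$dosage[, id]
      for (j in near) {
        b <- g$dosage[, ids[j]]
        if (stats::var(a) == 0 || stats::var(b) == 0) next
        if (stats::cor(a, b)^2 > r2_min) assigned[ids[j]] <- id
      }
    }
  }
  data.frame(index_snv = unname(assigned),
             member = ids,
             member_p = unname(p),
             is_index = unname(assigned) == ids,
             stringsAsFactors = FALSE)
}

#' Structural-variant record set
#'
#' @param dosage sample x SV dosage matrix (0/1/2)
#' @param sv_class per-SV class, one of \code{L1_insertion}, \code{L1_deletion},
#'   \code{Alu_insertion}, \code{Alu_deletion}, \code{other}
#' @return object of class \code{sv_set}
#' @export
sv_set <- function(dosage, sv_class) {
  dosage <- as.matrix(dosage)
  sv_class <- rep_len(as.character(sv_class), ncol(dosage))
  bad <- setdiff(unique(sv_class),
                 c("L1_insertion", "L1_deletion", "Alu_insertion",
                   "Alu_deletion", "other"))
  if (length(bad)) stop("unknown sv_class: ", paste(bad, collapse = ", "))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, sv_class = sv_class), class = "sv_set")
}

#' Net L1/Alu copy-number score
#'
#' Per-sample net retrotransposon copy-number load: the summed dosages of L1
#' and Alu insertions minus the summed dosages of L1 and Alu deletions.
#' \code{other} SV classes are ignored. Used as a covariate to control for
#' inter-individual differences in genomic TE copy-number load.
#'
#' @param svs an \code{\link{sv_set}}
#' @return named integer vector, one score per sample
#' @export
net_te_copy_number <- function(svs) {
  stopifnot(inherits(svs, "sv_set"))
  ins <- svs$sv_class %in% c("L1_insertion", "Alu_insertion")
  del <- svs$sv_class %in% c("L1_deletion", "Alu_deletion")
  score <- rowSums(svs$dosage[, ins, drop = FALSE]) -
    rowSums(svs$dosage[, del, drop = FALSE])
  stats::setNames(as.integer(score), rownames(svs$dosage))
}
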