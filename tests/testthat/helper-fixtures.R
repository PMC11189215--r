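# Small in-code fixture builders shared across the suite.

# genotype matrix from a dosage matrix given as samples x variants, with
# evenly spaced positions on one chromosome unless positions are supplied
make_geno <- function(dosage, chrom = "chr1", pos = NULL, ids = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = m)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(m))
  rownames(dosage) <- sprintf("S%03d", seq_len(nrow(dosage)))
  genotype_matrix(dosage,
                  data.frame(id = ids, chrom = rep_len(chrom, m), pos = pos,
                             ref = "A", alt = "G",
                             stringsAsFactors = FALSE))
}

# random segregating dosage matrix (no LD structure)
random_geno <- function(n, m, seed = 1, maf_range = c(0.1, 0.5)) {
  set.seed(seed)
  f <- runif(m, maf_range[1], maf_range[2])
  make_geno(matrix(rbinom(n * m, 2, rep(f, each = n)), n, m))
}

# count matrix with given dims; all-gene kind by default
random_counts <- function(n_feat, n_samp, seed = 1, kind = "gene",
                          lambda = 100) {
  set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, lambda), n_feat, n_samp)
  rownames(m) <- sprintf("f%03d", seq_len(n_feat))
  colnames(m) <- sprintf("S%03d", seq_len(n_samp))
  count_matrix(m, kind)
}

# inverse-normal expression matrix from a values matrix (features x samples)
make_int_expr <- function(values, kind = "gene") {
  rn <- rownames(values); cn <- colnames(values)
  if (is.null(rn)) rn <- sprintf("f%03d", seq_len(nrow(values)))
  if (is.null(cn)) cn <- sprintf("S%03d", seq_len(ncol(values)))
  dimnames(values) <- list(rn, cn)
  e <- expression_matrix(values, kind, "residualized")
  inverse_normal_transform(e)
}

# independent exact signed-rank two-sided p by full 2^n enumeration
wilcoxon_exact_enum <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# independent naive GSEA running-sum computation
gsea_es_naive <- function(ranked, set, weight_exp = 1) {
  hit <- names(ranked) %in% set
  tot_w <- sum(abs(ranked[hit])^weight_exp)
  run <- 0; pos <- -Inf; neg <- Inf
  for (i in seq_along(ranked)) {
    run <- if (hit[i]) run + abs(ranked[i])^weight_exp / tot_w
           else run - 1 / (length(ranked) - sum(hit))
    pos <- max(pos, run); neg <- min(neg, run)
  }
  tol <- 1e-9 * max(pos, -neg, 1e-300)
  unname(if (pos + neg >= -tol) pos else neg)
}

# independent HWE tail probability by direct enumeration over heterozygote
# configurations with the same allele totals (choose()-based, n <= 50)
hwe_enum <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  rare <- min(2 * n_hom_alt + n_het, 2 * n_hom_ref + n_het)
  if (rare == 0) return(1.0)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  w <- vapply(hets, function(h) {
    hr <- (2 * n - rare - h) / 2
    choose(n, hr) * choose(n - hr, h) * 2^h
  }, numeric(1))
  obs <- w[hets == n_het]
  min(1, sum(w[w <= obs * (1 + 1e-9)]) / sum(w))
}
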