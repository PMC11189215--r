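# Genotype QC, LD utilities, PCA and copy-number covariates.

test_that("HWE exact test matches enumeration and handles edge cases", {
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)
  expect_equal(hwe_exact_test(5, 10, 5), hwe_enum(5, 10, 5), tolerance = 1e-12)
  # extreme heterozygote excess fails the QC threshold
  p_het <- hwe_exact_test(0, 50, 0)
  expect_lt(p_het, 1e-6)
  expect_equal(p_het, hwe_enum(0, 50, 0), tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "empty")
  # random configurations up to n = 50 agree with the oracle
  set.seed(42)
  for (i in 1:40) {
    n <- sample(3:50, 1)
    cnt <- as.vector(stats::rmultinom(1, n, prob = c(0.4, 0.4, 0.2)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_enum(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("variant QC filters on MAF, HWE and biallelic status", {
  g <- make_geno(cbind(c(0, 0, 1, 2), c(0, 0, 0, 0), c(0, 1, 1, 2)))
  f <- qc_filter_variants(g)
  expect_equal(f$variants$id, c("v001", "v003"))
  expect_equal(f$variants$maf[1], 3 / 8)      # hand allele count 3/8
  # monomorphic column dropped (maf 0 < 0.01)
  expect_false("v002" %in% f$variants$id)
  # idempotence: filtering a filtered matrix changes nothing
  f2 <- qc_filter_variants(f)
  expect_identical(f2$dosage, f$dosage)
  expect_equal(f2$variants, f$variants)
  # empty result warns, does not error
  mono <- make_geno(cbind(rep(0, 4), rep(2, 4)))
  expect_warning(ef <- qc_filter_variants(mono), "no variants")
  expect_equal(ncol(ef$dosage), 0)
})

test_that("QC filter equals an independent per-variant loop on a panel", {
  g <- random_geno(60, 1000, seed = 7, maf_range = c(0.005, 0.5))
  f <- qc_filter_variants(g)
  keep <- vapply(seq_len(1000), function(j) {
    d <- g$dosage[, j]
    af <- sum(d) / (2 * length(d))
    maf <- min(af, 1 - af)
    p <- hwe_enum(sum(d == 0), sum(d == 1), sum(d == 2))
    maf >= 0.01 && p >= 1e-6
  }, logical(1))
  expect_equal(f$variants$id, g$variants$id[keep])
})

test_that("ld_r2 is squared Pearson correlation with guards", {
  a <- c(0, 2, 0, 2, 1, 1)
  expect_equal(ld_r2(a, a), 1.0)
  expect_equal(ld_r2(c(0, 2, 0, 2), c(0, 0, 2, 2)), 0.0)
  set.seed(1)
  x <- rbinom(30, 2, 0.4); y <- rbinom(30, 2, 0.4)
  expect_equal(ld_r2(x, y),
               (sum((x - mean(x)) * (y - mean(y))) /
                  sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2)
  expect_error(ld_r2(rep(1, 5), c(0, 1, 2, 1, 0)), "zero variance")
})

test_that("LD pruning removes the lower-MAF member of correlated pairs", {
  set.seed(3)
  base <- matrix(rbinom(40 * 10, 2, 0.4), 40, 10)
  g0 <- make_geno(base)
  # orthogonal-ish panel with all r2 <= 0.1: identity after pruning
  r2 <- suppressWarnings(cor(base)^2)
  if (all(r2[upper.tri(r2)] <= 0.1))
    expect_equal(prune_ld(g0)$variants$id, g0$variants$id)
  # duplicated column: exactly one of the duplicate pair survives
  dup <- cbind(base, base[, 1])
  gd <- make_geno(dup)
  pr <- prune_ld(gd)
  expect_equal(sum(c("v001", "v011") %in% pr$variants$id), 1)
  expect_error(prune_ld(make_geno(base, pos = rev(seq_len(10) * 1000))),
               "sorted")
})

test_that("pruning equals an independent reference loop on a toy panel", {
  set.seed(9)
  n <- 50; m <- 60
  f <- runif(m, 0.1, 0.5)
  base <- matrix(rbinom(n * m, 2, rep(f, each = n)), n, m)
  # plant LD by copying some columns with noise
  for (j in seq(5, 55, by = 10)) {
    base[, j + 1] <- base[, j]
    flip <- sample(n, 4)
    base[flip, j + 1] <- rbinom(4, 2, f[j])
  }
  g <- make_geno(base)
  got <- prune_ld(g, window = 15, step = 5, r2_max = 0.1)

  # reference: same greedy rule written as plain loops
  maf <- apply(base, 2, function(d) min(mean(d) / 2, 1 - mean(d) / 2))
  keep <- rep(TRUE, m)
  for (s in seq(1, m - 1, by = 5)) {
    repeat {
      w <- intersect(s:min(s + 14, m), which(keep))
      victim <- NULL
      for (i in w) {
        for (j in w[w > i]) {
          if (sd(base[, i]) == 0 || sd(base[, j]) == 0) next
          if (cor(base[, i], base[, j])^2 > 0.1) {
            victim <- if (maf[j] < maf[i] || maf[j] == maf[i]) j else i
            break
          }
        }
        if (!is.null(victim)) break
      }
      if (is.null(victim)) break
      keep[victim] <- FALSE
    }
  }
  expect_equal(got$variants$id, g$variants$id[keep])
})

test_that("genotype PCA matches dense eigendecomposition and is orthogonal", {
  set.seed(5)
  X <- matrix(rbinom(20 * 8, 2, 0.4), 20, 8)
  g <- make_geno(X)
  pcs <- genotype_pca(g, 4)
  Xs <- scale(X)
  ev <- eigen(stats::cov(Xs))
  scores <- Xs %*% ev$vectors[, 1:4]
  for (k in 1:4)
    expect_equal(abs(pcs[[k]]), abs(scores[, k]), ignore_attr = TRUE,
                 tolerance = 1e-8)
  # orthogonality of score columns
  gram <- crossprod(as.matrix(pcs))
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # sign convention: largest-magnitude loading positive => deterministic
  pcs2 <- genotype_pca(g, 4)
  expect_identical(pcs, pcs2)
  expect_error(genotype_pca(g, 21), "exceeds")
})

test_that("PCA drops constant variants with a warning", {
  X <- cbind(rep(1, 10), rbinom(10, 2, 0.5), rbinom(10, 2, 0.5))
  X[1, 2] <- 2 - X[1, 2]  # ensure non-constant
  g <- make_geno(X)
  expect_warning(pcs <- genotype_pca(g, 2), "zero-variance")
  expect_equal(ncol(pcs), 2)
})

test_that("PC1-2 separate two simulated populations", {
  cfg <- sim_config(n_samples = 200, n_snvs = 2000, fst = 0.1)
  geno <- simulate_genotypes(cfg, seed = 21)
  pr <- prune_ld(qc_filter_variants(geno$genotypes))
  pcs <- genotype_pca(pr, 2)
  pop <- geno$sample_info$population
  cent <- lapply(split(as.data.frame(pcs), pop), colMeans)
  d2 <- sapply(names(cent), function(k)
    rowSums((as.matrix(pcs) -
               matrix(cent[[k]], nrow(pcs), 2, byrow = TRUE))^2))
  assigned <- colnames(d2)[apply(d2, 1, which.min)]
  expect_gte(mean(assigned == pop), 0.95)
  # between-population distance on PC1 exceeds within-population spread
  expect_gt(abs(diff(tapply(pcs$PC1, pop, mean))),
            max(tapply(pcs$PC1, pop, sd)))
})

test_that("clumping follows the greedy p-value rule", {
  # A and B in LD, C independent, all within 500 kb
  A <- c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2)
  B <- A; B[c(1, 5)] <- c(1, 0)
  C <- c(0, 1, 2, 1, 1, 1, 1, 1, 0, 1, 2, 1)
  stopifnot(ld_r2(A, B) > 0.1, ld_r2(A, C) <= 0.1, ld_r2(B, C) <= 0.1)
  g <- make_geno(cbind(A, B, C), pos = c(1e5, 2e5, 3e5),
                 ids = c("A", "B", "C"))
  p <- c(A = 1e-8, B = 1e-6, C = 1e-7)
  cl <- clump_by_pvalue(p, g)
  expect_setequal(cl$index_snv[cl$is_index], c("A", "C"))
  expect_equal(cl$index_snv[cl$member == "B"], "A")
  # partition: every variant in exactly one clump
  expect_setequal(cl$member, names(p))
  expect_equal(anyDuplicated(cl$member), 0)
  # index p <= member p within each clump
  for (ix in unique(cl$index_snv))
    expect_true(all(p[ix] <= cl$member_p[cl$index_snv == ix]))
})

test_that("clumping edge cases: singletons and unknown variants", {
  g <- make_geno(cbind(c(0, 1, 2, 1, 0, 1)))
  cl <- clump_by_pvalue(c(v001 = 0.01), g)
  expect_true(cl$is_index)
  expect_error(clump_by_pvalue(c(nope = 0.01), g), "nope")
  # no pair above r2 threshold: everyone is an index
  set.seed(11)
  gm <- random_geno(80, 6, seed = 11)
  r2 <- cor(gm$dosage)^2
  if (all(r2[upper.tri(r2)] <= 0.1)) {
    p6 <- setNames(runif(6), gm$variants$id)
    cl6 <- clump_by_pvalue(p6, gm)
    expect_true(all(cl6$is_index))
  }
})

test_that("net TE copy number adds insertions and subtracts deletions", {
  dos <- rbind(c(1, 2, 1, 0, 2), c(0, 1, 0, 1, 0))
  svs <- sv_set(dos, c("L1_insertion", "Alu_insertion", "L1_deletion",
                       "Alu_deletion", "other"))
  expect_equal(unname(net_te_copy_number(svs)), c(1 + 2 - 1 - 0, 0 + 1 - 0 - 1))
  # no L1/Alu SVs -> zeros
  svs0 <- sv_set(cbind(c(1, 2)), "other")
  expect_equal(unname(net_te_copy_number(svs0)), c(0, 0))
  # random table equals naive per-sample loop
  set.seed(2)
  d <- matrix(rbinom(8 * 10, 2, 0.3), 8, 10)
  cls <- sample(c("L1_insertion", "L1_deletion", "Alu_insertion",
                  "Alu_deletion", "other"), 10, replace = TRUE)
  svr <- sv_set(d, cls)
  naive <- sapply(1:8, function(i)
    sum(d[i, cls %in% c("L1_insertion", "Alu_insertion")]) -
      sum(d[i, cls %in% c("L1_deletion", "Alu_deletion")]))
  expect_equal(unname(net_te_copy_number(svr)), naive)
})
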