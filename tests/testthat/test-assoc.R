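# cis/trans scans, BH FDR, permutation-averaged empirical FDR, thresholds,
# targeted replication.

test_that("marginal regression matches the textbook closed form", {
  set.seed(20)
  x <- rbinom(10, 2, 0.5); y <- rnorm(10) + 0.5 * x
  got <- marginal_regression(x, y)
  # closed-form slope, SE and two-sided t-test
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  res <- y - mean(y) - beta * (x - mean(x))
  se <- sqrt(sum(res^2) / 8 / sum((x - mean(x))^2))
  expect_equal(got$beta, beta, tolerance = 1e-12)
  expect_equal(got$se, se, tolerance = 1e-12)
  expect_equal(got$t_stat, beta / se, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(beta / se), 8), tolerance = 1e-12)
  # agreement with lm() as an independent reference
  fit <- summary(lm(y ~ x))$coefficients
  expect_equal(got$beta, fit["x", "Estimate"])
  expect_equal(got$p, fit["x", "Pr(>|t|)"])
  # constant expression -> beta 0, p 1; constant dosage -> error
  flat <- marginal_regression(x, rep(1, 10))
  expect_equal(flat$beta, 0); expect_equal(flat$p, 1)
  expect_error(marginal_regression(rep(1, 10), y), "constant dosage")
})

test_that("regression p-values are uniform under the null", {
  set.seed(21)
  x <- rbinom(200, 2, 0.3)
  p <- replicate(2000, marginal_regression(x, rnorm(200))$p)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment equals the hand step-up evaluation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.001, 0.04, 0.9)), c(0.003, 0.06, 0.9))
  # order-preserving with the input
  p <- c(0.9, 0.001, 0.04)
  expect_equal(bh_fdr(p), c(0.9, 0.003, 0.06))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("cis scan pairs SNVs and genes by the 1 Mb boundary rule", {
  set.seed(22)
  n <- 60
  g <- make_geno(matrix(rbinom(n * 5, 2, 0.4), n, 5),
                 pos = c(1e5, 9e5, 1.5e6, 2.6e6, 5e6))
  gm <- gene_models(
    data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
               start = c(1.4e6, 4.2e6), end = c(1.45e6, 4.25e6)),
    data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
               start = c(1.4e6, 4.2e6), end = c(1.41e6, 4.21e6)))
  vals <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("gA", "gB"), rownames(g$dosage)))
  e <- make_int_expr(vals)
  res <- cis_scan(g, e, gm)
  # roster from a naive double loop over the distance rule
  roster <- expand.grid(v = g$variants$id, gene = c("gA", "gB"),
                        stringsAsFactors = FALSE)
  keep <- mapply(function(v, gene) {
    pos <- g$variants$pos[g$variants$id == v]
    row <- gm$genes[gm$genes$gene_id == gene, ]
    max(0, row$start - pos, pos - row$end) <= 1e6
  }, roster$v, roster$gene)
  expect_setequal(paste(res$snv_id, res$feature_id),
                  paste(roster$v, roster$gene)[keep])
  # each pair equals the marginal regression on the same vectors
  i <- 1
  mr <- marginal_regression(g$dosage[, res$snv_id[i]],
                            e$values[res$feature_id[i], ])
  expect_equal(res$beta[i], mr$beta)
  expect_equal(res$p[i], mr$p)
  # a gene 2 Mb from the only SNV yields zero tests
  far_gm <- gene_models(
    data.frame(gene_id = "gF", chrom = "chr1", start = 3e6, end = 3.1e6),
    data.frame(gene_id = "gF", chrom = "chr1", start = 3e6, end = 3.01e6))
  one <- make_geno(cbind(rbinom(n, 2, 0.4)), pos = 1e5)
  vf <- matrix(rnorm(n), 1, n, dimnames = list("gF", rownames(one$dosage)))
  expect_warning(r0 <- cis_scan(one, make_int_expr(vf), far_gm), "no SNV-gene")
  expect_equal(nrow(r0), 0)
})

test_that("planted cis effect is recovered at FDR < 0.05", {
  set.seed(23)
  n <- 200
  dos <- matrix(rbinom(n * 20, 2, 0.3), n, 20)
  g <- make_geno(dos, pos = seq(1e5, by = 5e4, length.out = 20))
  gm <- gene_models(
    data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
               start = seq(2e5, by = 2e5, length.out = 4),
               end = seq(2e5, by = 2e5, length.out = 4) + 1e4),
    data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
               start = seq(2e5, by = 2e5, length.out = 4),
               end = seq(2e5, by = 2e5, length.out = 4) + 1000))
  vals <- matrix(rnorm(4 * n), 4, n, dimnames = list(paste0("g", 1:4), NULL))
  vals[2, ] <- vals[2, ] + 0.6 * dos[, 5]
  e <- make_int_expr(vals)
  colnames(e$values) <- rownames(g$dosage)
  res <- cis_scan(g, e, gm)
  hit <- res[res$snv_id == "v005" & res$feature_id == "g2", ]
  expect_lt(hit$fdr_bh, 0.05)
})

test_that("trans scan tests every SNV x subfamily pair consistently", {
  set.seed(24)
  n <- 80
  g <- make_geno(matrix(rbinom(n * 7, 2, 0.4), n, 7))
  vals <- matrix(rnorm(3 * n), 3, n,
                 dimnames = list(c("AluY", "L1HS", "MIR"), NULL))
  e <- make_int_expr(vals, "te_subfamily")
  colnames(e$values) <- rownames(g$dosage)
  ts <- trans_scan(g, e)
  expect_equal(nrow(ts$results), 7 * 3)
  k <- 11
  mr <- marginal_regression(g$dosage[, ts$results$snv_id[k]],
                            e$values[ts$results$feature_id[k], ])
  expect_equal(ts$results$p[k], mr$p)
  expect_equal(ts$results$beta[k], mr$beta)
})

test_that("scan results are invariant to consistent sample reordering", {
  set.seed(25)
  n <- 50
  g <- make_geno(matrix(rbinom(n * 4, 2, 0.4), n, 4))
  vals <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("a", "b"), NULL))
  e <- make_int_expr(vals, "te_subfamily")
  colnames(e$values) <- rownames(g$dosage)
  r1 <- trans_scan(g, e)$results
  ord <- sample(n)
  g2 <- genotype_matrix(g$dosage[ord, ], g$variants)
  e2 <- expression_matrix(e$values[, ord], "te_subfamily", "inverse_normal")
  r2 <- trans_scan(g2, e2)$results
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-12)
})

test_that("empirical FDR reproduces the three-step hand count", {
  real <- c(0.001, 0.01, 0.05)
  nulls <- list(c(0.02, 0.2, 0.6), c(0.005, 0.3, 0.9))
  ef <- empirical_fdr(real, nulls)
  # nulls <= 0.01: 1 across 2 permutations -> 0.5 average; real <= 0.01: 2
  expect_equal(ef$efdr_at(0.01), 0.25)
  # no null at or below the smallest real p -> eFDR 0
  expect_equal(ef$efdr_at(0.001), 0)
  # threshold: largest real p with eFDR < alpha
  expect_equal(ef$threshold(0.3), 0.01)
  # one permutation with null p identical to real p -> eFDR(max p) = 1,
  # and no real p has eFDR < alpha -> threshold 0
  ef2 <- empirical_fdr(real, list(real))
  expect_equal(ef2$efdr_at(max(real)), 1)
  expect_equal(ef2$threshold(0.05), 0)
  # capped at 1
  ef3 <- empirical_fdr(c(0.5), list(c(0.1, 0.2), c(0.3, 0.4)))
  expect_equal(ef3$efdr_at(0.5), 1)
})

test_that("empirical FDR threshold is reproducible from stored null sets", {
  set.seed(26)
  real <- runif(500)^2
  nulls <- lapply(1:20, function(i) runif(500))
  ef <- empirical_fdr(real, nulls)
  # round-trip the null sets through disk as the pipeline stores them
  tmp <- tempfile(); dir.create(tmp)
  for (i in seq_along(nulls))
    write.table(data.frame(p = nulls[[i]]), file.path(tmp, paste0(i, ".tsv")),
                sep = "\t", row.names = FALSE)
  nulls2 <- lapply(seq_along(nulls), function(i)
    read.table(file.path(tmp, paste0(i, ".tsv")), header = TRUE)$p)
  ef2 <- empirical_fdr(real, nulls2)
  expect_equal(ef$threshold(0.05), ef2$threshold(0.05))
  expect_equal(ef$table$efdr, ef2$table$efdr)
  unlink(tmp, recursive = TRUE)
})

test_that("permutation rounds are seeded and reproducible", {
  set.seed(27)
  n <- 40
  g <- make_geno(matrix(rbinom(n * 5, 2, 0.4), n, 5))
  vals <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("a", "b"), NULL))
  e <- make_int_expr(vals, "te_subfamily")
  colnames(e$values) <- rownames(g$dosage)
  t1 <- trans_scan(g, e, n_perm = 5, seed = 99)
  t2 <- trans_scan(g, e, n_perm = 5, seed = 99)
  expect_identical(t1$perm_p, t2$perm_p)
  expect_identical(t1$results$fdr_emp, t2$results$fdr_emp)
  t3 <- trans_scan(g, e, n_perm = 5, seed = 100)
  expect_false(identical(t1$perm_p, t3$perm_p))
})

test_that("the stricter of the two thresholds wins", {
  th <- significance_threshold(2.31e-8, 3.44e-8)
  expect_equal(th$p_final, 2.31e-8)
  expect_equal(significance_threshold(1e-5, 1e-5)$p_final, 1e-5)
  # an empirical threshold of 0 (nothing passes) blocks all calls
  expect_equal(significance_threshold(1e-5, 0)$p_final, 0)
})

test_that("targeted scan reuses statistics with its own FDR family", {
  set.seed(28)
  n <- 86
  g <- make_geno(matrix(rbinom(n * 6, 2, 0.4), n, 6))
  vals <- matrix(rnorm(3 * n), 3, n,
                 dimnames = list(c("x", "y", "z"), NULL))
  vals[1, ] <- vals[1, ] + 0.8 * g$dosage[, 2]   # planted replication effect
  e <- make_int_expr(vals, "te_subfamily")
  colnames(e$values) <- rownames(g$dosage)
  full <- trans_scan(g, e)$results
  pairs <- full[, c("snv_id", "feature_id")]
  tg <- targeted_scan(pairs, g, e)
  expect_equal(tg$p, full$p)                      # same statistics
  sub <- targeted_scan(pairs[1:4, ], g, e)
  expect_equal(sub$p, full$p[1:4])
  expect_equal(sub$fdr_bh, p.adjust(full$p[1:4], "BH"))  # own FDR family
  # planted effect replicates at fdr < 0.05 at n = 86 scale
  expect_lt(tg$fdr_bh[tg$snv_id == "v002" & tg$feature_id == "x"], 0.05)
  expect_equal(nrow(targeted_scan(pairs[0, ], g, e)), 0)
  bad <- data.frame(snv_id = "v999", feature_id = "x")
  expect_error(targeted_scan(bad, g, e), "v999")
})
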