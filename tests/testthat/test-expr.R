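# Expression preparation: filtering, normalization, residualization, INT,
# hidden factors.

test_that("low-expression filter applies the strict CPM-in-fraction rule", {
  # 4-sample toy with hand-computed CPM table; cpm_min 1.0, min_fraction 0.75
  counts <- rbind(f1 = c(5, 5, 5, 5),       # cpm 5000... passes everywhere
                  f2 = c(0, 0, 0, 0),       # all zero -> out
                  f3 = c(1, 0, 1, 1),       # passes in 3/4 samples
                  f4 = c(1, 1, 0, 0))       # passes in 2/4 -> out
  colnames(counts) <- paste0("S", 1:4)
  cm <- count_matrix(counts, "gene")
  f <- filter_low_expression(cm, cpm_min = 1.0, min_fraction = 0.75)
  expect_setequal(rownames(f$counts), c("f1", "f3"))
  expect_error(filter_low_expression(cm, -1), "nonnegative")
  # the comparison is strict: a feature sitting exactly at cpm_min fails
  one <- count_matrix(rbind(g = c(1, 1)), "gene", library_size = c(1e6, 1e6))
  expect_equal(nrow(filter_low_expression(one, 1, 1)$counts), 0)
})

test_that("CPM helper reproduces the reads-in-median-library rule", {
  lib <- c(20e6, 22.7e6, 25e6)
  expect_equal(cpm_for_reads(10, lib), 10 * 1e6 / 22.7e6)
})

test_that("median-of-ratios size factors behave as expected", {
  cm <- random_counts(50, 6, seed = 4, lambda = 200)
  f <- size_factors_median_ratio(cm)
  # direct formula evaluation
  lg <- log(cm$counts[rowSums(cm$counts > 0) == 6, ])
  raw <- exp(apply(lg - rowMeans(lg), 2, median))
  expect_equal(f, raw / exp(mean(log(raw))))
  expect_equal(exp(mean(log(f))), 1)
  # identical columns -> all ones
  same <- count_matrix(matrix(rep(c(10, 20, 30), 3), 3, 3,
                              dimnames = list(letters[1:3], NULL)), "gene")
  expect_equal(unname(size_factors_median_ratio(same)), rep(1, 3))
  # doubled column -> factor 2 relative to the others
  m <- cbind(a = c(10, 20, 40), b = c(10, 20, 40), c = 2 * c(10, 20, 40))
  rownames(m) <- letters[1:3]
  fd <- size_factors_median_ratio(count_matrix(m, "gene"))
  expect_equal(unname(fd[3] / fd[1]), 2)
  zero <- count_matrix(rbind(x = c(0, 5), y = c(5, 0)), "gene")
  expect_error(size_factors_median_ratio(zero), "pseudocount")
})

test_that("vst transform is log2(count/factor + 1) and scale-invariant", {
  cm <- random_counts(30, 5, seed = 8)
  e <- vst_transform(cm, size_factors = rep(1, 5))
  expect_equal(e$values, log2(cm$counts + 1), ignore_attr = TRUE)
  expect_equal(e$state, "transformed")
  expect_equal(e$provenance$transform, "log2_median_ratio_plus1")
  zm <- matrix(c(0, 7, 3, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  ez <- vst_transform(count_matrix(zm, "gene"), size_factors = c(1, 1))
  expect_equal(unname(ez$values["a", 1]), 0)   # count 0, factor 1
  expect_equal(unname(ez$values["b", 1]), 3)   # count 7, factor 1 -> log2(8)
  # doubling all counts and factors leaves values unchanged
  f <- size_factors_median_ratio(cm)
  e1 <- vst_transform(cm, f)
  cm2 <- count_matrix(2 * cm$counts, "gene")
  e2 <- vst_transform(cm2, 2 * f)
  expect_equal(e1$values, e2$values)
})

test_that("residualization matches the hat-matrix oracle and is idempotent", {
  set.seed(10)
  n <- 40
  cov <- data.frame(lab = sample(c("a", "b"), n, replace = TRUE),
                    pc1 = rnorm(n), sex = sample(c("f", "m"), n, TRUE))
  vals <- matrix(rnorm(6 * n), 6, n,
                 dimnames = list(paste0("g", 1:6), paste0("S", 1:n)))
  e <- expression_matrix(vals, "gene", "transformed")
  r <- residualize_covariates(e, cov)
  # explicit hat-matrix computation
  X <- cbind(1, as.numeric(cov$lab == "b"), cov$pc1,
             as.numeric(cov$sex == "m"))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  for (i in 1:6) {
    y <- vals[i, ]
    expect_equal(unname(r$values[i, ]),
                 unname(as.vector((diag(n) - H) %*% y) + mean(y)),
                 tolerance = 1e-10)
  }
  # feature equal to a covariate -> constant at its mean
  vals2 <- rbind(g1 = cov$pc1, g2 = rnorm(n))
  colnames(vals2) <- paste0("S", 1:n)
  r2 <- residualize_covariates(expression_matrix(vals2, "gene", "transformed"),
                               cov)
  expect_equal(unname(r2$values["g1", ]), rep(mean(cov$pc1), n),
               tolerance = 1e-10)
  # re-residualization on the same covariates is identity
  r3 <- residualize_covariates(r, cov)
  expect_equal(r3$values, r$values, tolerance = 1e-10)
  # covariate orthogonal to a feature leaves it unchanged (plus mean shift 0)
  ortho <- rnorm(n)
  ortho <- residuals(lm(ortho ~ X - 1))
  vals3 <- rbind(g1 = ortho); colnames(vals3) <- paste0("S", 1:n)
  r4 <- residualize_covariates(expression_matrix(vals3, "gene", "transformed"),
                               cov)
  expect_equal(unname(r4$values[1, ]), unname(ortho + mean(ortho)),
               tolerance = 1e-10)
})

test_that("rank-deficient covariate designs are rejected with names", {
  cov <- data.frame(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  vals <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), NULL))
  e <- expression_matrix(vals, "gene", "transformed")
  expect_error(residualize_covariates(e, cov), "rank deficient")
})

test_that("inverse normal transform produces exact Blom scores", {
  vals <- rbind(f1 = c(10, 20, 30))
  colnames(vals) <- paste0("S", 1:3)
  e <- expression_matrix(vals, "gene", "residualized")
  out <- inverse_normal_transform(e)
  expect_equal(unname(out$values[1, ]),
               qnorm((1:3 - 0.375) / 3.25), tolerance = 1e-10)
  expect_equal(unname(out$values[1, 2]), 0)
  expect_equal(round(out$values[1, 3], 4), 0.8694, ignore_attr = TRUE)
  # rank invariance under strictly monotone rescaling
  set.seed(3)
  y <- rnorm(21)
  v1 <- rbind(f = y); v2 <- rbind(f = exp(3 * y) + 5)
  colnames(v1) <- colnames(v2) <- paste0("S", 1:21)
  o1 <- inverse_normal_transform(expression_matrix(v1, "gene", "residualized"))
  o2 <- inverse_normal_transform(expression_matrix(v2, "gene", "residualized"))
  expect_equal(o1$values, o2$values)
  # odd n: middle sample maps to zero; rows have mean 0 and shared scores
  expect_equal(unname(o1$values[1, which(rank(y) == 11)]), 0,
               tolerance = 1e-12)
  expect_lt(abs(mean(o1$values[1, ])), 1e-10)
  # constant row is an error
  vc <- rbind(f = rep(1, 5)); colnames(vc) <- paste0("S", 1:5)
  expect_error(inverse_normal_transform(
    expression_matrix(vc, "gene", "residualized")), "constant")
})

test_that("state transitions are enforced forward-only", {
  vals <- matrix(rnorm(20), 2, 10,
                 dimnames = list(c("a", "b"), paste0("S", 1:10)))
  e_int <- make_int_expr(vals)
  expect_error(inverse_normal_transform(e_int), "residualized")
  expect_error(residualize_covariates(e_int, data.frame(x = rnorm(10))),
               "transformed")
  # INT of transformed state requires the explicit flag
  et <- expression_matrix(vals, "gene", "transformed")
  expect_error(inverse_normal_transform(et), "residualized")
  expect_equal(inverse_normal_transform(et, allow_transformed = TRUE)$state,
               "inverse_normal")
})

test_that("hidden factors recover a planted rank-1 batch effect", {
  set.seed(6)
  n <- 60; nf <- 80
  loading <- rnorm(n)
  vals <- matrix(rnorm(nf * n, sd = 0.5), nf, n) +
    outer(rnorm(nf, sd = 1.5), loading)
  dimnames(vals) <- list(paste0("g", 1:nf), paste0("S", 1:n))
  e <- expression_matrix(vals, "gene", "residualized")
  hf <- estimate_hidden_factors(e, 3)
  expect_gt(abs(cor(hf$HF1, loading)), 0.9)
  # factors mutually orthogonal
  gram <- crossprod(as.matrix(hf))
  expect_lt(max(abs(gram[upper.tri(gram)])) / max(diag(gram)), 1e-8)
  # k = 0 is a no-op
  expect_equal(ncol(estimate_hidden_factors(e, 0)), 0)
})

test_that("preparation pipeline is deterministic and order-preserving", {
  cm <- random_counts(40, 12, seed = 13)
  cov <- data.frame(lab = rep(c("x", "y"), 6), pc1 = rnorm(12))
  prep <- function() {
    e <- vst_transform(cm)
    e <- residualize_covariates(e, cov)
    inverse_normal_transform(e)
  }
  a <- prep(); b <- prep()
  expect_identical(a$values, b$values)
  expect_identical(rownames(a$values), rownames(cm$counts))
  expect_identical(colnames(a$values), colnames(cm$counts))
})
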