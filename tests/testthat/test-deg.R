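test_that("pooled t-test matches a hand-computed oracle and handles ties", {
  # groups: case = (0,0,1,1), control = (2,2,3,3); pooled-variance t, df = 6
  g <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  y <- c(0, 0, 1, 1, 2, 2, 3, 3)
  Y <- rbind(y,
             rep(5, 8),                  # identical constant in both groups
             c(1, 2, 3, 1, 1, 2, 3, 1))  # same spread & mean in both groups
  expr <- make_expr(Y, gene_ids = c("a", "b", "c"))
  des <- make_design(g, ph = seq_len(8))
  res <- deg_ttest(expr, des)

  # oracle: long-form pooled-t arithmetic
  sp2 <- (sum((y[1:4] - 0.5)^2) + sum((y[5:8] - 2.5)^2)) / 6
  t_or <- (0.5 - 2.5) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$statistic[1], t_or)
  expect_equal(res$pvalue[1], 2 * pt(-abs(t_or), 6))

  # no difference: t = 0, p = 1 (constant gene and symmetric gene alike)
  expect_identical(res$statistic[2], 0)
  expect_identical(res$pvalue[2], 1)
  expect_identical(res$statistic[3], 0)
  expect_identical(res$pvalue[3], 1)
})

test_that("t and d are antisymmetric under group-label swap, p unchanged", {
  set.seed(42)
  for (rep in 1:5) {
    ds <- rand_dataset(n_genes = 6L)
    flipped <- make_design(1L - ds$design$group, ds$design$phenotype)
    t1 <- deg_ttest(ds$expr, ds$design)
    t2 <- deg_ttest(ds$expr, flipped)
    expect_equal(t2$statistic, -t1$statistic)
    expect_equal(t2$pvalue, t1$pvalue)
    d1 <- sam_statistic(ds$expr, ds$design, s0 = 0.3)
    d2 <- sam_statistic(ds$expr, flipped, s0 = 0.3)
    expect_equal(d2, -d1)
  }
})

test_that("SAM statistic reduces to t at s0 = 0 and matches direct arithmetic", {
  g <- c(1L, 1L, 1L, 0L, 0L, 0L)
  Y <- rbind(c(4, 5, 6, 1, 2, 3),
             c(2, 2, 2, 2, 2, 2))
  expr <- make_expr(Y)
  des <- make_design(g, ph = 1:6)

  d0 <- sam_statistic(expr, des, s0 = 0)
  expect_equal(unname(d0), deg_ttest(expr, des)$statistic,
               tolerance = 1e-12)
  expect_identical(unname(d0[2]), 0)   # equal group means -> d = 0 for any s0
  expect_identical(unname(sam_statistic(expr, des, s0 = 1)[2]), 0)

  # one-line formula oracle for gene 1, s0 = 1
  s_i <- sqrt(((sum((c(4, 5, 6) - 5)^2) + sum((c(1, 2, 3) - 2)^2)) / 4) *
                (1 / 3 + 1 / 3))
  expect_equal(unname(sam_statistic(expr, des, s0 = 1)[1]),
               (5 - 2) / (s_i + 1))
  expect_error(sam_statistic(expr, des, s0 = -0.1), ">= 0")
})

test_that("fudge-factor selection minimises the binned-dispersion CV", {
  set.seed(7)
  # mixture: many quiet genes plus strong low-variance shifts, which make
  # the raw d unstable at small s_i and force a positive fudge factor
  n <- 20L
  g <- rep(c(0L, 1L), each = 10L)
  Y <- matrix(rnorm(200 * n, 0, 2), 200, n)
  Y[1:60, ] <- matrix(rnorm(60 * n, 0, 0.05), 60, n) +
    outer(runif(60, 0.5, 1), g)
  expr <- make_expr(Y)
  des <- make_design(g, ph = rnorm(n))
  s0 <- choose_fudge_factor(expr, des)
  expect_gt(s0, 0)

  # brute-force scan oracle over the 21 candidate percentiles
  gs <- degpag:::.group_stats(unclass(expr), g)
  s <- gs$s; num <- gs$m1 - gs$m0
  cands <- quantile(s, seq(0, 1, 0.05), names = FALSE)
  breaks <- unique(quantile(s, seq(0, 1, length.out = 21), names = FALSE))
  bin <- cut(s, breaks, include.lowest = TRUE)
  cv <- sapply(cands, function(cand) {
    v <- tapply(abs(num / (s + cand)), bin, median)
    sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)
  })
  expect_equal(s0, cands[which.min(cv)])

  # scale equivariance: doubling the data doubles the chosen s0
  expr2 <- make_expr(2 * Y)
  expect_equal(choose_fudge_factor(expr2, des), 2 * s0, tolerance = 1e-12)
})

test_that("identical gene-wise standard errors short-circuit with a warning", {
  g <- rep(c(0L, 1L), each = 3L)
  base <- c(-1, 0, 1, -1, 0, 1)
  Y <- t(replicate(12, base)) + seq_len(12)   # same spread, shifted means
  expr <- make_expr(Y)
  des <- make_design(g, ph = rnorm(6))
  expect_warning(s0 <- choose_fudge_factor(expr, des), "identical")
  expect_equal(s0, degpag:::.group_stats(unclass(expr), g)$s[[1]])
})

test_that("permutation engine enumerates all assignments for small designs", {
  set.seed(3)
  ds <- rand_dataset(n_genes = 30L, n1 = 3L, n0 = 3L, gamma1 = 2)
  fit <- sam(ds$expr, ds$design, s0 = 0.2, n_perm = 1000L, seed = 9L)
  expect_true(fit$enumerated)
  expect_identical(ncol(fit$permutations), 20L)   # C(6,3) = 20
  expect_identical(ncol(unique(fit$permutations, MARGIN = 2)), 20L)
})

test_that("SAM calling behaves at the delta extremes and FDR is monotone", {
  set.seed(5)
  ds <- rand_dataset(n_genes = 50L, n1 = 4L, n0 = 4L, gamma1 = 3)
  fit <- sam(ds$expr, ds$design, s0 = 0.2,
             delta = c(0, 0.5, 1, 2, 1e6), n_perm = 200L, seed = 2L)
  tab <- fit$delta_table
  # sentinel above any displacement: nothing called, FDR 0
  expect_identical(tab$n_called[tab$delta == 1e6], 0L)
  expect_identical(tab$fdr[tab$delta == 1e6], 0)
  # delta = 0: every gene displaced by a continuous amount is called
  expect_identical(tab$n_called[tab$delta == 0], 50L)
  # median FDR non-increasing in delta
  expect_true(all(diff(tab$fdr) <= 1e-12))
  expect_error(sam(ds$expr, ds$design, s0 = 0.2, delta = numeric(0)),
               "non-empty")
})

test_that("pooled permutation p-values are valid and signal-sensitive", {
  set.seed(8)
  ds <- rand_dataset(n_genes = 40L, n1 = 4L, n0 = 4L)
  Y <- ds$Y
  Y[1:4, ] <- Y[1:4, ] + outer(rep(8, 4), ds$g)   # strong shifts
  expr <- make_expr(Y)
  fit <- sam(expr, ds$design, s0 = 0.2, n_perm = 70L, seed = 4L)
  p <- sam_pvalues(fit)
  expect_true(all(p > 0 & p <= 1))
  expect_lt(max(p[1:4]), 0.05)          # shifted genes are called
  expect_gt(median(p[-(1:4)]), 0.2)     # null genes mostly are not
})
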