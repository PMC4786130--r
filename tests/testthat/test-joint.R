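test_that("joint LRT matches the closed-form least-squares oracle", {
  g <- c(0L, 0L, 0L, 1L, 1L, 1L)
  ph <- c(1, 2, 3, 2, 3, 4)
  y <- c(1.0, 2.1, 2.9, 3.2, 3.9, 5.1)
  fit <- joint_lrt(make_expr(rbind(y), gene_ids = "gA"), make_design(g, ph))
  n <- 6
  rss_full <- rss_oracle(y, cbind(1, g, ph))
  rss_1 <- rss_oracle(y, cbind(1, ph))   # gamma1 = 0
  rss_2 <- rss_oracle(y, cbind(1, g))    # gamma2 = 0
  expect_equal(fit$results$lrt_gamma1, n * log(rss_1 / rss_full))
  expect_equal(fit$results$lrt_gamma2, n * log(rss_2 / rss_full))
  expect_identical(fit$results$lambda,
                   min(fit$results$lrt_gamma1, fit$results$lrt_gamma2))
  expect_equal(fit$results$pvalue,
               pchisq(fit$results$lambda, 1, lower.tail = FALSE))
})

test_that("lambda is the exact min of the component LRTs on random data", {
  set.seed(101)
  for (rep in 1:20) {
    ds <- rand_dataset(n_genes = 10L, n1 = 4L, n0 = 4L,
                       gamma1 = runif(1, 0, 2), gamma2 = runif(1, 0, 0.5))
    fit <- joint_lrt(ds$expr, ds$design)
    expect_identical(fit$results$lambda,
                     pmin(fit$results$lrt_gamma1, fit$results$lrt_gamma2))
    # joint p is the max of the two component chi-square(1) p-values
    p1 <- pchisq(fit$results$lrt_gamma1, 1, lower.tail = FALSE)
    p2 <- pchisq(fit$results$lrt_gamma2, 1, lower.tail = FALSE)
    expect_equal(fit$results$pvalue, pmax(p1, p2))
  }
})

test_that("one-sided perfection does not reject the OR-null", {
  # expression identical to the phenotype, groups balanced in phenotype:
  # the phenotype reduction is infinitely worse, the group reduction is
  # not, so lambda stays near 0 and p near 1
  g <- rep(c(0L, 1L), each = 4L)
  ph <- c(1, 2, 3, 4, 1, 2, 3, 4)
  fit <- joint_lrt(make_expr(rbind(ph)), make_design(g, ph))
  expect_identical(fit$results$lrt_gamma2, Inf)
  expect_equal(fit$results$lrt_gamma1, 0)
  expect_equal(fit$results$pvalue, 1)
  expect_true(fit$results$degenerate)   # exact fit is flagged
})

test_that("degenerate genes are flagged, not fatal", {
  g <- rep(c(0L, 1L), each = 3L)
  ph <- c(5, 7, 9, 6, 8, 11)
  Y <- rbind(const = rep(2, 6),               # zero variance
             exact = 1 + 2 * g + 0.5 * ph,    # rss_full = 0, reductions not
             noisy = rnorm(6))
  fit <- joint_lrt(make_expr(Y, gene_ids = rownames(Y)), make_design(g, ph))
  expect_true(is.nan(fit$results$pvalue[1]))
  expect_true(fit$results$degenerate[1])
  expect_identical(fit$results$lambda[2], Inf)
  expect_identical(fit$results$pvalue[2], 0)
  expect_true(fit$results$degenerate[2])
  expect_false(fit$results$degenerate[3])
})

test_that("fit methods are mutually consistent", {
  set.seed(55)
  ds <- rand_dataset(n_genes = 8L, n1 = 6L, n0 = 6L, gamma1 = 1,
                     gamma2 = 0.3)
  fit <- joint_lrt(ds$expr, ds$design)
  # coefficients match per-gene lm fits
  cf <- coef(fit)
  for (i in c(1L, 5L)) {
    lmfit <- lm(ds$Y[i, ] ~ ds$g + ds$ph)
    expect_equal(unname(cf[i, ]), unname(coef(lmfit)), tolerance = 1e-9)
  }
  # fitted + residuals reconstruct the data; rss agrees
  expect_equal(predict(fit) + residuals(fit), unclass(ds$expr),
               ignore_attr = TRUE)
  expect_equal(rowSums(residuals(fit)^2), unname(fit$rss[, "full"]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # simulate: reproducible with a seed, right shape
  s1 <- simulate(fit, nsim = 2L, seed = 77L)
  s2 <- simulate(fit, nsim = 2L, seed = 77L)
  expect_identical(s1, s2)
  expect_identical(dim(s1[[1]]), dim(ds$expr))
  # print/summary/plot run quietly
  expect_output(print(fit), "intersection-union")
  expect_output(print(summary(fit)), "top genes")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("naive intersection behaves as a set operation", {
  mk <- function(ids, sig) gene_tests(ids, "x", 1, ifelse(sig, 0.01, 0.5))
  ids <- paste0("g", 1:5)
  expect_identical(
    naive_joint(mk(ids, c(TRUE, TRUE, TRUE, FALSE, FALSE)),
                mk(ids, c(FALSE, TRUE, TRUE, TRUE, FALSE))),
    c("g2", "g3"))
  # disjoint significant sets
  expect_identical(
    naive_joint(mk(ids, c(TRUE, FALSE, FALSE, FALSE, FALSE)),
                mk(ids, c(FALSE, TRUE, FALSE, FALSE, FALSE))),
    character(0))
  # idempotence on identical lists
  one <- mk(ids, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(naive_joint(one, one), c("g1", "g3", "g5"))
  expect_error(naive_joint(one, mk(paste0("h", 1:5), rep(TRUE, 5))),
               "different gene universes")
})

test_that("hierarchical screening degenerates correctly at the extremes", {
  set.seed(66)
  ds <- rand_dataset(n_genes = 40L, n1 = 6L, n0 = 6L, gamma1 = 1.5,
                     gamma2 = 0.3)
  # alpha = 1 at both stages: equals the stage-2 test on all genes
  all_m1 <- hierarchical_joint(ds$expr, ds$design, "ttest", "m1",
                               alpha = 1, order = "deg_first")
  expect_setequal(all_m1, ds$expr |> rownames())
  # alpha ~ 0 at stage 1: empty result, not an error
  expect_identical(
    hierarchical_joint(ds$expr, ds$design, "ttest", "m1", alpha = 1e-12),
    character(0))
})

test_that("naive and hierarchical coincide under raw p-value thresholds", {
  set.seed(77)
  for (rep in 1:10) {
    ds <- rand_dataset(n_genes = 60L, n1 = 5L, n0 = 5L,
                       gamma1 = runif(1, 0, 2), gamma2 = runif(1, 0, 0.3))
    for (pm in c("m1", "m2")) {
      nv <- naive_joint(deg_ttest(ds$expr, ds$design),
                        pag_test(ds$expr, ds$design, pm), alpha = 0.05)
      hr <- hierarchical_joint(ds$expr, ds$design, "ttest", pm,
                               alpha = 0.05, order = "deg_first")
      expect_setequal(nv, hr)
    }
  }
})

test_that("q-value thresholding can separate naive from hierarchical", {
  # recomputing BH within the stage-1 survivors makes the hierarchical
  # screen less stringent there, so the two strategies may differ
  set.seed(88)
  ds <- rand_dataset(n_genes = 200L, n1 = 8L, n0 = 8L)
  Y <- ds$Y
  Y[1:20, ] <- Y[1:20, ] + outer(rep(2, 20), ds$g) +
    outer(runif(20, 0.15, 0.3), ds$ph)
  expr <- make_expr(Y)
  nv <- naive_joint(deg_ttest(expr, ds$design),
                    pag_test(expr, ds$design, "m1"), alpha = 0.2,
                    use_q = TRUE)
  hr <- hierarchical_joint(expr, ds$design, "ttest", "m1", alpha = 0.2,
                           use_q = TRUE, order = "deg_first")
  expect_gte(length(hr), length(nv))
})
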