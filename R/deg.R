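# Differential-expression screens: pooled two-sample t-test and the SAM
# fudge-factor statistic with permutation-based FDR.

# Shared group summaries.  Returns per-gene means, pooled SD and the
# pooled standard error of the mean difference (Tusher-style s_i).
.group_stats <- function(Y, g) {
  n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  Y1 <- Y[, g == 1L, drop = FALSE]
  Y0 <- Y[, g == 0L, drop = FALSE]
  m1 <- rowMeans(Y1); m0 <- rowMeans(Y0)
  ss <- rowSums((Y1 - m1)^2) + rowSums((Y0 - m0)^2)
  sp2 <- ss / (n1 + n0 - 2L)
  list(m1 = m1, m0 = m0, sp2 = sp2,
       s = sqrt(sp2 * (1 / n1 + 1 / n0)), n1 = n1, n0 = n0)
}

#' Per-gene two-sample t-test between the two groups
#'
#' Pooled-variance Student's t with `n1 + n0 - 2` degrees of freedom,
#' two-sided.  Genes with zero pooled variance get `t = 0, p = 1` when the
#' group means are also equal, and `statistic = +/-Inf, p = NaN`
#' otherwise (perfect separation, flagged degenerate).
#'
#' @param expr an [expression_matrix()].
#' @param design a [study_design()] aligned with `expr`.
#' @param report_q add Benjamini-Hochberg q-values over all finite
#'   p-values (default `TRUE`).
#' @return a `gene_tests` data frame (gene_id, method, statistic, pvalue,
#'   qvalue), rows in input gene order.
#' @export
deg_ttest <- function(expr, design, report_q = TRUE) {
  check_aligned(expr, design)
  g <- design$group
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  Y <- unclass(as.matrix(expr))
  gs <- .group_stats(Y, g)
  diff <- gs$m1 - gs$m0
  df <- gs$n1 + gs$n0 - 2L
  t <- diff / gs$s
  p <- 2 * stats::pt(-abs(t), df)
  deg0 <- gs$s == 0
  t[deg0 & diff == 0] <- 0
  p[deg0 & diff == 0] <- 1
  t[deg0 & diff != 0] <- sign(diff[deg0 & diff != 0]) * Inf
  p[deg0 & diff != 0] <- NaN
  q <- if (report_q) bh_qvalues(p) else NA_real_
  gene_tests(rownames(Y), "ttest", t, p, q)
}

#' SAM fudge-factor statistic
#'
#' `d_i = (mean(case) - mean(control)) / (s_i + s0)` where `s_i` is the
#' pooled two-sample standard error of the mean difference and `s0 >= 0`
#' the fudge factor stabilising low-variance genes.
#'
#' @inheritParams deg_ttest
#' @param s0 fudge factor, a single value `>= 0`.
#' @return named numeric vector of per-gene d values.
#' @export
sam_statistic <- function(expr, design, s0) {
  check_aligned(expr, design)
  if (length(s0) != 1L || is.na(s0) || s0 < 0)
    stop("s0 must be a single value >= 0")
  g <- design$group
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  Y <- unclass(as.matrix(expr))
  gs <- .group_stats(Y, g)
  num <- gs$m1 - gs$m0
  d <- num / (gs$s + s0)
  d[num == 0] <- 0      # equal group means: d = 0 for any s0 (even 0/0)
  names(d) <- rownames(Y)
  d
}

#' Choose the SAM fudge factor
#'
#' Searches the percentiles `{0, 5, ..., 100}` of the gene-wise standard
#' errors `s_i` and returns the candidate minimising the coefficient of
#' variation of the median absolute d statistic across quantile bins of
#' `s_i` (the variance-stabilisation criterion of the original SAM
#' procedure).  Deterministic given the input.
#'
#' @inheritParams deg_ttest
#' @param alphas percentile levels searched (default `seq(0, 1, 0.05)`).
#' @return the chosen `s0` (single numeric).
#' @export
choose_fudge_factor <- function(expr, design, alphas = seq(0, 1, by = 0.05)) {
  check_aligned(expr, design)
  Y <- unclass(as.matrix(expr))
  if (nrow(Y) < 10L)
    stop("fudge-factor selection needs at least 10 genes")
  g <- design$group
  gs <- .group_stats(Y, g)
  s <- gs$s
  num <- gs$m1 - gs$m0
  if (max(s) == min(s)) {
    warning("all gene-wise standard errors identical; returning the common value")
    return(s[[1L]])
  }
  cands <- stats::quantile(s, alphas, names = FALSE, type = 7)
  n_bins <- max(2L, min(100L, floor(nrow(Y) / 10)))
  breaks <- unique(stats::quantile(s, seq(0, 1, length.out = n_bins + 1L),
                                   names = FALSE))
  bin <- cut(s, breaks, include.lowest = TRUE)
  cv <- vapply(cands, function(s0) {
    v <- tapply(abs(num / (s + s0)), bin, stats::median)
    v <- v[!is.na(v)]
    if (mean(v) == 0) return(if (stats::sd(v) == 0) 0 else Inf)
    stats::sd(v) / mean(v)
  }, numeric(1L))
  cands[[which.min(cv)]]   # which.min takes the first (smallest s0) on ties
}

# All distinct assignments of n1 samples to the case group (columns of a
# logical n x B matrix), enumerated exhaustively when their number is at
# most n_perm, otherwise sampled with the given seed.
.sam_permutations <- function(n, n1, n_perm, seed) {
  total <- choose(n, n1)
  if (total <= n_perm) {
    idx <- utils::combn(n, n1)
    enumerated <- TRUE
  } else {
    set.seed(seed)
    idx <- replicate(n_perm, sample.int(n, n1))
    enumerated <- FALSE
  }
  list(idx = idx, enumerated = enumerated)
}

#' SAM analysis with permutation-based FDR
#'
#' Computes the observed d statistics, the permutation-expected order
#' statistics `d_expected` (mean over permutations of the sorted permuted
#' d values), and, for each calling threshold `delta`, calls the genes
#' whose sorted displacement `|d_(i) - d_expected_(i)|` exceeds `delta`.
#' The reported FDR is the median over permutations of the number of
#' permuted genes beyond the same threshold, divided by the observed call
#' count and capped at 1.  Group-label assignments are enumerated
#' exhaustively whenever their number does not exceed `n_perm`.
#'
#' @inheritParams deg_ttest
#' @param s0 fudge factor; `NULL` (default) selects it with
#'   [choose_fudge_factor()].
#' @param delta numeric vector of calling thresholds (`>= 0`); `NULL` for
#'   an automatic grid over the observed displacement range.
#' @param n_perm maximum number of permutations (`>= 1`).
#' @param seed RNG seed used only when permutations are sampled.
#' @return an object of class `"sam_fit"`: observed `d`, `s`, `s0`,
#'   `d_expected` (aligned to `order(d)`), a `delta_table`
#'   (delta, n_called, median_perm_called, fdr), a logical `called`
#'   matrix (genes x deltas), and the permutation assignments used.
#' @export
sam <- function(expr, design, s0 = NULL, delta = NULL, n_perm = 1000L,
                seed = 1L) {
  check_aligned(expr, design)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  g <- design$group
  Y <- unclass(as.matrix(expr))
  if (is.null(s0)) s0 <- choose_fudge_factor(expr, design)
  d <- sam_statistic(expr, design, s0)
  n <- length(g); n1 <- sum(g == 1L)
  perms <- .sam_permutations(n, n1, n_perm, seed)
  B <- ncol(perms$idx)
  D_sorted <- matrix(0, nrow(Y), B)
  for (b in seq_len(B)) {
    gb <- integer(n); gb[perms$idx[, b]] <- 1L
    gsb <- .group_stats(Y, gb)
    D_sorted[, b] <- sort((gsb$m1 - gsb$m0) / (gsb$s + s0))
  }
  d_expected <- rowMeans(D_sorted)
  ord <- order(d)
  disp <- d[ord] - d_expected
  if (is.null(delta))
    delta <- seq(0, max(abs(disp)) * 1.01, length.out = 11L)
  if (length(delta) == 0L) stop("delta grid must be non-empty")
  if (any(delta < 0)) stop("delta thresholds must be >= 0")

  called <- matrix(FALSE, nrow(Y), length(delta),
                   dimnames = list(rownames(Y), signif(delta, 4L)))
  n_called <- integer(length(delta))
  med_perm <- numeric(length(delta))
  fdr <- numeric(length(delta))
  perm_disp <- abs(D_sorted - d_expected)   # recycled column-wise
  for (k in seq_along(delta)) {
    hit_sorted <- abs(disp) > delta[k]
    called[ord[hit_sorted], k] <- TRUE
    n_called[k] <- sum(hit_sorted)
    med_perm[k] <- stats::median(colSums(perm_disp > delta[k]))
    fdr[k] <- if (n_called[k] == 0L) 0 else min(1, med_perm[k] / n_called[k])
  }
  structure(list(d = d, s = .group_stats(Y, g)$s, s0 = s0,
                 d_expected = d_expected, order = ord,
                 perm_d_sorted = D_sorted,
                 delta_table = data.frame(delta = delta, n_called = n_called,
                                          median_perm_called = med_perm,
                                          fdr = fdr),
                 called = called,
                 permutations = perms$idx, enumerated = perms$enumerated,
                 call = match.call()),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("SAM analysis: ", length(x$d), " genes, s0 = ", signif(x$s0, 4L),
      ", ", ncol(x$permutations), " permutation",
      if (ncol(x$permutations) > 1L) "s",
      if (x$enumerated) " (exhaustive)", "\n", sep = "")
  print(x$delta_table, row.names = FALSE)
  invisible(x)
}

#' Pooled permutation p-values for the SAM statistic
#'
#' `p_i = (1 + #\{|d*| >= |d_i|\}) / (1 + N)` where the pool of permuted
#' `|d*|` values is taken across all genes and all permutations of a
#' [sam()] fit.  This puts the SAM screen on a p-value scale, as needed
#' by [hierarchical_joint()] with `deg_method = "sam"`.
#'
#' @param fit a `"sam_fit"` object from [sam()].
#' @return named numeric vector of per-gene permutation p-values.
#' @export
sam_pvalues <- function(fit) {
  pool <- sort(abs(as.vector(fit$perm_d_sorted)))
  N <- length(pool)
  # count of pool values >= |d_i| via binary search on the sorted pool
  ge <- N - findInterval(abs(fit$d) - 1e-12, pool)
  p <- (1 + ge) / (1 + N)
  names(p) <- names(fit$d)
  p
}
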