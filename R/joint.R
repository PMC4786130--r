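# Joint identification of differentially expressed and
# phenotype-associated genes: the model-based intersection-union LRT and
# the two-stage comparator strategies.

#' Model-based joint test for group and phenotype effects
#'
#' Fits, per gene, the Gaussian linear model
#' `expression = gamma0 + gamma1*group + gamma2*phenotype + error`
#' together with the two constrained fits (`gamma1 = 0`:
#' `expression ~ phenotype`; `gamma2 = 0`: `expression ~ group`).  Under
#' the profile Gaussian likelihood each component likelihood-ratio
#' statistic equals `n * log(rss_reduced / rss_full)`.  The composite
#' null "no group effect OR no phenotype effect" is rejected only when
#' both component tests do, so the intersection-union statistic is
#' `lambda = min(lrt_gamma1, lrt_gamma2)`, referred to the chi-square(1)
#' upper tail.  This is conservative near the origin of the
#' (gamma1, gamma2) plane and approaches the nominal level as either
#' effect grows.
#'
#' Degenerate genes (zero residual variance everywhere) get `NaN`
#' results; a perfect full-model fit with informative reductions gives
#' `lambda = Inf`, `p = 0`.  Both cases are flagged in the `degenerate`
#' column.
#'
#' @inheritParams deg_ttest
#' @return an object of class `"joint_lrt"` with components
#'   `results` (data frame: gene_id, lrt_gamma1, lrt_gamma2, lambda,
#'   pvalue, qvalue, degenerate), `coefficients` (genes x 3 matrix of
#'   gamma estimates), `rss` (genes x 3: full and the two reduced fits),
#'   `n`, `design`, `expr`, `call`.
#' @seealso [naive_joint()], [hierarchical_joint()] for the two-stage
#'   comparators.
#' @export
joint_lrt <- function(expr, design, report_q = TRUE) {
  check_aligned(expr, design)
  Y <- unclass(as.matrix(expr))
  g <- design$group
  ph <- design$phenotype
  n <- ncol(Y)
  if (n < 4L) stop("the joint model needs at least 4 samples")
  if (length(unique(g)) != 2L) stop("both groups must be present")
  if (max(ph) == min(ph)) stop("phenotype is constant")
  ph_w <- ph - stats::ave(ph, g)          # phenotype residualised on group
  if (sum(ph_w^2) == 0)
    stop("phenotype is collinear with group; the full model is singular")

  # Reduced fit gamma2 = 0: expression ~ group (within-group centring)
  Yg <- Y
  Yg[, g == 0L] <- Y[, g == 0L] - rowMeans(Y[, g == 0L, drop = FALSE])
  Yg[, g == 1L] <- Y[, g == 1L] - rowMeans(Y[, g == 1L, drop = FALSE])
  rss_g <- rowSums(Yg^2)
  # Full fit: add phenotype to the group model (Frisch-Waugh step)
  rss_full <- pmax(0, rss_g - as.vector(Yg %*% ph_w)^2 / sum(ph_w^2))
  # Reduced fit gamma1 = 0: expression ~ phenotype
  ph_c <- ph - mean(ph)
  Yc <- Y - rowMeans(Y)
  tss <- rowSums(Yc^2)
  rss_p <- pmax(0, tss - as.vector(Yc %*% ph_c)^2 / sum(ph_c^2))

  lrt1 <- n * log(rss_p / rss_full)   # tests gamma1 = 0 (group effect)
  lrt2 <- n * log(rss_g / rss_full)   # tests gamma2 = 0 (phenotype effect)
  # Perfect full-model fit (rss_full ~ 0 relative to the gene's total sum
  # of squares): a reduction that still fits perfectly adds nothing
  # (LRT 0); a reduction with real residual error is infinitely worse.
  tol <- tss * 1e-12
  perfect <- tss > 0 & rss_full <= tol
  lrt1[perfect] <- ifelse(rss_p[perfect] > tol[perfect], Inf, 0)
  lrt2[perfect] <- ifelse(rss_g[perfect] > tol[perfect], Inf, 0)
  # Zero-variance genes: every fit is exact, the test is undefined.
  lrt1[tss == 0] <- NaN
  lrt2[tss == 0] <- NaN
  lrt1 <- pmax(lrt1, 0)
  lrt2 <- pmax(lrt2, 0)
  lambda <- pmin(lrt1, lrt2)
  degenerate <- tss == 0 | perfect
  p <- stats::pchisq(lambda, df = 1L, lower.tail = FALSE)
  q <- if (report_q) bh_qvalues(p) else NA_real_

  X <- cbind(`(Intercept)` = 1, group = g, phenotype = ph)
  B <- Y %*% X %*% solve(crossprod(X))
  colnames(B) <- colnames(X)

  structure(list(
    results = data.frame(gene_id = rownames(Y), lrt_gamma1 = lrt1,
                         lrt_gamma2 = lrt2, lambda = lambda, pvalue = p,
                         qvalue = q, degenerate = degenerate | is.nan(lambda),
                         stringsAsFactors = FALSE),
    coefficients = B,
    rss = cbind(full = rss_full, gamma1_0 = rss_p, gamma2_0 = rss_g),
    n = n, design = design, expr = Y, call = match.call()),
    class = "joint_lrt")
}

#' @export
print.joint_lrt <- function(x, ...) {
  cat("Model-based joint DEG/PAG test (intersection-union LRT)\n")
  cat("  ", nrow(x$results), " genes, ", x$n, " samples (",
      sum(x$design$group == 0L), " control / ", sum(x$design$group == 1L),
      " case), phenotype '", attr(x$design, "phenotype_name"), "'\n", sep = "")
  p <- x$results$pvalue
  cat("  p < 0.05: ", sum(p < 0.05, na.rm = TRUE),
      "   q < 0.05: ", sum(x$results$qvalue < 0.05, na.rm = TRUE),
      "   degenerate: ", sum(x$results$degenerate), "\n", sep = "")
  invisible(x)
}

#' @export
summary.joint_lrt <- function(object, alpha = 0.05, n_top = 10L, ...) {
  res <- object$results
  ord <- order(res$pvalue)
  out <- list(
    n_genes = nrow(res), n_samples = object$n,
    phenotype = attr(object$design, "phenotype_name"),
    alpha = alpha,
    n_significant_p = sum(res$pvalue < alpha, na.rm = TRUE),
    n_significant_q = sum(res$qvalue < alpha, na.rm = TRUE),
    top = utils::head(res[ord, ], n_top))
  class(out) <- "summary.joint_lrt"
  out
}

#' @export
print.summary.joint_lrt <- function(x, ...) {
  cat("Joint DEG/PAG identification, phenotype '", x$phenotype, "'\n",
      sep = "")
  cat("  ", x$n_genes, " genes tested on ", x$n_samples, " samples\n",
      sep = "")
  cat("  significant at alpha = ", x$alpha, ": ", x$n_significant_p,
      " (p-value), ", x$n_significant_q, " (BH q-value)\n", sep = "")
  cat("  top genes:\n")
  print(x$top, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' @export
coef.joint_lrt <- function(object, ...) object$coefficients

#' @export
predict.joint_lrt <- function(object, design = object$design, ...) {
  X <- cbind(1, design$group, design$phenotype)
  out <- object$coefficients %*% t(X)
  colnames(out) <- design$sample_id
  out
}

#' @export
residuals.joint_lrt <- function(object, ...) {
  object$expr - predict(object)
}

#' @export
plot.joint_lrt <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  p <- x$results$pvalue
  graphics::hist(p[!is.na(p)], breaks = 20L, main = "Joint test p-values",
                 xlab = "p-value", col = "grey80", border = "white", ...)
  finite <- is.finite(x$results$lrt_gamma1) & is.finite(x$results$lrt_gamma2)
  graphics::plot(x$results$lrt_gamma1[finite], x$results$lrt_gamma2[finite],
                 xlab = expression(LRT ~ gamma[1]),
                 ylab = expression(LRT ~ gamma[2]),
                 main = "Component LRTs", pch = 16L,
                 col = grDevices::adjustcolor("steelblue", 0.5))
  crit <- stats::qchisq(0.95, 1L)
  graphics::abline(h = crit, v = crit, lty = 2L, col = "grey40")
  invisible(x)
}

#' Simulate expression matrices from a fitted joint model
#'
#' Draws new genes-by-samples matrices from the per-gene fitted Gaussian
#' linear model: fitted values plus normal noise with the gene's
#' unbiased residual standard deviation (`sqrt(rss_full / (n - 3))`).
#'
#' @param object a [joint_lrt()] fit.
#' @param nsim number of matrices to draw.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of `nsim` [expression_matrix()] objects.
#' @export
simulate.joint_lrt <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sd_g <- sqrt(object$rss[, "full"] / (object$n - 3L))
  lapply(seq_len(nsim), function(i) {
    noise <- matrix(stats::rnorm(length(mu), sd = sd_g), nrow(mu), ncol(mu))
    expression_matrix(mu + noise, rownames(mu), colnames(mu))
  })
}

.significant_ids <- function(results, alpha, use_q) {
  v <- if (use_q) results$qvalue else results$pvalue
  results$gene_id[!is.na(v) & v < alpha]
}

#' Naive joint identification
#'
#' Intersects the genes significant in a differential-expression result
#' table and in a phenotype-association result table, each thresholded at
#' `alpha` on p-values (or BH q-values with `use_q = TRUE`).
#'
#' @param deg_results,pag_results `gene_tests` tables over the same gene
#'   universe (e.g. from [deg_ttest()] and [pag_test()]).
#' @param alpha significance threshold.
#' @param use_q threshold q-values instead of p-values.
#' @return character vector of gene ids, in `deg_results` order.
#' @export
naive_joint <- function(deg_results, pag_results, alpha = 0.05,
                        use_q = FALSE) {
  if (!setequal(deg_results$gene_id, pag_results$gene_id) ||
      nrow(deg_results) != nrow(pag_results))
    stop("DEG and PAG result tables cover different gene universes")
  deg_sig <- .significant_ids(deg_results, alpha, use_q)
  pag_sig <- .significant_ids(pag_results, alpha, use_q)
  deg_results$gene_id[deg_results$gene_id %in% deg_sig &
                      deg_results$gene_id %in% pag_sig]
}

#' Hierarchical (two-stage) joint identification
#'
#' Stage 1 screens all genes with one test at level `alpha`; stage 2
#' re-tests only the stage-1 survivors with the other test.  With
#' `use_q = TRUE` the stage-2 q-values are recomputed within the survivor
#' subset, so the result can differ from [naive_joint()]; with raw
#' p-value thresholds the two strategies provably coincide (per-gene
#' p-values do not depend on which other genes are carried along).
#'
#' @inheritParams deg_ttest
#' @param deg_method `"ttest"` or `"sam"` (SAM uses pooled permutation
#'   p-values, see [sam_pvalues()]).
#' @param pag_model `"m1"` or `"m2"`.
#' @param alpha significance threshold applied at both stages.
#' @param use_q threshold BH q-values (stage 2 recomputed within the
#'   survivors) instead of raw p-values.
#' @param order `"deg_first"` (screen on differential expression, then
#'   association) or `"pag_first"`.
#' @param ... passed to [sam()] when `deg_method = "sam"`.
#' @return character vector of gene ids surviving both stages.
#' @export
hierarchical_joint <- function(expr, design, deg_method = c("ttest", "sam"),
                               pag_model = c("m1", "m2"), alpha = 0.05,
                               use_q = FALSE, order = c("deg_first",
                                                        "pag_first"), ...) {
  deg_method <- match.arg(deg_method)
  pag_model <- match.arg(pag_model)
  order <- match.arg(order)
  check_aligned(expr, design)

  deg_fun <- function(e) {
    if (deg_method == "ttest") return(deg_ttest(e, design))
    fit <- sam(e, design, ...)
    p <- sam_pvalues(fit)
    gene_tests(names(p), "sam", fit$d, p, bh_qvalues(p))
  }
  pag_fun <- function(e) pag_test(e, design, model = pag_model)

  stage <- if (order == "deg_first") list(deg_fun, pag_fun)
           else list(pag_fun, deg_fun)
  s1 <- .significant_ids(stage[[1L]](expr), alpha, use_q)
  if (length(s1) == 0L) return(character(0L))
  sub <- expression_matrix(unclass(as.matrix(expr))[s1, , drop = FALSE],
                           s1, colnames(expr))
  .significant_ids(stage[[2L]](sub), alpha, use_q)
}
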