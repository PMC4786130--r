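# Phenotype-association screens: per-gene regressions of the phenotype on
# expression (M1) and on expression plus group (M2), testing the
# expression slope by a partial F test.

#' Ordinary least squares with profile Gaussian log-likelihood
#'
#' Shared least-squares engine.  The caller supplies the full design
#' matrix (including any intercept column).
#'
#' @param response numeric vector.
#' @param covariates numeric design matrix, one row per observation.
#' @return an object of class `"ols_fit"`: `coefficients`, `rss`, `n`,
#'   `k` (number of columns), `loglik` (profile Gaussian log-likelihood,
#'   `+Inf` when `rss = 0`), and `fitted`.
#' @export
fit_ols <- function(response, covariates) {
  X <- as.matrix(covariates)
  y <- as.numeric(response)
  if (nrow(X) != length(y))
    stop("covariates must have one row per response value")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- qx$pivot[(qx$rank + 1L):ncol(X)]
    nm <- colnames(X)
    nm <- if (is.null(nm)) paste0("column ", dropped) else nm[dropped]
    stop("singular design: ", paste(nm, collapse = ", "),
         " collinear with the preceding columns")
  }
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  n <- length(y)
  exact <- rss <= 1e-12 * max(1, sum(y^2))   # numerically perfect fit
  loglik <- if (exact) Inf else -(n / 2) * (log(2 * pi * rss / n) + 1)
  structure(list(coefficients = beta, rss = rss, n = n, k = ncol(X),
                 loglik = loglik, fitted = y - res),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit: n = ", x$n, ", k = ", x$k, ", rss = ", signif(x$rss, 6L),
      ", logLik = ", signif(x$loglik, 6L), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

# Per-gene correlation of the rows of Y with x, after both have been
# residualised on the same projection; returns r and the usable flag.
.row_cor <- function(Yr, xr) {
  sxx <- sum(xr^2)
  syy <- rowSums(Yr^2)
  num <- as.vector(Yr %*% xr)
  r <- num / sqrt(syy * sxx)
  r[syy == 0] <- NaN
  r
}

#' Per-gene phenotype-association test (models M1 and M2)
#'
#' M1 regresses the phenotype on each gene's expression
#' (`phenotype ~ expression`); M2 adds the group covariate
#' (`phenotype ~ expression + group`).  The expression slope is tested by
#' the partial F statistic (the squared slope t), with `(1, n-2)` df for
#' M1 and `(1, n-3)` for M2.  Genes whose (for M2: within-group)
#' expression is constant are collinear with the remaining columns and
#' get `NaN` statistics and p-values; a perfect fit gives `F = Inf`,
#' `p = 0`.
#'
#' @inheritParams deg_ttest
#' @param model `"m1"` or `"m2"`.
#' @return a `gene_tests` data frame with the F statistic per gene.
#' @export
pag_test <- function(expr, design, model = c("m1", "m2"), report_q = TRUE) {
  model <- match.arg(model)
  check_aligned(expr, design)
  Y <- unclass(as.matrix(expr))
  ph <- design$phenotype
  g <- design$group
  n <- ncol(Y)
  if (model == "m1") {
    if (n < 3L) stop("M1 needs at least 3 samples")
    xr <- ph - mean(ph)
    Yr <- Y - rowMeans(Y)
    df2 <- n - 2L
  } else {
    if (n < 4L) stop("M2 needs at least 4 samples")
    if (length(unique(g)) != 2L) stop("both groups must be present")
    xr <- ph - stats::ave(ph, g)
    Yr <- Y
    Yr[, g == 0L] <- Y[, g == 0L] - rowMeans(Y[, g == 0L, drop = FALSE])
    Yr[, g == 1L] <- Y[, g == 1L] - rowMeans(Y[, g == 1L, drop = FALSE])
    df2 <- n - 3L
  }
  if (sum(xr^2) == 0)
    stop("phenotype is constant",
         if (model == "m2") " within groups" else "",
         "; the slope test is undefined")
  # By Frisch-Waugh, the partial F for the expression slope equals the
  # F of the simple regression between the residualised variables
  # (roles are symmetric for a single tested column).
  r <- .row_cor(Yr, xr)
  Fstat <- df2 * r^2 / (1 - r^2)
  p <- stats::pf(Fstat, 1L, df2, lower.tail = FALSE)
  exact <- !is.na(r) & abs(1 - r^2) < .Machine$double.eps * 100
  Fstat[exact] <- Inf
  p[exact] <- 0
  q <- if (report_q) bh_qvalues(p) else NA_real_
  gene_tests(rownames(Y), model, Fstat, p, q)
}
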