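#' Bonferroni-adjusted p-values
#'
#' `adjusted_i = min(1, m * p_i)` with `m` the number of non-missing
#' tests; `NaN`/`NA` entries (degenerate genes) are excluded from `m` and
#' propagate unchanged.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA/NaN allowed).
#' @return adjusted vector of the same length and order.
#' @export
bonferroni_adjust <- function(p) {
  .check_pvec(p)
  ok <- !is.na(p)
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "bonferroni")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values: sort ascending, `q_(i) = min_{j >= i}
#' (m * p_(j) / j)` capped at 1, original order restored.  `NaN`/`NA`
#' entries are excluded from the ranking and returned unchanged.
#'
#' @inheritParams bonferroni_adjust
#' @return q-value vector of the same length and order.
#' @export
bh_qvalues <- function(p) {
  .check_pvec(p)
  ok <- !is.na(p)
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

.check_pvec <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  invisible(TRUE)
}
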