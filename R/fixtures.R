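# On-disk fixture generation for tests, tutorials and the command line.

#' Write a small synthetic expression/design dataset with a known signal
#'
#' Generates a genes-by-samples dataset from the package's generative
#' model and writes it as a pair of tab-delimited files (expression
#' matrix + design).  One tenth of the genes (at least one) carry the
#' named signal; the rest are null:
#'
#' * `"null"` — all genes from the global null (`gamma1 = gamma2 = 0`).
#' * `"deg_only"` — planted genes have a strong group effect only.
#' * `"pag_only"` — planted genes have a strong phenotype slope only.
#' * `"joint"` — planted genes have both effects.
#' * `"v1rh4_pattern"` — planted genes show the crossing geometry in
#'   which the within-group phenotype association is strong but the
#'   group offsets cancel the marginal correlation, so the
#'   unadjusted regression (M1) misses and the group-adjusted one (M2)
#'   hits.  For this kind the phenotype is generated group-dependent
#'   (the cancellation needs a group shift in the phenotype).
#'
#' @param kind signal structure, see above.
#' @param n_genes number of genes (`>= 1`).
#' @param seed RNG seed.
#' @param dir output directory (created if missing).
#' @param n_case,n_control samples per group.
#' @return list with elements `expression` and `design` (file paths) and
#'   `planted` (character vector of planted gene ids).
#' @export
make_fixture <- function(kind = c("null", "deg_only", "pag_only", "joint",
                                  "v1rh4_pattern"),
                         n_genes = 100L, seed = 1L, dir = tempdir(),
                         n_case = 25L, n_control = 25L) {
  kind <- match.arg(kind)
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(as.integer(seed))
  n <- n_case + n_control
  g <- c(rep(0L, n_control), rep(1L, n_case))
  sample_ids <- sprintf("s%02d", seq_len(n))
  gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
  n_planted <- if (kind == "null") 0L else max(1L, round(n_genes / 10))
  planted <- utils::head(gene_ids, n_planted)

  noise_sd <- sqrt(78.3)
  if (kind == "v1rh4_pattern") {
    # Within-group phenotype driver u; phenotype gets a group shift delta,
    # expression follows u but with a group offset tuned so that
    # cov(phenotype, expression) = 0 marginally.
    delta <- 30; sd_u <- 5
    u <- stats::rnorm(n, 0, sd_u)
    ph <- 25.06 + delta * g + u
    # cov(ph, y) = sd_u^2 + c * delta * var(g) = 0  =>  c = -sd_u^2/(delta*var(g))
    cc <- -sd_u^2 / (delta * stats::var(g))
    Y <- matrix(stats::rnorm(n_genes * n, 0, 1), n_genes, n)
    for (gi in seq_len(n_planted))
      Y[gi, ] <- u + cc * g + stats::rnorm(n, 0, 1)
    Y <- Y + 5
  } else {
    ph <- stats::rnorm(n, 25.06, sqrt(274.896))
    g1 <- switch(kind, deg_only = 15, joint = 15, 0)
    g2 <- switch(kind, pag_only = 1.5, joint = 1.5, 0)
    Y <- matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n)
    Y <- Y + 5
    for (gi in seq_len(n_planted))
      Y[gi, ] <- Y[gi, ] + g1 * g + g2 * ph
  }

  expr <- expression_matrix(Y, gene_ids, sample_ids)
  expr_path <- file.path(dir, sprintf("fixture_%s_expression.tsv", kind))
  design_path <- file.path(dir, sprintf("fixture_%s_design.tsv", kind))
  write_expression(expr, expr_path)
  utils::write.table(
    data.frame(sample_id = sample_ids,
               group = ifelse(g == 1L, "HFD", "ND"),
               phenotype = ph, stringsAsFactors = FALSE),
    design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expression = expr_path, design = design_path, planted = planted)
}
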