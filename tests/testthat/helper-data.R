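# Shared builders and independent oracles for the test suite.

# Quick expression/design pair with given values.
make_expr <- function(Y, gene_ids = sprintf("g%d", seq_len(nrow(Y))),
                      sample_ids = sprintf("s%d", seq_len(ncol(Y)))) {
  expression_matrix(Y, gene_ids, sample_ids)
}

make_design <- function(g, ph, ids = sprintf("s%d", seq_along(g)),
                        phenotype_name = "phenotype") {
  study_design(ids, g, ph, phenotype_name = phenotype_name)
}

# Random small dataset (both groups, non-constant phenotype).
rand_dataset <- function(n_genes = 5L, n1 = 4L, n0 = 4L,
                         gamma1 = 0, gamma2 = 0, noise_sd = 1) {
  n <- n1 + n0
  g <- c(rep(0L, n0), rep(1L, n1))
  ph <- rnorm(n, 25, 5)
  Y <- matrix(rnorm(n_genes * n, 0, noise_sd), n_genes, n)
  Y <- Y + outer(rep(gamma1, n_genes), g) + outer(rep(gamma2, n_genes), ph)
  list(expr = make_expr(Y), design = make_design(g, ph), g = g, ph = ph,
       Y = Y)
}

# Independent least-squares residual-sum-of-squares oracle: explicit
# normal equations, no qr, no lm.
rss_oracle <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sum((y - X %*% beta)^2)
}

# Brute-force step-up BH oracle.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    q[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  q
}
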