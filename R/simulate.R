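# Generative model and the type-I-error / power study engine.
#
# Expression for one simulated gene follows
#   expression = gamma0 + gamma1*group + gamma2*phenotype + eps,
# with phenotype i.i.d. normal (defaults: the adiponectin moments,
# mean 25.06, variance 274.896), eps i.i.d. N(0, noise_var = 78.3), and
# a balanced two-group design of 25 cases and 25 controls.

#' Simulation configuration
#'
#' Defaults are the study conditions of the built-in generative model:
#' balanced 25 case / 25 control design, phenotype drawn
#' `N(25.06, 274.896)` (serum-adiponectin moments, assay units),
#' expression noise variance 78.3 (log-intensity units), 1000 replicates,
#' nominal level 0.05.  `gamma0` cancels from every test statistic (all
#' are location-invariant in expression) and defaults to 0.
#'
#' @param n_case,n_control samples per group (each `>= 2`).
#' @param pheno_mean,pheno_var phenotype distribution moments
#'   (`pheno_var > 0`).
#' @param gamma0 baseline expression.
#' @param gamma1 group effect (expression units).
#' @param gamma2 phenotype slope (expression units per phenotype unit).
#' @param noise_var expression noise variance (`> 0`).
#' @param n_reps Monte-Carlo replicates per grid cell.
#' @param seed base RNG seed (non-negative integer `< 2^31`).
#' @param alpha nominal significance level, in (0, 1).
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_case = 25L, n_control = 25L, pheno_mean = 25.06,
                       pheno_var = 274.896, gamma0 = 0, gamma1 = 0,
                       gamma2 = 0, noise_var = 78.3, n_reps = 1000L,
                       seed = 1L, alpha = 0.05) {
  if (n_case < 2L || n_control < 2L) stop("each group needs >= 2 samples")
  if (pheno_var <= 0 || noise_var <= 0) stop("variances must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (seed < 0 || seed >= 2^31) stop("seed must be a non-negative 32-bit integer")
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 pheno_mean = pheno_mean, pheno_var = pheno_var,
                 gamma0 = gamma0, gamma1 = gamma1, gamma2 = gamma2,
                 noise_var = noise_var, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), alpha = alpha),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: ", x$n_control, " control + ", x$n_case,
      " case samples\n  phenotype ~ N(", x$pheno_mean, ", ", x$pheno_var,
      "), noise var ", x$noise_var, "\n  gamma = (", x$gamma0, ", ",
      x$gamma1, ", ", x$gamma2, "), ", x$n_reps, " reps, alpha ",
      x$alpha, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate one single-gene dataset
#'
#' Draws the phenotype i.i.d. normal (independently of group), sets the
#' group vector to `n_control` zeros followed by `n_case` ones, and
#' generates the expression of one gene from the linear generative model.
#' Fully reproducible from `(config$seed, rep_index)` via the
#' counter-based stream seed
#' `(seed * 1000003 + rep_index * 7919) mod (2^31 - 1)` (the two
#' multipliers are coprime, so distinct base seeds give disjoint
#' replicate streams over any practical replicate range).
#'
#' @param config a [sim_config()].
#' @param rep_index replicate counter (non-negative integer).
#' @return `list(expr = <1-gene expression_matrix>, design = <study_design>)`.
#' @export
simulate_dataset <- function(config, rep_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed * 1000003 + as.integer(rep_index) * 7919) %%
             2147483647)
  n <- config$n_control + config$n_case
  g <- c(rep(0L, config$n_control), rep(1L, config$n_case))
  ph <- stats::rnorm(n, config$pheno_mean, sqrt(config$pheno_var))
  eps <- stats::rnorm(n, 0, sqrt(config$noise_var))
  y <- config$gamma0 + config$gamma1 * g + config$gamma2 * ph + eps
  sample_ids <- sprintf("s%02d", seq_len(n))
  list(expr = expression_matrix(matrix(y, 1L, n), "gene_1", sample_ids),
       design = study_design(sample_ids, g, ph,
                             phenotype_name = "simulated_phenotype"))
}

# Closed-form p-values of the four per-replicate tests on one gene.
# Backs both run_rejection_study() and (through the vectorised module
# functions) the per-gene tests; kept as one kernel so the study engine
# and the user-facing path share identical arithmetic.
.joint_rep_pvalues <- function(y, g, ph) {
  n <- length(y)
  n1 <- sum(g == 1L); n0 <- n - n1
  y1 <- y[g == 1L]; y0 <- y[g == 0L]
  sp2 <- (sum((y1 - mean(y1))^2) + sum((y0 - mean(y0))^2)) / (n - 2L)
  tstat <- (mean(y1) - mean(y0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  p_t <- 2 * stats::pt(-abs(tstat), n - 2L)

  r1 <- stats::cor(ph, y)
  p_m1 <- stats::pf((n - 2L) * r1^2 / (1 - r1^2), 1L, n - 2L,
                    lower.tail = FALSE)
  yw <- y - stats::ave(y, g)
  pw <- ph - stats::ave(ph, g)
  r2 <- sum(yw * pw) / sqrt(sum(yw^2) * sum(pw^2))
  p_m2 <- stats::pf((n - 3L) * r2^2 / (1 - r2^2), 1L, n - 3L,
                    lower.tail = FALSE)

  rss_g <- sum(yw^2)
  rss_full <- rss_g - sum(yw * pw)^2 / sum(pw^2)
  yc <- y - mean(y); pc <- ph - mean(ph)
  rss_p <- sum(yc^2) - sum(yc * pc)^2 / sum(pc^2)
  lambda <- min(n * log(rss_p / rss_full), n * log(rss_g / rss_full))
  p_model <- stats::pchisq(max(lambda, 0), 1L, lower.tail = FALSE)

  c(ttest = p_t, m1 = p_m1, m2 = p_m2, model = p_model)
}

.study_methods <- c("naive_m1", "naive_m2", "hier_m1", "hier_m2",
                    "model_based")

#' Monte-Carlo rejection-rate study over an effect grid
#'
#' For every `(gamma1, gamma2)` cell, simulates `config$n_reps`
#' single-gene datasets and applies the selected joint strategies at
#' level `config$alpha`.  The two-stage strategies use raw p-value
#' thresholds at both stages (the fixed-5% comparison), under which the
#' naive and hierarchical variants coincide; both are still computed by
#' their own decision rule.  Per-cell seeds are
#' `(seed + 131071 * cell_index) mod (2^31 - 1)`, so the table is
#' bit-reproducible and cells are independently re-runnable.
#'
#' @param gamma1_grid,gamma2_grid numeric effect grids (non-empty).
#' @param config a [sim_config()]; its `gamma1`/`gamma2` are overridden
#'   cell by cell.
#' @param methods subset of
#'   `c("naive_m1", "naive_m2", "hier_m1", "hier_m2", "model_based")`.
#' @return a data frame of class `"rejection_table"` with columns
#'   gamma1, gamma2, method, rejection_rate, mc_se
#'   (`sqrt(r*(1-r)/n_reps)`), n_reps.
#' @export
run_rejection_study <- function(gamma1_grid, gamma2_grid,
                                config = sim_config(),
                                methods = .study_methods) {
  if (length(gamma1_grid) == 0L || length(gamma2_grid) == 0L)
    stop("effect grids must be non-empty")
  bad <- setdiff(methods, .study_methods)
  if (length(bad) > 0L)
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  cells <- expand.grid(gamma1 = gamma1_grid, gamma2 = gamma2_grid,
                       KEEP.OUT.ATTRS = FALSE)
  alpha <- config$alpha
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cfg <- config
    cfg$gamma1 <- cells$gamma1[ci]
    cfg$gamma2 <- cells$gamma2[ci]
    cfg$seed <- as.integer((config$seed + 131071 * (ci - 1)) %% (2^31 - 1))
    rej <- matrix(FALSE, cfg$n_reps, length(.study_methods),
                  dimnames = list(NULL, .study_methods))
    for (rep in seq_len(cfg$n_reps)) {
      ds <- simulate_dataset(cfg, rep)
      pv <- .joint_rep_pvalues(as.vector(unclass(ds$expr)),
                               ds$design$group, ds$design$phenotype)
      deg <- pv[["ttest"]] < alpha
      rej[rep, ] <- c(deg && pv[["m1"]] < alpha,
                      deg && pv[["m2"]] < alpha,
                      if (deg) pv[["m1"]] < alpha else FALSE,
                      if (deg) pv[["m2"]] < alpha else FALSE,
                      pv[["model"]] < alpha)
    }
    r <- colMeans(rej)[methods]
    out[[ci]] <- data.frame(gamma1 = cells$gamma1[ci],
                            gamma2 = cells$gamma2[ci],
                            method = methods, rejection_rate = unname(r),
                            mc_se = unname(sqrt(r * (1 - r) / cfg$n_reps)),
                            n_reps = cfg$n_reps, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out),
            class = c("rejection_table", "data.frame"))
}

#' Power / type-I-error curves from a rejection table
#'
#' One panel per value of the fixed parameter; rejection rate against the
#' varying parameter, one line per method.
#'
#' @param table a `"rejection_table"` from [run_rejection_study()].
#' @param fixed which parameter indexes the panels, `"gamma1"` or
#'   `"gamma2"`.
#' @param file optional output file (`.pdf` or `.png`); `NULL` draws on
#'   the active device.
#' @return invisibly, the table.
#' @export
plot_power_curves <- function(table, fixed = c("gamma1", "gamma2"),
                              file = NULL) {
  fixed <- match.arg(fixed)
  varying <- setdiff(c("gamma1", "gamma2"), fixed)
  fvals <- sort(unique(table[[fixed]]))
  vvals <- sort(unique(table[[varying]]))
  methods <- unique(table$method)
  for (fv in fvals) for (vv in vvals) for (m in methods)
    if (sum(table[[fixed]] == fv & table[[varying]] == vv &
            table$method == m) != 1L)
      stop("rejection table is missing the cell (", fixed, " = ", fv, ", ",
           varying, " = ", vv, ", ", m, ")")
  if (!is.null(file)) {
    if (grepl("\\.png$", file)) grDevices::png(file, 1200L, 900L, res = 130L)
    else grDevices::pdf(file, width = 10L, height = 7.5)
    on.exit(grDevices::dev.off())
  }
  nf <- length(fvals)
  mfrow <- c(ceiling(nf / min(nf, 3L)), min(nf, 3L))
  oldpar <- graphics::par(mfrow = mfrow, mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(oldpar), add = TRUE)
  cols <- grDevices::hcl.colors(length(methods), "Dark 2")
  for (fv in fvals) {
    sub <- table[table[[fixed]] == fv, ]
    graphics::plot(NA, xlim = range(vvals),
                   ylim = c(0, max(sub$rejection_rate, 0.1) * 1.1),
                   xlab = varying, ylab = "rejection rate",
                   main = paste0(fixed, " = ", fv))
    for (k in seq_along(methods)) {
      s <- sub[sub$method == methods[k], ]
      s <- s[order(s[[varying]]), ]
      graphics::lines(s[[varying]], s$rejection_rate, col = cols[k],
                      lwd = 2L, type = "b", pch = 16L)
    }
    graphics::abline(h = 0.05, lty = 3L, col = "grey50")
    graphics::legend("topleft", legend = methods, col = cols, lwd = 2L,
                     bty = "n", cex = 0.8)
  }
  invisible(table)
}

#' @export
plot.rejection_table <- function(x, fixed = c("gamma1", "gamma2"),
                                 file = NULL, ...) {
  plot_power_curves(x, fixed = fixed, file = file)
}
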