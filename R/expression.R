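#' Construct an expression matrix
#'
#' Wraps a numeric genes-by-samples matrix of (typically log-scale)
#' expression values, enforcing unique gene and sample identifiers and
#' finite values.  Genes whose values are constant across all samples are
#' retained but flagged (attribute `"zero_variance"`); downstream tests
#' report `NaN` p-values for them instead of failing.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return a matrix of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required (or set dimnames on 'values')")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length of gene_ids (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("length of sample_ids (", length(sample_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite (no NA/NaN/Inf)")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values,
            zero_variance = zero_variance_genes(values),
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix: ", nrow(x), " genes x ", ncol(x), " samples\n",
      sep = "")
  nz <- sum(attr(x, "zero_variance"))
  if (!is.na(nz) && nz > 0)
    cat("  (", nz, " zero-variance gene",
        if (nz > 1) "s" else "", " flagged)\n", sep = "")
  utils::str(unclass(x)[seq_len(min(3L, nrow(x))),
                        seq_len(min(5L, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Flag genes with zero variance across samples
#'
#' @param expr an [expression_matrix()] (or plain numeric matrix).
#' @return named logical vector, `TRUE` for genes constant across samples.
#' @export
zero_variance_genes <- function(expr) {
  m <- unclass(as.matrix(expr))
  apply(m, 1L, function(v) max(v) == min(v))
}

.infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of gene ids
#' (the standard microarray matrix export layout: genes in rows).  The
#' delimiter is inferred from the extension (`.csv` for comma, otherwise
#' tab) unless given.
#'
#' @param path file path.
#' @param transform `"none"` (values used as read) or `"log2"` (all raw
#'   values must be strictly positive and are replaced by their log2).
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, transform = c("none", "log2"), sep = NULL) {
  transform <- match.arg(transform)
  if (is.null(sep)) sep <- .infer_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2L) stop("expression file needs a gene-id column plus >= 1 sample")
  gene_ids <- as.character(raw[[1L]])
  sample_ids <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("non-numeric value '", vals[bad[1L, 1L], bad[1L, 2L]],
           "' at gene '", gene_ids[bad[1L, 1L]],
           "', sample '", sample_ids[bad[1L, 2L]], "'")
    vals <- num
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop("missing value at gene '", gene_ids[bad[1L, 1L]],
         "', sample '", sample_ids[bad[1L, 2L]], "'")
  }
  if (transform == "log2") {
    if (any(vals <= 0))
      stop("log2 transform requested but the file contains values <= 0")
    vals <- log2(vals)
  }
  expression_matrix(vals, gene_ids, sample_ids)
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression()] (with `transform = "none"`).
#'
#' @param expr an [expression_matrix()].
#' @param path output file path.
#' @export
write_expression <- function(expr, path) {
  m <- unclass(as.matrix(expr))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a study design
#'
#' Per-sample two-group labels (0 = control, 1 = case) and one continuous
#' phenotype, aligned by sample id with a companion expression matrix.
#'
#' @param sample_id character vector of unique sample ids.
#' @param group integer/numeric vector of 0/1 labels, two levels present,
#'   each with at least two samples.
#' @param phenotype numeric vector of finite phenotype values.
#' @param phenotype_name name of the phenotype (e.g. `"leptin"`).
#' @param group_levels optional `c("0" = <label>, "1" = <label>)` record of
#'   the original group labels.
#' @return a data frame of class `"study_design"`.
#' @export
study_design <- function(sample_id, group, phenotype,
                         phenotype_name = "phenotype", group_levels = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in design")
  if (!all(group %in% c(0, 1)))
    stop("group must be coded 0/1 (use read_design() for labelled files)")
  group <- as.integer(group)
  if (length(unique(group)) != 2L)
    stop("exactly two group levels must be present")
  if (any(table(group) < 2L))
    stop("each group needs at least 2 samples")
  phenotype <- as.numeric(phenotype)
  if (!all(is.finite(phenotype)))
    stop("phenotype values must all be finite")
  if (length(group) != length(sample_id) ||
      length(phenotype) != length(sample_id))
    stop("sample_id, group and phenotype must have equal length")
  structure(data.frame(sample_id = sample_id, group = group,
                       phenotype = phenotype, stringsAsFactors = FALSE),
            phenotype_name = phenotype_name,
            group_levels = group_levels,
            class = c("study_design", "data.frame"))
}

#' Read a study design from delimited text
#'
#' Expects columns `sample_id`, `group`, and at least one phenotype
#' column.  Group labels are coerced to 0/1: numeric 0/1 is kept as-is;
#' otherwise a control-like label (`ND`, `control`, `ctrl`, `ctl`, `wt`,
#' `ref`, case-insensitive) maps to 0, else the first-appearing level
#' does.  The mapping is recorded in the `"group_levels"` attribute and
#' reported via `message()`.
#'
#' @param path file path.
#' @param phenotype_name which phenotype column to use.
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @return a [study_design()].
#' @export
read_design <- function(path, phenotype_name, sep = NULL) {
  if (is.null(sep)) sep <- .infer_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  for (col in c("sample_id", "group"))
    if (!col %in% colnames(df)) stop("design file lacks a '", col, "' column")
  if (!phenotype_name %in% colnames(df))
    stop("phenotype column '", phenotype_name, "' not found; available: ",
         paste(setdiff(colnames(df), c("sample_id", "group")), collapse = ", "))
  g_raw <- df$group
  lev <- unique(as.character(g_raw))
  if (length(lev) > 2L)
    stop("design has ", length(lev), " group levels (",
         paste(lev, collapse = ", "), "); exactly 2 are required")
  if (length(lev) < 2L)
    stop("design has a single group level; two are required")
  if (is.numeric(g_raw) && all(g_raw %in% c(0, 1))) {
    group <- as.integer(g_raw)
    group_levels <- c("0" = "0", "1" = "1")
  } else {
    control_like <- tolower(lev) %in% c("nd", "control", "ctrl", "ctl",
                                        "wt", "ref", "0")
    zero_lev <- if (sum(control_like) == 1L) lev[control_like] else lev[1L]
    group <- as.integer(as.character(g_raw) != zero_lev)
    group_levels <- c("0" = zero_lev, "1" = setdiff(lev, zero_lev))
    message("group coding: ", group_levels[["0"]], " -> 0, ",
            group_levels[["1"]], " -> 1")
  }
  ph <- suppressWarnings(as.numeric(df[[phenotype_name]]))
  if (anyNA(ph))
    stop("phenotype '", phenotype_name, "' has missing/non-numeric values")
  study_design(df$sample_id, group, ph, phenotype_name = phenotype_name,
               group_levels = group_levels)
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design: ", nrow(x), " samples (",
      sum(x$group == 0L), " control / ", sum(x$group == 1L), " case), ",
      "phenotype '", attr(x, "phenotype_name"), "'\n", sep = "")
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

# Refuse misaligned matrix/design pairs: every downstream test requires the
# sample_id sequences to be identical (not merely set-equal).
check_aligned <- function(expr, design) {
  if (!identical(colnames(expr), design$sample_id))
    stop("expression matrix and design are not aligned: sample id sequences differ")
  invisible(TRUE)
}

# Common carrier for per-gene test output.
gene_tests <- function(gene_id, method, statistic, pvalue, qvalue = NA_real_) {
  structure(data.frame(gene_id = as.character(gene_id), method = method,
                       statistic = statistic, pvalue = pvalue,
                       qvalue = qvalue, stringsAsFactors = FALSE),
            class = c("gene_tests", "data.frame"))
}

#' Write a per-gene result table
#'
#' Tab-delimited, deterministic column order
#' `gene_id, method, statistic, pvalue, qvalue`, rows in input gene order.
#'
#' @param results a result table from [deg_ttest()], [pag_test()] or the
#'   `$results` of a [joint_lrt()] fit.
#' @param path output file path.
#' @export
write_results <- function(results, path) {
  cols <- intersect(c("gene_id", "method", "statistic", "pvalue", "qvalue"),
                    colnames(results))
  utils::write.table(results[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a per-gene result table written by [write_results()]
#'
#' @param path file path.
#' @return a data frame of class `"gene_tests"`.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  class(df) <- c("gene_tests", "data.frame")
  df
}
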