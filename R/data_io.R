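#' Construct an expression matrix
#'
#' A thin typed container around a numeric genes x samples matrix. The scale
#' tag records whether values are linear (FPKM-like, non-negative) or already
#' log2(x+1) transformed; downstream statistics require the latter.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must carry
#'   unique row and column names.
#' @param scale one of `"linear"` or `"log2p1"`.
#' @return an object of class `expr_matrix` (a numeric matrix with a
#'   `scale` attribute).
#' @export
expr_matrix <- function(values, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene (row) and sample (column) names")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (scale == "linear" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at gene '%s', sample '%s' in linear-scale matrix",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("expr_matrix", class(out)))
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s scale]\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x an object.
#' @export
expr_scale <- function(x) attr(x, "scale")

#' Read an expression matrix from TSV
#'
#' Expects a header row whose first field is `gene_id` followed by sample
#' identifiers, then one row per gene with numeric values. Values are taken
#' to be linear scale (non-negative).
#'
#' @param path path to a tab-delimited file.
#' @return an [expr_matrix] with scale `"linear"`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a gene_id column plus >=1 sample")
  gene_ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(df) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, colnames(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                 bad[1], gene_ids[bad[1]], colnames(vals)[bad[2]]))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression at row %d (gene '%s'), column '%s'",
                 bad[1], gene_ids[bad[1]], colnames(vals)[bad[2]]))
  }
  rownames(vals) <- gene_ids
  expr_matrix(vals, scale = "linear")
}

#' Write an expression matrix to TSV
#'
#' Values are written at full precision (up to 17 significant digits) so that
#' `read_expression(write_expression(x))` reproduces `x` exactly.
#'
#' @param em an [expr_matrix].
#' @param path output path.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(gene_id = rownames(em),
                   format(unclass(em), digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(em))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_id`, `symbol`, `biotype`.
#' @return data.frame with one row per gene.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "biotype")
  if (!all(need %in% colnames(df)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  df
}

#' Read a clinical table
#'
#' Columns: `sample_id`, `time_days`, `event`, `stage`, `t_stage`, `n_stage`,
#' `m_stage`, `age`, `gender`; missing values may be empty strings or `NA`.
#'
#' @param path TSV path.
#' @return data.frame, one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!all(c("sample_id", "time_days", "event") %in% colnames(df)))
    stop("clinical TSV must have at least sample_id, time_days, event")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if (any(!is.finite(df$time_days)) || any(df$time_days <= 0))
    stop("time_days must be strictly positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path text file, one gene symbol per line; blank lines ignored.
#' @return character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Split an expression matrix by gene biotype
#'
#' Partitions genes into lncRNA and protein-coding sets using the annotation
#' table. Genes absent from the annotation are dropped with a warning.
#'
#' @param em an [expr_matrix].
#' @param annot annotation data.frame (`gene_id`, `symbol`, `biotype`).
#' @return list with elements `lncrna` and `mrna`, both [expr_matrix].
#' @export
split_by_biotype <- function(em, annot) {
  known <- rownames(em) %in% annot$gene_id
  if (any(!known))
    warning(sum(!known), " gene(s) absent from annotation were dropped")
  em <- em[known, , drop = FALSE]
  bt <- annot$biotype[match(rownames(em), annot$gene_id)]
  lnc <- em[bt == "lncRNA", , drop = FALSE]
  if (nrow(lnc) == 0) stop("no lncRNA-biotype genes present; cannot proceed")
  mrna <- em[bt == "protein_coding", , drop = FALSE]
  list(lncrna = lnc, mrna = mrna)
}

#' Filter a clinical table for survival analysis
#'
#' Drops samples with follow-up shorter than `min_days` (short-term deaths are
#' commonly attributed to causes other than the tumor) or with missing
#' time/event. Optional covariate columns whose cohort-wide missingness
#' exceeds `max_col_missing` are dropped as columns rather than triggering
#' sample exclusion; remaining samples with missing values in the surviving
#' optional covariates are then removed.
#'
#' @param clin clinical data.frame.
#' @param min_days minimum follow-up retained, inclusive (default 30).
#' @param max_col_missing drop a covariate column when more than this fraction
#'   of samples is missing (default 0.25).
#' @return filtered clinical data.frame.
#' @export
filter_clinical <- function(clin, min_days = 30, max_col_missing = 0.25) {
  keep <- !is.na(clin$time_days) & !is.na(clin$event) & clin$time_days >= min_days
  clin <- clin[keep, , drop = FALSE]
  optional <- setdiff(colnames(clin), c("sample_id", "time_days", "event"))
  if (length(optional) && nrow(clin)) {
    miss <- vapply(clin[optional], function(v) mean(is.na(v)), numeric(1))
    drop_cols <- optional[miss > max_col_missing]
    if (length(drop_cols)) {
      warning("dropping covariate column(s) with >", max_col_missing * 100,
              "% missing: ", paste(drop_cols, collapse = ", "))
      clin <- clin[, setdiff(colnames(clin), drop_cols), drop = FALSE]
    }
    optional <- setdiff(optional, drop_cols)
    if (length(optional)) {
      complete <- !Reduce(`|`, lapply(clin[optional], is.na))
      clin <- clin[complete, , drop = FALSE]
    }
  }
  if (nrow(clin) == 0) stop("no samples remain after clinical filtering")
  rownames(clin) <- NULL
  clin
}

#' log2(x + 1) transform of a linear-scale expression matrix
#'
#' @param em an [expr_matrix] with scale `"linear"`.
#' @return an [expr_matrix] with scale `"log2p1"`.
#' @export
log_transform <- function(em) {
  if (!inherits(em, "expr_matrix")) stop("`em` must be an expr_matrix")
  if (expr_scale(em) != "linear")
    stop("matrix is already log-transformed (scale '", expr_scale(em), "')")
  expr_matrix(log2(unclass(em) + 1), scale = "log2p1")
}
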