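#' Score one gene pair within one sample
#'
#' The pair score is 1 when the first gene's expression strictly exceeds the
#' second's, otherwise 0 (ties score 0). Because the score depends only on the
#' within-sample ordering, it is invariant to any strictly increasing
#' per-sample transform — the property that makes pair signatures portable
#' across platforms and normalizations.
#'
#' @param e_a,e_b finite expression values (any common monotone scale).
#' @return 0 or 1.
#' @export
score_pair <- function(e_a, e_b) {
  if (any(!is.finite(e_a)) || any(!is.finite(e_b)))
    stop("expression values must be finite")
  as.numeric(e_a > e_b)
}

#' Build the binary pair-score matrix over a gene set
#'
#' Enumerates every unordered gene pair once, in canonical orientation
#' (`gene_a` lexicographically before `gene_b`), and scores each pair in each
#' sample with [score_pair()]. The mirrored pair would carry the complementary
#' score, so nothing is lost by fixing the orientation. Rows are named
#' `"GENEA|GENEB"`.
#'
#' The matrix is materialized densely; this is comfortable up to a few
#' thousand genes (C(2000, 2) rows). Use [build_filtered_pairs()] to stream
#' larger gene sets directly through the frequency filter.
#'
#' @param em [expr_matrix] restricted to the genes of interest (typically the
#'   DEirlncRNAs) and to tumor samples.
#' @return binary matrix of class `pair_matrix`, pairs x samples.
#' @export
build_pair_matrix <- function(em) {
  if (nrow(em) < 2) stop("need at least 2 genes to form pairs")
  if (ncol(em) < 1) stop("need at least 1 sample")
  x <- t(unclass(em))[, order(rownames(em)), drop = FALSE]
  if (any(!is.finite(x))) stop("expression values must be finite")
  idx <- utils::combn(ncol(x), 2)
  scores <- t((x[, idx[1, ], drop = FALSE] > x[, idx[2, ], drop = FALSE]) + 0)
  rownames(scores) <- paste(colnames(x)[idx[1, ]], colnames(x)[idx[2, ]], sep = "|")
  colnames(scores) <- rownames(x)
  structure(scores, class = c("pair_matrix", class(scores)))
}

#' @export
`[.pair_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) out <- structure(out, class = c("pair_matrix", class(out)))
  out
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %d pairs x %d samples (binary scores)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Split pair identifiers into their member genes
#'
#' @param pm a `pair_matrix`, or a character vector of `"GENEA|GENEB"` ids.
#' @return data.frame with columns `pair`, `gene_a`, `gene_b`.
#' @export
pair_defs <- function(pm) {
  ids <- if (is.character(pm)) pm else rownames(pm)
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(pair = ids,
             gene_a = vapply(parts, `[`, character(1), 1),
             gene_b = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Frequency filter for pair scores
#'
#' A pair whose score is (nearly) constant across the cohort cannot rank
#' patients; only pairs whose score-1 frequency lies in the closed interval
#' \[`low`, `high`\] are kept.
#'
#' @param pm a `pair_matrix`.
#' @param low,high inclusive frequency bounds (defaults 0.2 and 0.8).
#' @return the filtered `pair_matrix` (sample order unchanged).
#' @export
frequency_filter <- function(pm, low = 0.2, high = 0.8) {
  if (ncol(pm) < 1) stop("pair matrix has no samples")
  freq <- rowMeans(pm)
  pm[freq >= low & freq <= high, , drop = FALSE]
}

#' Build and frequency-filter pairs in streaming chunks
#'
#' Equivalent to `frequency_filter(build_pair_matrix(em), low, high)` but
#' never materializes more than `chunk_size` unfiltered pair rows at a time,
#' so gene sets well beyond the dense builder's comfort zone remain tractable.
#'
#' @inheritParams build_pair_matrix
#' @inheritParams frequency_filter
#' @param chunk_size unfiltered pair rows held in memory at once.
#' @return filtered `pair_matrix`.
#' @export
build_filtered_pairs <- function(em, low = 0.2, high = 0.8,
                                 chunk_size = 100000L) {
  if (nrow(em) < 2) stop("need at least 2 genes to form pairs")
  x <- t(unclass(em))[, order(rownames(em)), drop = FALSE]
  g <- ncol(x)
  idx <- utils::combn(g, 2)
  kept <- vector("list", ceiling(ncol(idx) / chunk_size))
  for (k in seq_along(kept)) {
    cols <- seq((k - 1) * chunk_size + 1, min(k * chunk_size, ncol(idx)))
    sub <- idx[, cols, drop = FALSE]
    scores <- t((x[, sub[1, ], drop = FALSE] > x[, sub[2, ], drop = FALSE]) + 0)
    rownames(scores) <- paste(colnames(x)[sub[1, ]], colnames(x)[sub[2, ]], sep = "|")
    freq <- rowMeans(scores)
    kept[[k]] <- scores[freq >= low & freq <= high, , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  colnames(out) <- rownames(x)
  structure(out, class = c("pair_matrix", class(out)))
}

#' Write / read a pair-score matrix as TSV
#'
#' First column `pair` holds `"GENEA|GENEB"` identifiers; remaining columns
#' are samples with binary entries.
#'
#' @param pm a `pair_matrix`.
#' @param path file path.
#' @export
write_pair_matrix <- function(pm, path) {
  df <- data.frame(pair = rownames(pm), unclass(pm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!all(m %in% c(0, 1))) stop("pair matrix entries must be 0/1")
  structure(m, class = c("pair_matrix", class(m)))
}
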