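#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation with the two-sided p-value from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom. Constant
#' input has no defined correlation; such calls return a flagged degenerate
#' record with p = 1 so that screening simply never retains the gene.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with `r`, `p`, and logical `degenerate`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = 1, degenerate = TRUE))
  r <- stats::cor(x, y)
  p <- .cor_pvalue(r, n)
  list(r = r, p = p, degenerate = FALSE)
}

# two-sided p for a correlation at sample size n; exact +/-1 underflows to
# the smallest positive double so -log10(p) stays finite
.cor_pvalue <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[!is.finite(t)] <- 0
  pmax(p, .Machine$double.xmin)
}

#' Select immune-related lncRNAs by co-expression with immune genes
#'
#' A lncRNA is retained when at least one immune gene correlates with it at
#' |r| > `r_thresh` and p < `p_thresh` (both strict). The absolute value is
#' deliberate: negatively co-regulated lncRNAs are still immune-related.
#'
#' @param lnc_em,imm_em [expr_matrix] objects on the log2(x+1) scale sharing
#'   the same samples (order may differ).
#' @param r_thresh,p_thresh screening thresholds (defaults 0.4 and 0.001).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `ids` (retained lncRNA identifiers) and `records`, a
#'   data.frame of all qualifying (lnc_id, immune_gene_id, r, p) records.
#' @export
select_immune_lncrnas <- function(lnc_em, imm_em, r_thresh = 0.4,
                                  p_thresh = 0.001,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(colnames(lnc_em), colnames(imm_em))
  if (length(common) == 0) stop("lncRNA and immune matrices share no samples")
  if (length(common) < ncol(lnc_em) || length(common) < ncol(imm_em))
    warning("matrices restricted to ", length(common), " shared samples")
  lx <- t(unclass(lnc_em[, common, drop = FALSE]))
  ix <- t(unclass(imm_em[, common, drop = FALSE]))
  n <- length(common)
  if (method == "spearman") {
    lx <- apply(lx, 2, rank)
    ix <- apply(ix, 2, rank)
  }
  suppressWarnings(rmat <- stats::cor(lx, ix))  # NA for zero-variance genes
  pmat <- .cor_pvalue(rmat, n)
  hit <- !is.na(rmat) & abs(rmat) > r_thresh & pmat < p_thresh
  idx <- which(hit, arr.ind = TRUE)
  records <- data.frame(
    lnc_id = rownames(rmat)[idx[, 1]],
    immune_gene_id = colnames(rmat)[idx[, 2]],
    r = rmat[idx], p = pmat[idx],
    stringsAsFactors = FALSE
  )
  records <- records[order(records$lnc_id, records$immune_gene_id), , drop = FALSE]
  rownames(records) <- NULL
  list(ids = rownames(lnc_em)[rownames(lnc_em) %in% unique(records$lnc_id)],
       records = records)
}

#' Tumor-vs-normal differential expression (Welch t-test)
#'
#' Per-gene Welch two-sample t-test on log2(x+1) values with
#' Benjamini-Hochberg adjustment across all tested genes. The log fold change
#' is the plain difference of group means on the log2 scale.
#'
#' @param em [expr_matrix] on the log2(x+1) scale.
#' @param groups data.frame with columns `sample_id` and
#'   `group` (values `"tumor"` / `"normal"`), covering the matrix samples.
#' @return data.frame with columns gene_id, log_fc, p, fdr, direction.
#' @export
differential_expression <- function(em, groups) {
  g <- groups$group[match(colnames(em), groups$sample_id)]
  if (anyNA(g)) stop("some samples are missing from `groups`")
  tum <- unclass(em)[, g == "tumor", drop = FALSE]
  nor <- unclass(em)[, g == "normal", drop = FALSE]
  n1 <- ncol(tum); n2 <- ncol(nor)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(tum); m2 <- rowMeans(nor)
  v1 <- apply(tum, 1, stats::var); v2 <- apply(nor, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  # degenerate genes: zero variance in both groups
  flat <- se2 == 0
  p[flat & m1 == m2] <- 1
  p[flat & m1 != m2] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  data.frame(
    gene_id = rownames(em),
    log_fc = m1 - m2,
    p = p,
    fdr = bh_adjust(p),
    direction = ifelse(m1 - m2 >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Identify differentially expressed immune-related lncRNAs
#'
#' Convenience composition of the co-expression screen and the DE test:
#' restrict to immune-related lncRNAs, test tumor vs normal, and keep genes
#' with |logFC| > `logfc_thresh` and FDR < `fdr_thresh` (both strict; the
#' absolute value keeps down-regulated lncRNAs).
#'
#' @param lnc_em lncRNA [expr_matrix] (log2(x+1) scale), all samples.
#' @param imm_em immune-gene [expr_matrix] (log2(x+1) scale), all samples.
#' @param groups sample grouping data.frame (`sample_id`, `group`).
#' @param r_thresh,p_thresh co-expression screen thresholds.
#' @param logfc_thresh,fdr_thresh DE thresholds (defaults 1 and 0.05).
#' @return list with `ids` (DEirlncRNA identifiers), `de` (full DE table over
#'   immune-related lncRNAs), and `correlation` (screen output).
#' @export
screen_deirlncrna <- function(lnc_em, imm_em, groups,
                              r_thresh = 0.4, p_thresh = 0.001,
                              logfc_thresh = 1, fdr_thresh = 0.05) {
  sel <- select_immune_lncrnas(lnc_em, imm_em, r_thresh, p_thresh)
  if (length(sel$ids) == 0)
    return(list(ids = character(), de = NULL, correlation = sel))
  de <- differential_expression(lnc_em[sel$ids, , drop = FALSE], groups)
  keep <- abs(de$log_fc) > logfc_thresh & de$fdr < fdr_thresh
  list(ids = de$gene_id[keep], de = de, correlation = sel)
}
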