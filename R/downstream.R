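#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator per group via [survival::survfit()]; censored
#' times reduce the risk set without producing a step.
#'
#' @param time,event survival data.
#' @param group group labels aligned with `time`.
#' @return named list (one element per group) of data.frames with columns
#'   `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event, group) {
  group <- as.character(group)
  if (any(table(group) == 0) || anyNA(group)) stop("every sample needs a group")
  out <- lapply(split(seq_along(time), group), function(i) {
    if (length(i) == 0) stop("empty group")
    sf <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               surv = sf$surv)
  })
  structure(out, class = c("km_curves", "list"))
}

#' Two-group log-rank test
#'
#' Observed minus hypergeometric-expected events summed over distinct event
#' times, via [survival::survdiff()]; chi-square with (groups - 1) degrees
#' of freedom.
#'
#' @param time,event survival data.
#' @param group labels with at least two non-empty groups.
#' @return list with `chi_square`, `df`, `p`, and logical `degenerate`
#'   (zero total variance, e.g. a single event).
#' @export
log_rank <- function(time, event, group) {
  group <- as.character(group)
  if (length(unique(group)) < 2) stop("need at least two groups")
  if (sum(event) < 1) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  if (!is.finite(sd$chisq))
    return(list(chi_square = NA_real_, df = df, p = NA_real_,
                degenerate = TRUE))
  list(chi_square = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Chi-square association between risk group and a categorical covariate
#'
#' Pearson chi-square without continuity correction. Cells with expected
#' count below 5 trigger the usual approximation warning.
#'
#' @param group risk-group labels.
#' @param covariate categorical covariate aligned with `group`; missing
#'   values are dropped pairwise.
#' @return list with `statistic`, `df`, `p`, `table` (observed contingency
#'   table), `expected`.
#' @export
chi_square_assoc <- function(group, covariate) {
  keep <- !is.na(group) & !is.na(covariate)
  tab <- table(group[keep], covariate[keep])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate contingency table (empty margin)")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, expected = ct$expected)
}

#' Rank-sum (Mann-Whitney) comparison of a value between two groups
#'
#' Exact enumeration for small untied samples (total n <= 20), otherwise the
#' tie-corrected normal approximation; two-sided.
#'
#' @param values numeric vector.
#' @param group two-level labels aligned with `values`.
#' @return list with `U` (Mann-Whitney statistic of the first group level),
#'   `p`, and the group level order used.
#' @export
rank_sum_compare <- function(values, group) {
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2) stop("need exactly two groups")
  v1 <- values[group == lev[1]]
  v2 <- values[group == lev[2]]
  if (length(v1) == 0 || length(v2) == 0) stop("empty group")
  ties <- anyDuplicated(c(v1, v2)) > 0
  exact <- (length(v1) + length(v2) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(v1, v2, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value, levels = lev)
}

#' Associate the risk score with an external sample-by-feature table
#'
#' For each feature column, either Spearman correlation against the
#' continuous risk score (t-approximation p-value) or a rank-sum comparison
#' between the high/low risk groups. Both raw and BH-adjusted p-values are
#' reported; the significance flag follows the conventional unadjusted
#' p < 0.05.
#'
#' @param rp a `risk_profile` (with `group` set when using the rank-sum
#'   method).
#' @param features data.frame whose first column is `sample_id`, remaining
#'   columns numeric features (immune-cell fractions, checkpoint-gene
#'   expression, per-drug IC50, ...); or a numeric matrix with sample row
#'   names.
#' @param method `"spearman_vs_score"` or `"rank_sum_vs_group"`.
#' @param min_overlap_warn warn when the shared-sample fraction falls below
#'   this value (default 0.5).
#' @return data.frame with feature_id, statistic kind and value, p,
#'   adjusted p, direction, significant flag.
#' @export
associate_features <- function(rp, features,
                               method = c("spearman_vs_score",
                                          "rank_sum_vs_group"),
                               min_overlap_warn = 0.5) {
  method <- match.arg(method)
  if (is.matrix(features))
    features <- data.frame(sample_id = rownames(features), features,
                           check.names = FALSE, stringsAsFactors = FALSE)
  common <- intersect(rp$sample_id, features$sample_id)
  if (length(common) == 0) stop("no overlapping samples")
  if (length(common) < 3) stop("need at least 3 overlapping samples")
  if (length(common) / nrow(rp) < min_overlap_warn)
    warning("only ", length(common), "/", nrow(rp),
            " risk-profile samples overlap the feature table")
  rp2 <- rp[match(common, rp$sample_id), ]
  fx <- features[match(common, features$sample_id), -1, drop = FALSE]

  rows <- lapply(colnames(fx), function(fid) {
    v <- as.numeric(fx[[fid]])
    ok <- !is.na(v)
    if (method == "spearman_vs_score") {
      ct <- suppressWarnings(
        stats::cor.test(rp2$risk_score[ok], v[ok], method = "spearman",
                        exact = FALSE))
      data.frame(feature_id = fid, kind = "spearman_rho",
                 statistic = unname(ct$estimate), p = ct$p.value,
                 direction = ifelse(ct$estimate >= 0, "positive", "negative"),
                 stringsAsFactors = FALSE)
    } else {
      if (is.null(rp2$group)) stop("risk profile has no group; dichotomize first")
      rs <- rank_sum_compare(v[ok], rp2$group[ok])
      med_diff <- stats::median(v[ok][rp2$group[ok] == "high"]) -
        stats::median(v[ok][rp2$group[ok] == "low"])
      data.frame(feature_id = fid, kind = "rank_sum",
                 statistic = rs$U, p = rs$p,
                 direction = ifelse(med_diff >= 0, "higher_in_high_risk",
                                    "higher_in_low_risk"),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  out[, c("feature_id", "kind", "statistic", "p", "p_adjusted",
          "direction", "significant")]
}

#' Ordinal encoding of clinical covariates for Cox models
#'
#' Stage-like variables are encoded ordinally (I-IV and T1-T4 to 1-4, N0-N3
#' to 0-3, M0/M1 to 0/1), gender as an indicator (male = 1), age passed
#' through. Only columns present in the table are encoded.
#'
#' @param clin clinical data.frame.
#' @return numeric matrix, samples x encoded covariates, with sample ids as
#'   row names.
#' @export
encode_clinical <- function(clin) {
  enc <- list()
  if ("stage" %in% names(clin))
    enc$stage <- match(clin$stage, c("I", "II", "III", "IV"))
  if ("t_stage" %in% names(clin))
    enc$t_stage <- match(clin$t_stage, c("T1", "T2", "T3", "T4"))
  if ("n_stage" %in% names(clin))
    enc$n_stage <- match(clin$n_stage, c("N0", "N1", "N2", "N3")) - 1
  if ("m_stage" %in% names(clin))
    enc$m_stage <- match(clin$m_stage, c("M0", "M1")) - 1
  if ("age" %in% names(clin)) enc$age <- as.numeric(clin$age)
  if ("gender" %in% names(clin))
    enc$gender <- as.numeric(clin$gender == "male")
  if (length(enc) == 0)
    return(matrix(numeric(0), nrow = nrow(clin), ncol = 0,
                  dimnames = list(clin$sample_id, NULL)))
  m <- do.call(cbind, enc)
  rownames(m) <- clin$sample_id
  m
}

#' Univariate and multivariate Cox independence analysis of the risk score
#'
#' Fits one single-covariate Cox model per covariate (risk score plus each
#' clinical variable) and one joint model, reporting hazard ratios, 95%
#' Wald confidence intervals and p-values in forest-table form. Collinear
#' covariates in the joint fit are flagged by name.
#'
#' @param risk named numeric vector of risk scores (names = sample ids), or
#'   a `risk_profile`.
#' @param clin clinical data.frame covering the same samples.
#' @param covariates which clinical columns to include (default: all
#'   encodable ones present).
#' @return list with `univariate` (data.frame, one row per covariate),
#'   `multivariate` (`cox_fit`), and `collinear` (character vector of
#'   dropped/aliased covariates in the joint fit).
#' @export
cox_independence <- function(risk, clin, covariates = NULL) {
  if (inherits(risk, "risk_profile"))
    risk <- stats::setNames(risk$risk_score, risk$sample_id)
  common <- intersect(names(risk), clin$sample_id)
  if (length(common) == 0) stop("risk scores and clinical table share no samples")
  cl <- clin[match(common, clin$sample_id), ]
  enc <- encode_clinical(cl)
  if (!is.null(covariates))
    enc <- enc[, intersect(covariates, colnames(enc)), drop = FALSE]
  keep_col <- colSums(is.na(enc)) == 0
  enc <- enc[, keep_col, drop = FALSE]
  x <- cbind(risk_score = unname(risk[common]), enc)

  uni <- do.call(rbind, lapply(colnames(x), function(v) {
    f <- fit_cox(x[, v, drop = FALSE], cl$time_days, cl$event)
    f$table
  }))

  qrk <- qr(cbind(1, x))$rank
  collinear <- character(0)
  if (qrk < ncol(x) + 1) {
    # identify columns that add no rank on top of the preceding ones
    r <- 1
    base <- matrix(1, nrow(x), 1)
    for (v in colnames(x)) {
      cand <- cbind(base, x[, v])
      if (qr(cand)$rank > r) { base <- cand; r <- r + 1 }
      else collinear <- c(collinear, v)
    }
  }
  multi <- fit_cox(x[, setdiff(colnames(x), collinear), drop = FALSE],
                   cl$time_days, cl$event)
  list(univariate = uni, multivariate = multi, collinear = collinear)
}
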