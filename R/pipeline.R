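#' Run the full pair-signature pipeline on a cohort
#'
#' Chains every stage: log2(x+1) transform, biotype split, immune
#' co-expression screen, tumor-vs-normal differential expression, pair-score
#' matrix with frequency filter, univariate Cox screen, cross-validated
#' Lasso-Cox, AIC-stepwise multivariate Cox, risk scoring, 3-year
#' time-dependent ROC with Youden cutoff, dichotomization, and Kaplan-Meier /
#' log-rank validation of the resulting groups.
#'
#' Model selection and the ROC cutoff use the samples in `fit_sample_ids`
#' (default: all tumor samples passing the clinical filter), so held-out
#' samples can be scored and evaluated with the returned model without
#' leakage.
#'
#' @param expression linear-scale [expr_matrix] over tumor and normal
#'   samples, or a `synthetic_cohort` (in which case the other data arguments
#'   are taken from it).
#' @param annotation gene annotation data.frame.
#' @param clinical clinical data.frame (tumor samples).
#' @param immune_genes character vector of immune gene symbols.
#' @param groups data.frame (`sample_id`, `group` in tumor/normal).
#' @param r_thresh,p_thresh co-expression screen thresholds.
#' @param logfc_thresh,fdr_thresh differential-expression thresholds.
#' @param min_days minimum clinical follow-up retained.
#' @param freq_low,freq_high pair-frequency filter bounds.
#' @param uni_p univariate Cox retention threshold.
#' @param folds,lasso_rule Lasso-Cox cross-validation settings.
#' @param horizon_days ROC horizon (default 1095, i.e. 3 years).
#' @param seed integer seed for the cross-validation fold assignment.
#' @param fit_sample_ids samples used for selection/fitting (default all).
#' @return list of class `pair_pipeline` with elements `screen` (correlation
#'   + DE output), `deirlncrna_ids`, `pair_matrix` (frequency-filtered, all
#'   clinical tumor samples), `univariate`, `lasso`, `model`
#'   (`pair_signature`), `risk` (`risk_profile` over all clinical tumor
#'   samples, dichotomized when a cutoff exists), `roc` (training `td_roc`),
#'   `cutoff`, `km`, `log_rank`, `clinical` (filtered), and `fit_sample_ids`.
#' @export
run_pair_pipeline <- function(expression, annotation = NULL, clinical = NULL,
                              immune_genes = NULL, groups = NULL,
                              r_thresh = 0.4, p_thresh = 0.001,
                              logfc_thresh = 1, fdr_thresh = 0.05,
                              min_days = 30, freq_low = 0.2, freq_high = 0.8,
                              uni_p = 0.05, folds = 10,
                              lasso_rule = c("min", "1se"),
                              horizon_days = 1095, seed = 1L,
                              fit_sample_ids = NULL) {
  lasso_rule <- match.arg(lasso_rule)
  if (inherits(expression, "synthetic_cohort")) {
    cohort <- expression
    expression <- cohort$expression
    annotation <- cohort$annotation
    clinical <- cohort$clinical
    groups <- cohort$groups
    immune_genes <- cohort$annotation$symbol[
      cohort$annotation$gene_id %in% cohort$immune_genes]
  }

  log_em <- log_transform(expression)
  parts <- split_by_biotype(log_em, annotation)
  imm_ids <- annotation$gene_id[annotation$symbol %in% immune_genes]
  imm_em <- parts$mrna[intersect(rownames(parts$mrna), imm_ids), , drop = FALSE]
  if (nrow(imm_em) == 0) stop("no immune genes found in the expression matrix")

  screen <- screen_deirlncrna(parts$lncrna, imm_em, groups,
                              r_thresh = r_thresh, p_thresh = p_thresh,
                              logfc_thresh = logfc_thresh,
                              fdr_thresh = fdr_thresh)
  if (length(screen$ids) < 2)
    stop("fewer than 2 DEirlncRNAs survive the screen; cannot build pairs")

  clin <- filter_clinical(clinical, min_days = min_days)
  tumor_ids <- intersect(clin$sample_id,
                         groups$sample_id[groups$group == "tumor"])
  clin <- clin[clin$sample_id %in% tumor_ids, , drop = FALSE]
  if (is.null(fit_sample_ids)) fit_sample_ids <- tumor_ids
  fit_sample_ids <- intersect(fit_sample_ids, tumor_ids)
  fit_clin <- clin[clin$sample_id %in% fit_sample_ids, , drop = FALSE]

  pm <- build_pair_matrix(log_em[screen$ids, tumor_ids, drop = FALSE])
  pm_fit <- frequency_filter(pm[, fit_sample_ids, drop = FALSE],
                             freq_low, freq_high)
  pm <- pm[rownames(pm_fit), , drop = FALSE]

  uni <- univariate_cox_screen(pm_fit, fit_clin, p_thresh = uni_p)

  lasso <- NULL
  candidates <- uni$retained
  if (length(candidates) >= 2) {
    lasso <- lasso_cox_cv(pm_fit[candidates, , drop = FALSE], fit_clin,
                          folds = folds, seed = seed, rule = lasso_rule)
    candidates <- lasso$selected
  }

  if (length(candidates) >= 1) {
    model <- stepwise_multivariate_cox(pm_fit[candidates, , drop = FALSE],
                                       fit_clin)
  } else {
    model <- structure(list(pairs = character(), betas = numeric(),
                            aic = NA_real_, loglik = NA_real_, fit = NULL,
                            anova = NULL,
                            meta = list(direction = "none", fallback = FALSE)),
                       class = "pair_signature")
  }

  risk <- compute_risk_scores(model, pm)
  fit_risk <- risk$risk_score[match(fit_sample_ids, risk$sample_id)]
  roc <- td_roc(fit_risk, fit_clin$time_days, fit_clin$event, horizon_days)
  cutoff <- NA_real_
  km <- NULL
  lr <- NULL
  if (!roc$degenerate && length(model$pairs) > 0 &&
      length(unique(fit_risk)) > 1) {
    cutoff <- select_cutoff(roc)
    risk <- dichotomize(risk, cutoff)
    cl_all <- clin[match(risk$sample_id, clin$sample_id), ]
    if (length(unique(risk$group)) == 2) {
      km <- km_estimate(cl_all$time_days, cl_all$event, risk$group)
      lr <- log_rank(cl_all$time_days, cl_all$event, risk$group)
    }
  }

  structure(list(
    screen = screen, deirlncrna_ids = screen$ids,
    pair_matrix = pm, univariate = uni, lasso = lasso, model = model,
    risk = risk, roc = roc, cutoff = cutoff, km = km, log_rank = lr,
    clinical = clin, fit_sample_ids = fit_sample_ids,
    params = list(r_thresh = r_thresh, p_thresh = p_thresh,
                  logfc_thresh = logfc_thresh, fdr_thresh = fdr_thresh,
                  min_days = min_days, freq_low = freq_low,
                  freq_high = freq_high, uni_p = uni_p, folds = folds,
                  lasso_rule = lasso_rule, horizon_days = horizon_days,
                  seed = seed)
  ), class = "pair_pipeline")
}

#' @export
print.pair_pipeline <- function(x, ...) {
  cat("pair-signature pipeline\n")
  cat(sprintf("  DEirlncRNAs:            %d\n", length(x$deirlncrna_ids)))
  cat(sprintf("  pairs after freq filter: %d\n", nrow(x$pair_matrix)))
  cat(sprintf("  univariate survivors:    %d\n", length(x$univariate$retained)))
  if (!is.null(x$lasso))
    cat(sprintf("  lasso survivors:         %d\n", length(x$lasso$selected)))
  cat(sprintf("  signature pairs:         %d\n", length(x$model$pairs)))
  if (!x$roc$degenerate)
    cat(sprintf("  %.0f-day AUC (training): %.4f\n", x$roc$horizon, x$roc$auc))
  if (!is.na(x$cutoff)) {
    cat(sprintf("  cutoff: %.4f (%d high / %d low)\n", x$cutoff,
                sum(x$risk$group == "high"), sum(x$risk$group == "low")))
  }
  if (!is.null(x$log_rank))
    cat(sprintf("  log-rank: chi-square %.3f, p = %.3g\n",
                x$log_rank$chi_square, x$log_rank$p))
  invisible(x)
}
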