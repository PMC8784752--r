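#' Fit a Cox proportional hazards model
#'
#' Thin typed wrapper around [survival::coxph()] with Breslow tie handling
#' and a tightened convergence tolerance. Covariates caught in a monotone
#' partial likelihood (perfect separation of event order) are flagged rather
#' than allowed to crash the caller; constant covariates are an error.
#'
#' @param features samples x k numeric matrix or data.frame with column
#'   names.
#' @param time,event survival time (days) and 0/1 event indicator.
#' @return object of class `cox_fit`: list with `table` (term, beta, hr,
#'   ci_low, ci_high, se, p per covariate), `loglik` (maximized log partial
#'   likelihood), `aic`, `n`, `n_events`, `flagged` (covariates with a
#'   monotone likelihood), `converged`, and the underlying `coxph` object.
#' @export
fit_cox <- function(features, time, event) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  if (length(time) != nrow(features) || length(event) != nrow(features))
    stop("time/event length must match the number of rows of `features`")
  if (sum(event) < 1) stop("need at least one observed event")
  const <- apply(features, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    stop("constant covariate column(s): ",
         paste(colnames(features)[const], collapse = ", "))

  terms <- colnames(features)
  safe <- make.names(terms, unique = TRUE)
  df <- data.frame(features, check.names = FALSE)
  colnames(df) <- safe
  df$.time <- time
  df$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", safe), collapse = " + ")))

  flagged <- integer(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-11,
                                                      iter.max = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("beta may be infinite|coefficient may be infinite", msg)) {
        nums <- as.integer(regmatches(msg, gregexpr("[0-9]+", msg))[[1]])
        flagged <<- union(flagged, nums[nums <= length(terms)])
        invokeRestart("muffleWarning")
      } else if (grepl("Ran out of iterations", msg)) {
        flagged <<- union(flagged, seq_along(terms))
        invokeRestart("muffleWarning")
      }
    })

  beta <- unname(stats::coef(fit))
  flagged <- union(flagged, which(!is.finite(beta)))
  se <- sqrt(diag(fit$var))
  z <- beta / se
  tab <- data.frame(
    term = terms,
    beta = beta,
    hr = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    se = se,
    p = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(
    table = tab,
    loglik = fit$loglik[2],
    aic = 2 * length(beta) - 2 * fit$loglik[2],
    n = nrow(features),
    n_events = sum(event),
    flagged = terms[flagged],
    converged = length(flagged) == 0,
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("cox_fit: %d covariate(s), n = %d, events = %d, loglik = %.4f\n",
              nrow(x$table), x$n, x$n_events, x$loglik))
  print(format(x$table, digits = digits), row.names = FALSE)
  if (length(x$flagged))
    cat("monotone-likelihood flag:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Univariate Cox screen over pair scores
#'
#' Fits one single-covariate Cox model (Breslow ties) per pair and retains
#' pairs with Wald p below `p_thresh`. Pairs with a monotone likelihood or a
#' score that is constant over the clinical samples are excluded with a
#' recorded reason.
#'
#' @param pm `pair_matrix` (pairs x tumor samples).
#' @param clin clinical data.frame (`sample_id`, `time_days`, `event`).
#' @param p_thresh retention threshold on the Wald p-value (default 0.05).
#' @return list with `retained` (pair ids), `table` (per-pair beta, hr, se,
#'   p), and `excluded` (pair, reason).
#' @export
univariate_cox_screen <- function(pm, clin, p_thresh = 0.05) {
  common <- intersect(colnames(pm), clin$sample_id)
  if (length(common) == 0) stop("pair matrix and clinical table share no samples")
  cl <- clin[match(common, clin$sample_id), ]
  y <- survival::Surv(cl$time_days, cl$event)
  ctrl <- survival::coxph.control(eps = 1e-11, iter.max = 50)
  w <- rep(1, length(common))

  res <- lapply(rownames(pm), function(id) {
    x <- matrix(as.numeric(pm[id, common]), ncol = 1,
                dimnames = list(common, id))
    if (length(unique(x[, 1])) == 1L)
      return(list(pair = id, reason = "constant"))
    fit <- tryCatch(
      suppressWarnings(
        survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = 0,
                            control = ctrl, weights = w, method = "breslow",
                            rownames = common)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients))
      return(list(pair = id, reason = "fit_failure"))
    beta <- unname(fit$coefficients)
    se <- sqrt(fit$var[1, 1])
    if (!is.finite(se) || abs(beta) > 10 || se > 50)
      return(list(pair = id, reason = "monotone_likelihood"))
    list(pair = id, beta = beta, se = se,
         p = 2 * stats::pnorm(-abs(beta / se)))
  })

  ok <- vapply(res, function(r) is.null(r$reason), logical(1))
  tab <- do.call(rbind, lapply(res[ok], function(r)
    data.frame(pair = r$pair, beta = r$beta, hr = exp(r$beta), se = r$se,
               p = r$p, stringsAsFactors = FALSE)))
  if (is.null(tab))
    tab <- data.frame(pair = character(), beta = numeric(), hr = numeric(),
                      se = numeric(), p = numeric())
  excluded <- do.call(rbind, lapply(res[!ok], function(r)
    data.frame(pair = r$pair, reason = r$reason, stringsAsFactors = FALSE)))
  if (is.null(excluded))
    excluded <- data.frame(pair = character(), reason = character())
  list(retained = tab$pair[tab$p < p_thresh], table = tab, excluded = excluded)
}

#' Cross-validated Lasso-Cox pair selection
#'
#' L1-penalized Cox regression over a descending penalty path via
#' [glmnet::cv.glmnet()]; the penalty minimizing the mean cross-validated
#' partial-likelihood deviance (or the one-standard-error penalty) is chosen
#' with a seeded fold assignment, and covariates with nonzero coefficients at
#' that penalty are returned.
#'
#' @param pm `pair_matrix` restricted to the candidate pairs.
#' @param clin clinical data.frame.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param rule `"min"` (default, minimum CV deviance) or `"1se"`.
#' @return list with `selected` (pair ids), `lambda`, `rule`, `seed`,
#'   `cv_fit` (the cv.glmnet object).
#' @export
lasso_cox_cv <- function(pm, clin, folds = 10, seed = 1L,
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  common <- intersect(colnames(pm), clin$sample_id)
  if (length(common) == 0) stop("pair matrix and clinical table share no samples")
  if (nrow(pm) < 2) stop("need at least 2 candidate pairs")
  cl <- clin[match(common, clin$sample_id), ]
  if (sum(cl$event) < folds)
    stop("fewer events (", sum(cl$event), ") than folds (", folds,
         "); reduce `folds`")
  x <- t(unclass(pm[, common, drop = FALSE]))
  y <- survival::Surv(cl$time_days, cl$event)
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = length(common)))
  cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
  lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.matrix(stats::coef(cv, s = lambda))[, 1]
  list(selected = names(cf)[cf != 0], lambda = lambda, rule = rule,
       seed = seed, cv_fit = cv)
}

#' AIC-guided stepwise multivariate Cox model
#'
#' Bidirectional stepwise search minimizing AIC = 2k - 2 log partial
#' likelihood, starting from the model containing all supplied pairs; the
#' search stops when no single addition or removal lowers the AIC, and the
#' surviving coefficients are those of the final refit. When the full
#' starting model cannot be fit (monotone likelihood), the search falls back
#' to forward selection from the empty model.
#'
#' @param pm `pair_matrix` restricted to the pairs entering the search
#'   (typically the Lasso survivors).
#' @param clin clinical data.frame.
#' @return object of class `pair_signature`: list with `pairs` (retained
#'   pair ids, possibly empty), `betas` (named coefficients), `aic`,
#'   `loglik`, `fit` (final `coxph` or NULL), `anova` (accepted stepwise
#'   path), and `meta` (direction, fallback flag).
#' @export
stepwise_multivariate_cox <- function(pm, clin) {
  common <- intersect(colnames(pm), clin$sample_id)
  if (length(common) == 0) stop("pair matrix and clinical table share no samples")
  if (nrow(pm) < 1) stop("need at least 1 candidate pair")
  cl <- clin[match(common, clin$sample_id), ]
  ids <- rownames(pm)
  safe <- make.names(ids, unique = TRUE)
  df <- data.frame(t(unclass(pm[, common, drop = FALSE])), check.names = FALSE)
  colnames(df) <- safe
  df$.time <- cl$time_days
  df$.event <- cl$event

  full_fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", safe), collapse = " + ")))
  null_fml <- survival::Surv(.time, .event) ~ 1

  fallback <- FALSE
  start <- tryCatch({
    fit <- survival::coxph(full_fml, data = df, ties = "breslow")
    if (any(!is.finite(stats::coef(fit))) ||
        any(abs(stats::coef(fit)) > 15)) stop("monotone likelihood")
    fit
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(start)) {
    fallback <- TRUE
    start <- survival::coxph(null_fml, data = df, ties = "breslow")
  }
  direction <- if (fallback) "forward" else "both"
  stepped <- stats::step(start,
                         scope = list(lower = null_fml, upper = full_fml),
                         direction = direction, trace = 0)

  cf <- stats::coef(stepped)
  kept_safe <- names(cf)
  kept_safe <- gsub("^`|`$", "", kept_safe)
  kept <- ids[match(kept_safe, safe)]
  betas <- stats::setNames(unname(cf), kept)
  aic <- 2 * length(cf) - 2 * stepped$loglik[length(stepped$loglik)]
  structure(list(
    pairs = kept,
    betas = betas,
    aic = aic,
    loglik = stepped$loglik[length(stepped$loglik)],
    fit = if (length(cf)) stepped else NULL,
    anova = stepped$anova,
    meta = list(direction = direction, fallback = fallback)
  ), class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("pair_signature: %d pair(s), AIC = %.3f\n",
              length(x$pairs), x$aic))
  if (length(x$pairs))
    print(data.frame(pair = x$pairs, beta = unname(x$betas)), row.names = FALSE)
  invisible(x)
}

#' Per-sample risk score of a pair signature
#'
#' risk = sum over signature pairs of beta_j * score_j.
#'
#' @param model a `pair_signature`.
#' @param pm `pair_matrix` containing at least the model's pairs.
#' @return data.frame of class `risk_profile` with columns `sample_id`,
#'   `risk_score` (and `group` once [dichotomize()] has been applied); the
#'   cutoff is carried as attribute `cutoff`.
#' @export
compute_risk_scores <- function(model, pm) {
  missing <- setdiff(model$pairs, rownames(pm))
  if (length(missing))
    stop("pair(s) absent from the pair matrix: ",
         paste(missing, collapse = ", "))
  risk <- if (length(model$pairs) == 0) {
    stats::setNames(rep(0, ncol(pm)), colnames(pm))
  } else {
    drop(crossprod(unclass(pm[model$pairs, , drop = FALSE]), model$betas))
  }
  structure(
    data.frame(sample_id = colnames(pm), risk_score = unname(risk),
               stringsAsFactors = FALSE, row.names = NULL),
    cutoff = NA_real_, class = c("risk_profile", "data.frame"))
}

# Kaplan-Meier survival probability at a time point (last value carried
# forward past the end of follow-up)
.km_at <- function(time, event, at) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(sf, times = at, extend = TRUE)$surv
  if (length(s) == 0) 1 else s
}

#' Time-dependent ROC curve (cumulative cases / dynamic controls)
#'
#' At horizon t, cases are subjects with an event by t and controls are
#' subjects surviving past t; censoring is handled with the Kaplan-Meier
#' estimator: for each candidate cut c, with p_c the fraction of samples
#' with risk >= c and S_c(t) the KM survival at t within that set,
#' sensitivity = (1 - S_c(t)) p_c / (1 - S(t)) and
#' 1 - specificity = S_c(t) p_c / S(t). The AUC is the trapezoidal area of
#' the resulting curve. With no censoring before the horizon this reduces
#' exactly to the empirical (Mann-Whitney) ROC of cases vs controls.
#'
#' @param risk numeric risk scores.
#' @param time,event survival data aligned with `risk`.
#' @param horizon_days evaluation horizon t.
#' @return object of class `td_roc`: list with `horizon`, `cut_values`
#'   (ascending candidate thresholds; classification is positive when
#'   risk >= cut), `tpr`, `fpr`, `auc` (NA with `degenerate = TRUE` when
#'   there are no cases or no controls at the horizon).
#' @export
td_roc <- function(risk, time, event, horizon_days) {
  n <- length(risk)
  if (length(time) != n || length(event) != n)
    stop("risk, time and event must be aligned")
  if (any(!is.finite(risk))) stop("risk scores must be finite")
  s_all <- .km_at(time, event, horizon_days)
  if (s_all <= 0 || s_all >= 1) {
    return(structure(list(horizon = horizon_days,
                          cut_values = sort(unique(risk)),
                          tpr = NULL, fpr = NULL, auc = NA_real_,
                          degenerate = TRUE), class = "td_roc"))
  }
  cuts <- sort(unique(risk))
  pts <- vapply(cuts, function(cv) {
    sel <- risk >= cv
    p <- mean(sel)
    sc <- .km_at(time[sel], event[sel], horizon_days)
    c((1 - sc) * p / (1 - s_all), sc * p / s_all)
  }, numeric(2))
  tpr <- pmin(pmax(pts[1, ], 0), 1)
  fpr <- pmin(pmax(pts[2, ], 0), 1)
  # integrate along the threshold path (cut descending, both rates
  # non-decreasing), closed by the (0,0) and (1,1) endpoints
  xs <- c(0, rev(fpr), 1)
  ys <- c(0, rev(tpr), 1)
  auc <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  structure(list(horizon = horizon_days, cut_values = cuts, tpr = tpr,
                 fpr = fpr, auc = auc, degenerate = FALSE),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("td_roc at %.0f days: degenerate (no cases or no controls)\n",
                x$horizon))
  else
    cat(sprintf("td_roc at %.0f days: AUC = %.4f over %d candidate cuts\n",
                x$horizon, x$auc, length(x$cut_values)))
  invisible(x)
}

#' Choose a risk cutoff on a time-dependent ROC curve
#'
#' Returns the candidate cut maximizing Youden's J = sensitivity +
#' specificity - 1; ties are broken toward the smallest cut value.
#'
#' @param roc a non-degenerate `td_roc`.
#' @return the selected cutoff (classification: high risk iff
#'   risk >= cutoff).
#' @export
select_cutoff <- function(roc) {
  if (!inherits(roc, "td_roc")) stop("`roc` must come from td_roc()")
  if (roc$degenerate || is.na(roc$auc)) stop("degenerate ROC: no cutoff defined")
  j <- roc$tpr - roc$fpr
  best <- j >= max(j) - 1e-12
  min(roc$cut_values[best])
}

#' Dichotomize a risk profile at a cutoff
#'
#' @param rp a `risk_profile` from [compute_risk_scores()].
#' @param cutoff finite cutoff; samples with risk >= cutoff are labelled
#'   `"high"`, the rest `"low"`.
#' @return the `risk_profile` with a `group` column and the cutoff attribute
#'   set.
#' @export
dichotomize <- function(rp, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  rp$group <- ifelse(rp$risk_score >= cutoff, "high", "low")
  attr(rp, "cutoff") <- cutoff
  rp
}
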