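test_that("fit_cox reproduces the closed-form single-covariate solution", {
  # binary covariate, deaths at 1,4 (x=1) and 2,3 (x=0), no censoring:
  # the score equation reduces to u^2 + u - 1 = 0, u = exp(beta)
  f <- fit_cox(matrix(c(1, 1, 0, 0), ncol = 1, dimnames = list(NULL, "x")),
               time = c(1, 4, 2, 3), event = rep(1, 4))
  expect_equal(f$table$beta, log((sqrt(5) - 1) / 2), tolerance = 1e-7)
  expect_equal(f$table$hr, (sqrt(5) - 1) / 2, tolerance = 1e-7)
  expect_true(f$table$ci_low <= f$table$hr && f$table$hr <= f$table$ci_high)
})

test_that("fit_cox rejects constant covariates and flags separation", {
  expect_error(fit_cox(matrix(1, 5, 1, dimnames = list(NULL, "flat")),
                       time = 1:5, event = rep(1, 5)),
               "constant covariate.*flat")
  # all x=1 events precede all x=0 events: monotone likelihood
  f <- fit_cox(matrix(rep(c(1, 0), each = 5), ncol = 1,
                      dimnames = list(NULL, "x")),
               time = c(1:5, 11:15), event = rep(1, 10))
  expect_false(f$converged)
  expect_identical(f$flagged, "x")
})

test_that("fit_cox matches a grid-search partial-likelihood oracle", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1:2] <- c(0, 1)
    time <- rexp(n, exp(0.7 * x))
    event <- rbinom(n, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1
    f <- fit_cox(matrix(x, ncol = 1, dimnames = list(NULL, "x")), time, event)
    if (!f$converged) next
    expect_lt(abs(f$table$beta - grid_cox_beta(x, time, event)), 1e-4)
  }
})

test_that("univariate screen retains signal, controls noise, excludes separation", {
  set.seed(66)
  n <- 150
  ids <- sprintf("S%03d", 1:n)
  signal <- rbinom(n, 1, 0.5)
  lp <- 1.2 * signal
  time <- pmax(rexp(n, 5e-4 * exp(lp)), 1)
  cens <- runif(n, 0, 3650)
  clin <- toy_clinical(pmin(time, cens), as.integer(time <= cens), ids)
  noise <- matrix(rbinom(20 * n, 1, 0.5), 20,
                  dimnames = list(sprintf("N%02d|M%02d", 1:20, 1:20), ids))
  pm <- structure(rbind("SIG|REF" = signal, noise),
                  class = c("pair_matrix", "matrix"))
  colnames(pm) <- ids
  sc <- univariate_cox_screen(pm, clin, p_thresh = 0.05)
  expect_true("SIG|REF" %in% sc$retained)
  expect_lt(mean(rownames(noise) %in% sc$retained), 0.3)

  # a score perfectly aligned with event order is excluded, not crashed
  o <- order(clin$time_days)
  sep <- as.numeric(seq_len(n) %in% o[1:40])
  clin2 <- clin; clin2$event <- as.integer(seq_len(n) %in% o[1:40])
  pm2 <- structure(matrix(sep, 1, dimnames = list("P|Q", ids)),
                   class = c("pair_matrix", "matrix"))
  sc2 <- univariate_cox_screen(pm2, clin2)
  expect_identical(sc2$excluded$reason, "monotone_likelihood")
  expect_length(sc2$retained, 0)
})

test_that("lasso selection is seeded-deterministic and fully shrinks at the path top", {
  set.seed(19)
  n <- 120
  ids <- sprintf("S%03d", 1:n)
  pm <- structure(matrix(rbinom(30 * n, 1, 0.5), 30,
                         dimnames = list(sprintf("A%02d|B%02d", 1:30, 1:30), ids)),
                  class = c("pair_matrix", "matrix"))
  lp <- 1.5 * pm[1, ]
  time <- pmax(rexp(n, 5e-4 * exp(lp)), 1)
  cens <- runif(n, 0, 3650)
  clin <- toy_clinical(pmin(time, cens), as.integer(time <= cens), ids)

  a <- lasso_cox_cv(pm, clin, folds = 5, seed = 11)
  b <- lasso_cox_cv(pm, clin, folds = 5, seed = 11)
  expect_identical(a$selected, b$selected)

  # at the largest penalty every coefficient is zero
  top <- as.matrix(stats::coef(a$cv_fit$glmnet.fit,
                               s = max(a$cv_fit$lambda)))
  expect_true(all(top == 0))

  expect_error(lasso_cox_cv(pm, clin, folds = 200), "fewer events")
})

test_that("stepwise search keeps informative covariates and drops duplicates", {
  set.seed(29)
  n <- 400
  ids <- sprintf("S%03d", 1:n)
  informative <- rbinom(n, 1, 0.5)
  noise <- rbinom(n, 1, 0.5)
  lp <- 1.0 * informative
  time <- pmax(rexp(n, 5e-4 * exp(lp)), 1)
  cens <- runif(n, 0, 3650)
  clin <- toy_clinical(pmin(time, cens), as.integer(time <= cens), ids)
  pm <- structure(rbind("INF|REF" = informative, "NOI|REF" = noise),
                  class = c("pair_matrix", "matrix"))
  colnames(pm) <- ids
  m <- stepwise_multivariate_cox(pm, clin)
  expect_true("INF|REF" %in% m$pairs)
  expect_false("NOI|REF" %in% m$pairs)
  # accepted path never increases AIC
  expect_true(all(diff(m$anova$AIC) <= 1e-8))

  # duplicated covariate: AIC keeps exactly one of the two copies
  pm_dup <- structure(rbind("INF|REF" = informative, "INF|ALT" = informative),
                      class = c("pair_matrix", "matrix"))
  colnames(pm_dup) <- ids
  m2 <- stepwise_multivariate_cox(pm_dup, clin)
  expect_length(m2$pairs, 1)

  # single-covariate input degenerates to an AIC comparison with the null
  m3 <- stepwise_multivariate_cox(pm["INF|REF", , drop = FALSE], clin)
  expect_identical(m3$pairs, "INF|REF")
})

test_that("risk scores are the beta-weighted pair scores", {
  pm <- structure(matrix(c(1, 0, 1), 3, 1,
                         dimnames = list(c("A|B", "C|D", "E|F"), "S1")),
                  class = c("pair_matrix", "matrix"))
  model <- structure(list(pairs = c("A|B", "C|D", "E|F"),
                          betas = c("A|B" = 0.5, "C|D" = -1.0, "E|F" = 2.0)),
                     class = "pair_signature")
  rp <- compute_risk_scores(model, pm)
  expect_equal(rp$risk_score, 2.5)

  model0 <- structure(list(pairs = c("A|B"), betas = c("A|B" = 0)),
                      class = "pair_signature")
  expect_equal(compute_risk_scores(model0, pm)$risk_score, 0)

  bad <- structure(list(pairs = "X|Y", betas = c("X|Y" = 1)),
                   class = "pair_signature")
  expect_error(compute_risk_scores(bad, pm), "X\\|Y")
})

test_that("flipping a pair orientation shifts every risk by a constant", {
  set.seed(3)
  em <- random_expr(6, 25, seed = 3)
  pm <- build_pair_matrix(em)
  pairs <- rownames(pm)[1:3]
  betas <- stats::setNames(c(0.8, -0.4, 1.1), pairs)
  model <- structure(list(pairs = pairs, betas = betas),
                     class = "pair_signature")
  r1 <- compute_risk_scores(model, pm)$risk_score
  # flip pair 1: mirrored score is 1 - s (no ties), negated beta
  pm_flip <- pm
  pm_flip[pairs[1], ] <- 1 - pm_flip[pairs[1], ]
  betas2 <- betas; betas2[1] <- -betas2[1]
  model2 <- structure(list(pairs = pairs, betas = betas2),
                      class = "pair_signature")
  r2 <- compute_risk_scores(model2, pm_flip)$risk_score
  expect_equal(r2 - r1, rep(-betas[[1]], length(r1)), tolerance = 1e-12)
  expect_identical(order(r1), order(r2))
})

test_that("time-dependent ROC handles separation, matches Mann-Whitney, flags degeneracy", {
  # perfect separation at the horizon
  roc <- td_roc(risk = c(0.1, 0.2, 0.8, 0.9),
                time = c(10, 9, 1, 2), event = c(0, 0, 1, 1),
                horizon_days = 5)
  expect_equal(roc$auc, 1)
  expect_equal(select_cutoff(roc), 0.8)

  # equals the pairwise Mann-Whitney statistic with no censoring
  set.seed(41)
  for (i in 1:10) {
    n <- sample(20:50, 1)
    risk <- rnorm(n)
    time <- rexp(n, exp(0.8 * risk))
    hz <- unname(stats::quantile(time, runif(1, 0.3, 0.7)))
    roc <- td_roc(risk, time, rep(1, n), hz)
    expect_lt(abs(roc$auc - mw_auc(risk, time <= hz)), 1e-10)
  }

  # risk independent of outcome: AUC near 1/2
  set.seed(47)
  n <- 1000
  risk <- rnorm(n); time <- rexp(n, 1e-3); cens <- runif(n, 0, 3650)
  roc0 <- td_roc(risk, pmin(time, cens), as.integer(time <= cens), 1095)
  expect_gt(roc0$auc, 0.45); expect_lt(roc0$auc, 0.55)

  # no cases before the horizon: degenerate, no cutoff
  rocd <- td_roc(c(1, 2, 3), time = c(50, 60, 70), event = c(1, 1, 1),
                 horizon_days = 5)
  expect_true(rocd$degenerate)
  expect_error(select_cutoff(rocd), "degenerate")
})

test_that("cutoff selection maximizes Youden's J with ties toward the smallest cut", {
  # flat curve: all J equal, smallest candidate returned
  flat <- structure(list(horizon = 100, cut_values = c(-1, 0, 2),
                         tpr = c(1, 0.6, 0.2), fpr = c(1, 0.6, 0.2),
                         auc = 0.5, degenerate = FALSE), class = "td_roc")
  expect_identical(select_cutoff(flat), -1)
  # unique interior maximum
  toy <- structure(list(horizon = 100, cut_values = c(1, 2, 3),
                        tpr = c(1, 0.9, 0.3), fpr = c(1, 0.4, 0.2),
                        auc = 0.75, degenerate = FALSE), class = "td_roc")
  j <- toy$tpr - toy$fpr                     # exhaustive: 0, 0.5, 0.1
  expect_identical(select_cutoff(toy), toy$cut_values[which.max(j)])
})

test_that("dichotomization uses the inclusive high-risk boundary", {
  rp <- structure(data.frame(sample_id = c("a", "b", "c"),
                             risk_score = c(1, 2, 3)),
                  cutoff = NA_real_, class = c("risk_profile", "data.frame"))
  expect_identical(dichotomize(rp, 2)$group, c("low", "high", "high"))
  expect_identical(dichotomize(rp, 0.5)$group, rep("high", 3))
  expect_identical(dichotomize(rp, 99)$group, rep("low", 3))
  expect_error(dichotomize(rp, Inf), "finite")
})
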