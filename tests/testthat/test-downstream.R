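test_that("Kaplan-Meier estimates match product-limit hand computations", {
  km <- km_estimate(c(1, 2), c(1, 1), rep("g", 2))$g
  expect_equal(km$surv, c(0.5, 0))

  km2 <- km_estimate(c(5, 8, 11), c(0, 0, 0), rep("g", 3))$g
  expect_true(all(km2$surv == 1))

  # censor at 1, death at 2: single step of full size (risk set of 1)
  km3 <- km_estimate(c(1, 2), c(0, 1), rep("g", 2))$g
  expect_equal(km3$surv[km3$time == 2], 0)
  expect_equal(km3$n_event[km3$time == 2], 1)

  # with no censoring the curve is 1 - empirical CDF of event times
  set.seed(14)
  t <- rexp(40, 0.01)
  km4 <- km_estimate(t, rep(1, 40), rep("g", 40))$g
  expect_equal(km4$surv, 1 - ecdf(t)(km4$time), tolerance = 1e-12)
})

test_that("log-rank reproduces the hand-computed statistic and is label-symmetric", {
  lr <- log_rank(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr$chi_square, (7 / 6)^2 / (17 / 36), tolerance = 1e-9)
  expect_equal(lr$chi_square, 49 / 17, tolerance = 1e-9)

  swapped <- log_rank(c(1, 2, 3, 4), rep(1, 4), c("B", "B", "A", "A"))
  expect_equal(lr$chi_square, swapped$chi_square, tolerance = 1e-12)

  # identical groups: statistic 0
  same <- log_rank(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
})

test_that("log-rank p agrees with a permutation oracle on a small instance", {
  set.seed(25)
  time <- rexp(14, 0.1)
  event <- rbinom(14, 1, 0.85)
  group <- rep(c("A", "B"), each = 7)
  lr <- log_rank(time, event, group)
  expect_lt(abs(lr$p - perm_logrank_p(time, event, group)), 0.1)
})

test_that("chi-square association matches the direct formula", {
  cs <- chi_square_assoc(rep(c("hi", "lo"), c(30, 30)),
                         c(rep(c("x", "y"), c(10, 20)),
                           rep(c("x", "y"), c(20, 10))))
  expect_equal(cs$statistic, 20 / 3, tolerance = 1e-12)
  expect_identical(cs$df, 1L)

  flat <- chi_square_assoc(rep(c("hi", "lo"), each = 20),
                           rep(c("x", "y"), 20))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)

  # brute force sum((O-E)^2/E) on random tables
  set.seed(10)
  for (i in 1:5) {
    g <- sample(c("a", "b"), 60, replace = TRUE)
    v <- sample(c("p", "q", "r"), 60, replace = TRUE)
    got <- suppressWarnings(chi_square_assoc(g, v))
    o <- table(g, v)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    expect_equal(got$statistic, sum((o - e)^2 / e), tolerance = 1e-12)
  }

  expect_error(chi_square_assoc(rep("hi", 10), rep(c("x", "y"), 5)),
               "degenerate")
})

test_that("rank-sum comparison is exact for small samples and tie-robust", {
  rs <- rank_sum_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(rs$U, 0)
  expect_equal(rs$p, 0.1)   # enumeration over C(6,3) = 20 rankings

  same <- rank_sum_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)

  set.seed(18)
  v <- rnorm(16)
  g <- rep(c("a", "b"), each = 8)
  rs2 <- rank_sum_compare(v, g)
  expect_lt(abs(rs2$p - perm_ranksum_p(v, g)), 0.05)

  expect_error(rank_sum_compare(1:3, rep("a", 3)), "two groups")
})

test_that("feature association recovers monotone identities and reports BH", {
  set.seed(36)
  n <- 60
  ids <- sprintf("S%03d", 1:n)
  rp <- structure(data.frame(sample_id = ids, risk_score = rnorm(n)),
                  cutoff = NA_real_, class = c("risk_profile", "data.frame"))
  feats <- data.frame(sample_id = ids,
                      same = rp$risk_score,
                      flipped = -rp$risk_score,
                      noise = rnorm(n))
  rec <- associate_features(rp, feats, method = "spearman_vs_score")
  expect_equal(rec$statistic[rec$feature_id == "same"], 1)
  expect_equal(rec$statistic[rec$feature_id == "flipped"], -1)
  expect_true(all(rec$p_adjusted >= rec$p))
  # invariant to monotone transforms of the feature
  feats2 <- feats; feats2$same <- exp(feats2$same)
  rec2 <- associate_features(rp, feats2, method = "spearman_vs_score")
  expect_equal(rec2$statistic[rec2$feature_id == "same"], 1)

  # rank-sum route requires groups
  expect_error(associate_features(rp, feats, method = "rank_sum_vs_group"),
               "dichotomize")
  rp2 <- dichotomize(rp, stats::median(rp$risk_score))
  rec3 <- associate_features(rp2, feats, method = "rank_sum_vs_group")
  expect_true(rec3$significant[rec3$feature_id == "same"])

  expect_error(
    associate_features(rp, data.frame(sample_id = c("X1", "X2", "X3"),
                                      f = 1:3)),
    "no overlapping")
})

test_that("null features are flagged at roughly the nominal rate", {
  set.seed(58)
  n <- 200
  ids <- sprintf("S%03d", 1:n)
  rp <- structure(data.frame(sample_id = ids, risk_score = rnorm(n)),
                  cutoff = NA_real_, class = c("risk_profile", "data.frame"))
  feats <- data.frame(sample_id = ids,
                      matrix(rnorm(n * 50), n,
                             dimnames = list(NULL, sprintf("f%02d", 1:50))))
  rec <- associate_features(rp, feats, method = "spearman_vs_score")
  expect_lte(mean(rec$significant), 0.16)          # ~5% expected
  expect_lte(sum(rec$p_adjusted < 0.05), 1L)       # ~0 after BH
})

test_that("Cox independence analysis is consistent and detects collinearity", {
  set.seed(62)
  n <- 200
  ids <- sprintf("S%03d", 1:n)
  risk <- stats::setNames(rnorm(n), ids)
  time <- pmax(rexp(n, 5e-4 * exp(0.8 * risk)), 1)
  cens <- runif(n, 0, 3650)
  clin <- data.frame(sample_id = ids,
                     time_days = pmin(time, cens),
                     event = as.integer(time <= cens),
                     age = round(rnorm(n, 65, 10)),
                     gender = sample(c("male", "female"), n, TRUE),
                     stringsAsFactors = FALSE)

  # joint fit with a single covariate equals fit_cox on that covariate
  ci <- cox_independence(risk, clin[, c("sample_id", "time_days", "event")])
  ref <- fit_cox(matrix(unname(risk[ids]), ncol = 1,
                        dimnames = list(NULL, "risk_score")),
                 clin$time_days, clin$event)
  expect_equal(ci$multivariate$table$beta, ref$table$beta, tolerance = 1e-10)
  expect_equal(ci$univariate$beta, ref$table$beta, tolerance = 1e-10)

  # risk is significant in the joint model; independent noise is not
  ci2 <- cox_independence(risk, clin)
  tab <- ci2$multivariate$table
  expect_lt(tab$p[tab$term == "risk_score"], 0.001)
  expect_gt(min(tab$p[tab$term != "risk_score"]), 0.01)

  # a covariate duplicating the risk score is flagged as collinear
  clin3 <- clin
  clin3$age <- unname(risk[ids]) * 2        # exact linear copy
  ci3 <- cox_independence(risk, clin3)
  expect_true("age" %in% ci3$collinear)
  expect_false("age" %in% ci3$multivariate$table$term)
})
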