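# Independent oracles and small fixture builders shared across tests.

# Mann-Whitney AUC of case risks vs control risks (brute-force pairwise).
mw_auc <- function(risk, is_case) {
  cmp <- outer(risk[is_case], risk[!is_case], ">") +
    0.5 * outer(risk[is_case], risk[!is_case], "==")
  mean(cmp)
}

# Breslow log partial likelihood for a single covariate, written directly
# from the definition (independent of the survival package).
breslow_loglik <- function(beta, x, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    rs <- time >= time[i]
    s <- s + beta * x[i] - log(sum(exp(beta * x[rs])))
  }
  s
}

# Grid/line-search maximizer of the Breslow partial likelihood.
grid_cox_beta <- function(x, time, event, lower = -5, upper = 5) {
  stats::optimize(function(b) breslow_loglik(b, x, time, event),
                  c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

# Brute-force pair filter: nested loops over canonical pairs, counting 1s.
brute_filtered_pairs <- function(vals, low = 0.2, high = 0.8) {
  g <- sort(rownames(vals))
  kept <- character(0)
  for (i in seq_len(length(g) - 1)) {
    for (j in seq((i + 1), length(g))) {
      ones <- sum(vals[g[i], ] > vals[g[j], ])
      f <- ones / ncol(vals)
      if (f >= low && f <= high)
        kept <- c(kept, paste(g[i], g[j], sep = "|"))
    }
  }
  kept
}

# Random linear-scale expression matrix with named genes/samples.
random_expr <- function(n_gene, n_samp, seed = 1) {
  set.seed(seed)
  vals <- matrix(stats::rlnorm(n_gene * n_samp, 2, 1), n_gene, n_samp,
                 dimnames = list(sprintf("G%03d", seq_len(n_gene)),
                                 sprintf("S%03d", seq_len(n_samp))))
  expr_matrix(vals, scale = "linear")
}

# Distinct strictly increasing transform per sample (nonlinear, positive
# domain): x -> exp(a_s * log(x + 1)) + b_s with a_s > 0.
monotone_warp <- function(em, seed = 99) {
  set.seed(seed)
  v <- unclass(em)
  a <- stats::runif(ncol(v), 0.5, 2)
  b <- stats::runif(ncol(v), 0, 3)
  out <- sapply(seq_len(ncol(v)), function(s) exp(a[s] * log(v[, s] + 1)) + b[s])
  dimnames(out) <- dimnames(v)
  expr_matrix(out, scale = "linear")
}

# Tiny clinical table around given survival data.
toy_clinical <- function(time, event, ids = sprintf("S%03d", seq_along(time))) {
  data.frame(sample_id = ids, time_days = time, event = event,
             stringsAsFactors = FALSE)
}

# Permutation p-value for the two-group log-rank statistic.
perm_logrank_p <- function(time, event, group, n_perm = 2000, seed = 5) {
  set.seed(seed)
  obs <- log_rank(time, event, group)$chi_square
  perm <- replicate(n_perm, {
    g <- sample(group)
    survival::survdiff(survival::Surv(time, event) ~ g)$chisq
  })
  mean(perm >= obs - 1e-12)
}

# Permutation p-value for the rank-sum comparison (two-sided, via |U - n1n2/2|).
perm_ranksum_p <- function(values, group, n_perm = 4000, seed = 5) {
  set.seed(seed)
  lev <- unique(group)
  n1 <- sum(group == lev[1]); n2 <- sum(group == lev[2])
  ustat <- function(g) {
    r <- rank(values)
    sum(r[g == lev[1]]) - n1 * (n1 + 1) / 2
  }
  obs <- abs(ustat(group) - n1 * n2 / 2)
  perm <- replicate(n_perm, abs(ustat(sample(group)) - n1 * n2 / 2))
  mean(perm >= obs - 1e-12)
}
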