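#' Simulation configuration for a synthetic tumor/normal cohort
#'
#' Defines the generative model used by [simulate_cohort()]: a single latent
#' immune factor shared by immune genes and a subset of lncRNAs, a planted
#' tumor-vs-normal expression shift on some of those lncRNAs, and survival
#' driven by an exponential-baseline Cox model on a small set of planted
#' gene-pair indicators, with uniform right censoring.
#'
#' With loading \eqn{a} and residual SD \eqn{s}, the population correlation
#' between any two latent-linked genes is \eqn{a^2 / (a^2 + s^2)}; the default
#' (1.0, 0.5) gives 0.8, comfortably above the 0.4 co-expression screen.
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_lnc,n_immune_genes,n_other_mrna gene counts per biotype block.
#' @param n_immune_linked lncRNAs loaded on the immune latent factor.
#' @param n_de lncRNAs (drawn from the immune-linked set) with a planted
#'   tumor shift.
#' @param de_log2fc planted tumor-vs-normal shift, log2 units.
#' @param n_planted_pairs prognostic pairs planted among the DE lncRNAs;
#'   pairs are disjoint and the two genes of a pair share a log2 mean so the
#'   pair indicator is close to Bernoulli(0.5).
#' @param planted_betas log-hazard coefficients, one per planted pair.
#' @param baseline_hazard events per day for a sample with all pair
#'   indicators 0.
#' @param censor_max_days upper bound of the uniform censoring time.
#' @param noise_sd residual SD on the log2 scale.
#' @param latent_loading loading of the immune latent factor.
#' @param seed integer seed governing all randomness.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_tumor = 400, n_normal = 50,
                              n_lnc = 200, n_immune_genes = 60,
                              n_other_mrna = 100,
                              n_immune_linked = 80, n_de = 60,
                              de_log2fc = 2,
                              n_planted_pairs = 5,
                              planted_betas = seq(0.5, 1, length.out = n_planted_pairs),
                              baseline_hazard = 5e-4,
                              censor_max_days = 3650,
                              noise_sd = 0.5, latent_loading = 1.0,
                              seed = 1L) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_lnc = n_lnc,
              n_immune_genes = n_immune_genes, n_other_mrna = n_other_mrna,
              n_immune_linked = n_immune_linked, n_de = n_de,
              de_log2fc = de_log2fc, n_planted_pairs = n_planted_pairs,
              planted_betas = planted_betas,
              baseline_hazard = baseline_hazard,
              censor_max_days = censor_max_days,
              noise_sd = noise_sd, latent_loading = latent_loading,
              seed = as.integer(seed))
  counts <- c("n_tumor", "n_normal", "n_lnc", "n_immune_genes", "n_other_mrna",
              "n_immune_linked", "n_de")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop("`", nm, "` must be a positive count")
  if (cfg$n_immune_linked > cfg$n_lnc)
    stop("n_immune_linked exceeds n_lnc")
  if (cfg$n_de > cfg$n_immune_linked)
    stop("n_de exceeds n_immune_linked: DE lncRNAs are drawn from the immune-linked set")
  if (cfg$n_planted_pairs > choose(cfg$n_de, 2))
    stop("n_planted_pairs exceeds the number of available DE pairs")
  if (2 * cfg$n_planted_pairs > cfg$n_de)
    stop("planted pairs are disjoint: need n_de >= 2 * n_planted_pairs")
  if (length(cfg$planted_betas) != cfg$n_planted_pairs)
    stop("planted_betas must have length n_planted_pairs")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (cfg$censor_max_days <= 30) stop("censor_max_days must exceed 30")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a tumor/normal expression cohort with known ground truth
#'
#' Generative steps, all driven by `config$seed`:
#' \enumerate{
#'   \item a per-sample latent immune factor f ~ N(0, 1); immune genes and the
#'     immune-linked lncRNAs have log2 expression
#'     mu_g + latent_loading * f + N(0, noise_sd); all other genes are
#'     independent of f.
#'   \item the first `n_de` immune-linked lncRNAs gain `de_log2fc` in tumor
#'     samples only.
#'   \item disjoint planted pairs (a, b) are formed over the DE lncRNAs with
#'     mu_a = mu_b; for each tumor sample the pair indicator is
#'     z = 1(expr_a > expr_b), and survival time is exponential with hazard
#'     baseline_hazard * exp(sum beta_j z_j), censored by U(0, censor_max_days);
#'     observed times shorter than one day are pushed up to 1.
#'   \item linear-scale expression is 2^(log2 value) - 1, floored at 0.
#' }
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_cohort` with elements `expression`
#'   (linear-scale [expr_matrix] over all samples), `annotation`, `groups`
#'   (data.frame sample_id/group), `clinical` (tumor samples only), and
#'   `truth` (immune-linked ids, DE ids, planted pair table with betas, and
#'   the config).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must come from simulation_config()")
  set.seed(config$seed)
  n_samp <- config$n_tumor + config$n_normal
  sample_ids <- sprintf("S%04d", seq_len(n_samp))
  group <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))

  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lnc))
  imm_ids <- sprintf("IMM%04d", seq_len(config$n_immune_genes))
  oth_ids <- sprintf("MRNA%04d", seq_len(config$n_other_mrna))
  gene_ids <- c(lnc_ids, imm_ids, oth_ids)

  immune_linked <- lnc_ids[seq_len(config$n_immune_linked)]
  de_ids <- immune_linked[seq_len(config$n_de)]

  mu <- stats::runif(length(gene_ids), 2, 6)
  names(mu) <- gene_ids

  # planted pairs: disjoint, partners share a baseline mean
  pair_gene_a <- de_ids[2 * seq_len(config$n_planted_pairs) - 1]
  pair_gene_b <- de_ids[2 * seq_len(config$n_planted_pairs)]
  mu[pair_gene_b] <- mu[pair_gene_a]
  swap <- pair_gene_a > pair_gene_b   # canonical orientation (lexicographic)
  tmp <- pair_gene_a[swap]; pair_gene_a[swap] <- pair_gene_b[swap]; pair_gene_b[swap] <- tmp
  planted <- data.frame(gene_a = pair_gene_a, gene_b = pair_gene_b,
                        beta = config$planted_betas, stringsAsFactors = FALSE)

  f <- stats::rnorm(n_samp)
  loading <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  loading[c(immune_linked, imm_ids)] <- config$latent_loading

  log2v <- matrix(mu, nrow = length(gene_ids), ncol = n_samp) +
    outer(loading, f) +
    matrix(stats::rnorm(length(gene_ids) * n_samp, sd = config$noise_sd),
           nrow = length(gene_ids))
  dimnames(log2v) <- list(gene_ids, sample_ids)
  log2v[de_ids, group == "tumor"] <- log2v[de_ids, group == "tumor"] + config$de_log2fc

  tumor_ids <- sample_ids[group == "tumor"]
  z <- vapply(seq_len(nrow(planted)), function(j) {
    as.numeric(log2v[planted$gene_a[j], tumor_ids] > log2v[planted$gene_b[j], tumor_ids])
  }, numeric(length(tumor_ids)))
  lp <- drop(z %*% planted$beta)
  hazard <- config$baseline_hazard * exp(lp)
  t_death <- stats::rexp(length(tumor_ids), rate = hazard)
  t_cens <- stats::runif(length(tumor_ids), 0, config$censor_max_days)
  time <- pmax(pmin(t_death, t_cens), 1)
  event <- as.integer(t_death <= t_cens)

  clinical <- data.frame(
    sample_id = tumor_ids,
    time_days = time,
    event = event,
    stage = sample(c("I", "II", "III", "IV"), length(tumor_ids), replace = TRUE,
                   prob = c(0.5, 0.25, 0.15, 0.10)),
    t_stage = sample(c("T1", "T2", "T3", "T4"), length(tumor_ids), replace = TRUE,
                     prob = c(0.3, 0.45, 0.15, 0.10)),
    n_stage = sample(c("N0", "N1", "N2", "N3"), length(tumor_ids), replace = TRUE,
                     prob = c(0.6, 0.2, 0.15, 0.05)),
    m_stage = ifelse(stats::runif(length(tumor_ids)) < 0.3, NA_character_,
                     sample(c("M0", "M1"), length(tumor_ids), replace = TRUE,
                            prob = c(0.9, 0.1))),
    age = round(stats::rnorm(length(tumor_ids), 65, 10)),
    gender = sample(c("male", "female"), length(tumor_ids), replace = TRUE),
    stringsAsFactors = FALSE
  )

  annotation <- data.frame(
    gene_id = gene_ids,
    symbol = gene_ids,
    biotype = rep(c("lncRNA", "protein_coding", "protein_coding"),
                  c(config$n_lnc, config$n_immune_genes, config$n_other_mrna)),
    stringsAsFactors = FALSE
  )

  expression <- expr_matrix(pmax(2^log2v - 1, 0), scale = "linear")

  structure(list(
    expression = expression,
    annotation = annotation,
    groups = data.frame(sample_id = sample_ids, group = group,
                        stringsAsFactors = FALSE),
    clinical = clinical,
    immune_genes = imm_ids,
    truth = list(immune_linked = immune_linked, de = de_ids,
                 planted_pairs = planted, config = config)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples (%d tumor / %d normal)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$groups$group == "tumor"), sum(x$groups$group == "normal")))
  cat(sprintf("  immune-linked lncRNAs: %d; DE lncRNAs: %d; planted pairs: %d\n",
              length(x$truth$immune_linked), length(x$truth$de),
              nrow(x$truth$planted_pairs)))
  invisible(x)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `expression.tsv`, `annotation.tsv`, `clinical.tsv`, `groups.tsv`,
#' `immune_genes.txt`, and truth sidecars `truth_pairs.tsv`
#' (gene_a, gene_b, beta) and `truth_genes.tsv` (gene_id, role with role in
#' {immune_linked, de}). Reading the files back reproduces the cohort values
#' exactly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory; must not already exist unless
#'   `overwrite = TRUE`.
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite)
    stop("directory '", dir, "' exists; use overwrite = TRUE to replace its files")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "annotation.tsv", "clinical.tsv",
                            "groups.tsv", "immune_genes.txt",
                            "truth_pairs.tsv", "truth_genes.tsv"))
  names(paths) <- c("expression", "annotation", "clinical", "groups",
                    "immune_genes", "truth_pairs", "truth_genes")
  write_expression(cohort$expression, paths["expression"])
  utils::write.table(cohort$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  clin <- cohort$clinical
  clin$time_days <- format(clin$time_days, digits = 17, trim = TRUE,
                           scientific = FALSE)
  utils::write.table(clin, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cohort$groups, paths["groups"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(cohort$immune_genes, paths["immune_genes"])
  utils::write.table(cohort$truth$planted_pairs, paths["truth_pairs"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tg <- rbind(
    data.frame(gene_id = cohort$truth$immune_linked, role = "immune_linked",
               stringsAsFactors = FALSE),
    data.frame(gene_id = cohort$truth$de, role = "de", stringsAsFactors = FALSE)
  )
  utils::write.table(tg, paths["truth_genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
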