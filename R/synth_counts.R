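# Negative-binomial count-matrix generator emulating the study design: six
# conditions (control genotype, post-deletion days 4/6/8/13, and a
# rapamycin-treated day-13 arm), four biological replicates each, planted
# differential expression whose effect sizes escalate over the days, a
# curated gene subset (standing in for an ion-channel / action-potential
# gene list), and a rescued subgroup whose rapamycin-arm means return to
# the control baseline.

#' Parameters for the count simulator
#'
#' @param n_genes Number of genes.
#' @param samples_per_condition Biological replicates per condition
#'   (default 4, the study design).
#' @param conditions Ordered condition labels; the last label is the
#'   rapamycin-treated arm and the one before it the reference day.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline mean.
#' @param dispersion_shape,dispersion_rate Gamma prior of the per-gene NB
#'   dispersion (defaults give mean 0.1, typical of bulk tissue).
#' @param de_fraction Fraction of genes with planted differential
#'   expression.
#' @param lfc_magnitude Absolute log2 fold change of planted genes at the
#'   reference day (sign drawn at random).
#' @param effect_schedule Named non-decreasing multipliers giving, per day,
#'   the fraction of the full effect already present (emulates the
#'   escalation of transcriptome changes over epileptogenesis).
#' @param curated_fraction Fraction of genes placed on the curated list.
#' @param curated_de_enrichment Relative enrichment of planted DE genes on
#'   the curated list (1 = none).
#' @param rescue_fraction Fraction of planted genes whose rapamycin-arm
#'   means equal the control baseline (full rescue); the rest keep their
#'   reference-day effect under treatment.
#' @param libsize_cv Coefficient of variation of log-normal library-size
#'   factors.
#' @param severity_sd SD of an optional per-sample severity multiplier on
#'   reference-day effect sizes (0 disables; emulates the large day-13
#'   sample-to-sample variation).
#' @return An object of class `count_sim_params`.
#' @export
count_sim_params <- function(n_genes = 2000,
                             samples_per_condition = 4,
                             conditions = c("Cre-", "d4", "d6", "d8", "d13", "Rap4"),
                             baseline_meanlog = log(150), baseline_sdlog = 1.2,
                             dispersion_shape = 4, dispersion_rate = 40,
                             de_fraction = 0.15, lfc_magnitude = 1.5,
                             effect_schedule = c("d4" = 0.2, "d6" = 0.35,
                                                 "d8" = 0.7, "d13" = 1),
                             curated_fraction = 0.1,
                             curated_de_enrichment = 1,
                             rescue_fraction = 0.95,
                             libsize_cv = 0.2,
                             severity_sd = 0) {
  stopifnot(n_genes >= 1, samples_per_condition >= 2,
            de_fraction >= 0, de_fraction <= 1,
            curated_fraction >= 0, curated_fraction <= 1,
            rescue_fraction >= 0, rescue_fraction <= 1,
            all(diff(effect_schedule) >= 0), libsize_cv >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 samples_per_condition = as.integer(samples_per_condition),
                 conditions = conditions,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion_shape = dispersion_shape,
                 dispersion_rate = dispersion_rate,
                 de_fraction = de_fraction, lfc_magnitude = lfc_magnitude,
                 effect_schedule = effect_schedule,
                 curated_fraction = curated_fraction,
                 curated_de_enrichment = curated_de_enrichment,
                 rescue_fraction = rescue_fraction,
                 libsize_cv = libsize_cv, severity_sd = severity_sd),
            class = "count_sim_params")
}

#' Simulate a six-condition count matrix with planted DE and rescue
#'
#' Counts are drawn NB with mean `baseline * 2^log2FC * library factor` and
#' a gamma-distributed gene-wise dispersion. Planted genes reach their full
#' log2 fold change at the reference day following the effect schedule;
#' rescued planted genes have rapamycin-arm means equal to the control
#' baseline, non-rescued ones keep their reference-day effect.
#'
#' @param p A [count_sim_params()].
#' @param seed Integer seed; fixes all randomness.
#' @return A list with `counts` (a [count_matrix()]), `truth` (list:
#'   `lfc` gene x condition matrix of true log2 fold changes, `de_by_day`
#'   gene x day logical matrix flagging |planted effect| >= 0.5,
#'   `planted`, `rescued`, `curated` logical vectors), and `curated_genes`
#'   (character vector of curated gene ids).
#' @export
simulate_counts <- function(p = count_sim_params(), seed = 1) {
  stopifnot(inherits(p, "count_sim_params"))
  set.seed(as.integer(seed))
  ng <- p$n_genes
  conds <- p$conditions
  npc <- p$samples_per_condition
  ref_day <- conds[length(conds) - 1L]
  rap <- conds[length(conds)]
  days <- names(p$effect_schedule)

  genes <- sprintf("gene_%05d", seq_len(ng))
  base_mu <- stats::rlnorm(ng, p$baseline_meanlog, p$baseline_sdlog)
  disp <- stats::rgamma(ng, shape = p$dispersion_shape, rate = p$dispersion_rate)

  planted <- stats::runif(ng) < p$de_fraction
  sign_g <- sample(c(-1, 1), ng, replace = TRUE)
  full_lfc <- ifelse(planted, sign_g * p$lfc_magnitude, 0)
  rescued <- planted & stats::runif(ng) < p$rescue_fraction

  # curated membership, optionally enriched for planted genes
  w <- ifelse(planted, p$curated_de_enrichment, 1)
  n_cur <- round(p$curated_fraction * ng)
  curated <- logical(ng)
  curated[sample.int(ng, n_cur, prob = w)] <- TRUE

  lfc <- matrix(0, ng, length(conds), dimnames = list(genes, conds))
  for (d in days) lfc[, d] <- full_lfc * p$effect_schedule[[d]]
  lfc[, rap] <- ifelse(rescued, 0, full_lfc)

  sample_cond <- rep(conds, each = npc)
  sample_ids <- paste0(sample_cond, "_", rep(seq_len(npc), length(conds)))
  libf <- stats::rlnorm(length(sample_ids),
                        meanlog = -log(1 + p$libsize_cv^2) / 2,
                        sdlog = sqrt(log(1 + p$libsize_cv^2)))
  sev <- rep(1, length(sample_ids))
  if (p$severity_sd > 0) {
    is_ref <- sample_cond == ref_day
    sev[is_ref] <- pmax(0.2, stats::rnorm(sum(is_ref), 1, p$severity_sd))
  }

  counts <- matrix(0L, ng, length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu_j <- base_mu * 2^(lfc[, sample_cond[j]] * sev[j]) * libf[j]
    counts[, j] <- stats::rnbinom(ng, size = 1 / pmax(disp, 1e-8), mu = mu_j)
  }

  de_by_day <- abs(lfc[, days, drop = FALSE]) >= 0.5
  cm <- count_matrix(counts, sample_cond)
  list(counts = cm,
       truth = list(lfc = lfc, de_by_day = de_by_day, planted = planted,
                    rescued = rescued & planted, curated = curated,
                    libsize = libf, dispersion = disp),
       curated_genes = genes[curated])
}

#' Write simulated counts to disk
#'
#' Emits `counts.tsv` (genes x samples), `samples.tsv` (sample, condition)
#' and `curated.txt` (one gene id per line) under `dir`.
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_count_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, "counts.tsv")
  utils::write.table(sim$counts$counts, cp, sep = "\t", quote = FALSE,
                     col.names = NA)
  sp <- file.path(dir, "samples.tsv")
  utils::write.table(data.frame(sample = colnames(sim$counts$counts),
                                condition = sim$counts$condition),
                     sp, sep = "\t", quote = FALSE, row.names = FALSE)
  gp <- file.path(dir, "curated.txt")
  writeLines(sim$curated_genes, gp)
  invisible(c(counts = cp, samples = sp, curated = gp))
}
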