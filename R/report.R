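# Cohort-level report assembly and the end-to-end synthetic study runner.
# assemble_report() aggregates per-cell measures into per-condition
# summaries, applying the per-animal cap (at most 8 randomly picked cells
# per animal, seeded) and recording every exclusion with a machine-readable
# reason. run_study() wires the whole pipeline together on synthetic data:
# simulate traces and counts, extract features, run the group statistics
# and the expression funnel, and write all artifacts under one directory
# with a manifest.

#' Pipeline configuration
#'
#' Bundles the per-module configurations with seeds and cohort sizes. Every
#' threshold defaults to the value used throughout the package.
#'
#' @param feature A [feature_config()].
#' @param detection A [detection_config()].
#' @param funnel A [funnel_config()].
#' @param counts A [count_sim_params()].
#' @param cells_per_group Cells simulated per genotype in [run_study()].
#' @param max_cells_per_animal Per-animal cap on cells entering the final
#'   analysis (default 8).
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(feature = feature_config(),
                            detection = detection_config(),
                            funnel = funnel_config(),
                            counts = count_sim_params(),
                            cells_per_group = 8L,
                            max_cells_per_animal = 8L,
                            seed = 1L) {
  structure(list(feature = feature, detection = detection, funnel = funnel,
                 counts = counts,
                 cells_per_group = as.integer(cells_per_group),
                 max_cells_per_animal = as.integer(max_cells_per_animal),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Assemble a cohort report from per-cell measurements
#'
#' @param cells Data frame with one row per cell: columns `cell_id`,
#'   `animal_id`, `condition`, plus any numeric measure columns.
#' @param cfg A [pipeline_config()] (supplies the per-animal cap and seed).
#' @param exclusions Optional data frame (`cell_id`, `reason`) of cells
#'   excluded upstream (e.g. insufficient events, no qualifying adaptation
#'   sweep); they are removed before aggregation and listed in the report.
#' @return A list of class `cohort_report`: `per_condition` (data frame of
#'   n, mean and SEM per measure and condition), `exclusions` (cell, reason;
#'   including cells dropped by the per-animal cap), `n_total`,
#'   `n_analyzed`.
#' @export
assemble_report <- function(cells, cfg = pipeline_config(),
                            exclusions = NULL) {
  stopifnot(all(c("cell_id", "animal_id", "condition") %in% names(cells)))
  excl <- if (is.null(exclusions)) {
    data.frame(cell_id = character(0), reason = character(0))
  } else exclusions[, c("cell_id", "reason")]
  work <- cells[!cells$cell_id %in% excl$cell_id, , drop = FALSE]

  # per-animal cap: seeded random subsample when an animal contributes more
  # than the cap
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  drop_ids <- character(0)
  for (an in sort(unique(work$animal_id))) {
    ids <- sort(work$cell_id[work$animal_id == an])
    if (length(ids) > cfg$max_cells_per_animal) {
      kept <- sort(sample(ids, cfg$max_cells_per_animal))
      drop_ids <- c(drop_ids, setdiff(ids, kept))
    }
  }
  if (length(drop_ids)) {
    excl <- rbind(excl, data.frame(cell_id = drop_ids,
                                   reason = "per-animal cap"))
    work <- work[!work$cell_id %in% drop_ids, , drop = FALSE]
  }

  measures <- setdiff(names(work), c("cell_id", "animal_id", "condition"))
  measures <- measures[vapply(work[measures], is.numeric, logical(1))]
  conds <- unique(cells$condition)
  rows <- lapply(conds, function(cc) {
    sub <- work[work$condition == cc, , drop = FALSE]
    row <- data.frame(condition = cc, n = nrow(sub))
    for (m in measures) {
      x <- sub[[m]][is.finite(sub[[m]])]
      row[[paste0(m, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0(m, "_sem")]] <- if (length(x) > 1)
        stats::sd(x) / sqrt(length(x)) else NA_real_
    }
    row
  })
  structure(list(per_condition = do.call(rbind, rows),
                 exclusions = excl,
                 n_total = nrow(cells), n_analyzed = nrow(work)),
            class = "cohort_report")
}

# simulate one cell's step family and extract intrinsic features; cells of
# a genotype share mean parameters but carry biological jitter (5% CV on
# conductance and capacitance, 1 mV SD on the threshold parameter) plus
# current noise, so cohort-level statistics see realistic variability
simulate_and_extract_cell <- function(np, protocol, seed, cfg) {
  set.seed(seed)
  np_j <- np
  np_j$gL_nS <- np$gL_nS * stats::rlnorm(1, 0, 0.05)
  np_j$C_pF <- np$C_pF * stats::rlnorm(1, 0, 0.05)
  np_j$VT_mV <- np$VT_mV + stats::rnorm(1, 0, 1)
  sim <- simulate_current_clamp(np_j, protocol, seed = seed, noise_sd_pA = 10)
  fi <- fi_curve(sim$sweeps, cfg$feature)
  ad <- adaptation_ratio(sim$sweeps, cfg$feature)
  list(fi = fi, adaptation = ad,
       rheobase = attr(fi, "rheobase_pA"))
}

#' Run the full synthetic study end to end
#'
#' Simulates a two-genotype current-clamp cohort (the mutant genotype has
#' lowered spike-triggered adaptation, yielding more spikes and an
#' adaptation ratio nearer 1), extracts F-I curves and adaptation ratios,
#' tests the genotype effect (two-way RM ANOVA on spike counts across
#' steps; t test on adaptation ratios), simulates paired mEPSC/mIPSC
#' recordings and computes E/I ratios, simulates one evoked pair and the
#' NMDA/AMPA ratio, simulates the six-condition count matrix and runs the
#' expression funnel with rescue classification, and assembles a cohort
#' report. All artifacts are written under `out_dir` with a manifest.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created; pass `NULL` to skip writing).
#' @param mutant_b_pA Spike-triggered adaptation increment of the mutant
#'   genotype (control uses the [neuron_params()] default).
#' @return A list of class `study_run` with elements `cells`, `rm_anova`,
#'   `adaptation_t`, `ei`, `evoked`, `funnel`, `report`, `manifest`.
#' @export
run_study <- function(cfg = pipeline_config(), out_dir = NULL,
                      mutant_b_pA = 10) {
  seed <- cfg$seed
  protocol <- step_protocol(n_sweeps = 36)
  groups <- list(control = neuron_params(),
                 mutant = neuron_params(b_pA = mutant_b_pA))
  cells <- list()
  fi_rows <- list()
  idx <- 0L
  for (gname in names(groups)) {
    for (ci in seq_len(cfg$cells_per_group)) {
      idx <- idx + 1L
      cell_seed <- seed * 10000L + idx
      ex <- simulate_and_extract_cell(groups[[gname]], protocol, cell_seed, cfg)
      cid <- sprintf("%s_c%02d", gname, ci)
      cells[[idx]] <- data.frame(
        cell_id = cid,
        animal_id = sprintf("%s_a%d", gname, ((ci - 1L) %/% 4L) + 1L),
        condition = gname,
        rheobase_pA = ex$rheobase,
        adaptation_ratio = ex$adaptation$ratio,
        adaptation_excluded = ex$adaptation$excluded)
      fi_rows[[idx]] <- data.frame(
        subject = cid, between = gname,
        within = sprintf("I%03d", seq_len(nrow(ex$fi))),
        value = ex$fi$n_spikes)
    }
  }
  cells <- do.call(rbind, cells)
  fi_long <- do.call(rbind, fi_rows)
  # restrict the RM ANOVA to suprathreshold steps (positive injected current)
  supra <- current_at(protocol, seq_len(protocol$n_sweeps) - 1L) > 0
  fi_long <- fi_long[fi_long$within %in% sprintf("I%03d", which(supra)), ]
  rm_res <- rm_anova_two_way(long_table(fi_long$subject, fi_long$between,
                                        fi_long$within, fi_long$value))
  ok <- !cells$adaptation_excluded
  a_ctrl <- cells$adaptation_ratio[ok & cells$condition == "control"]
  a_mut <- cells$adaptation_ratio[ok & cells$condition == "mutant"]
  ad_t <- if (length(a_ctrl) >= 2L && length(a_mut) >= 2L) {
    two_sample_t(a_ctrl, a_mut)
  } else {
    list(t = NA_real_, df = NA_real_, p = NA_real_, mean_diff = NA_real_,
         note = "fewer than 2 cells per group reached the 16-18-spike window")
  }

  # paired minis of one synthetic cell per genotype
  ei <- lapply(seq_along(groups), function(gi) {
    e_sim <- simulate_minis(event_train_params(rate_hz = 5, polarity = "inward"),
                            seed = seed * 100L + gi)
    i_sim <- simulate_minis(event_train_params(rate_hz = 8, polarity = "outward"),
                            seed = seed * 100L + 50L + gi)
    e_cfg <- cfg$detection
    i_cfg <- detection_config(polarity = "outward",
                              criterion = e_cfg$criterion,
                              min_events = e_cfg$min_events)
    e_ev <- detect_events(e_sim$sweeps, cfg = e_cfg)
    i_ev <- detect_events(i_sim$sweeps, cfg = i_cfg)
    dur <- 120
    ei_ratio(summarize_cell(e_ev, dur, e_cfg, cell_id = names(groups)[gi]),
             summarize_cell(i_ev, dur, i_cfg, cell_id = names(groups)[gi]))
  })
  names(ei) <- names(groups)

  ev_sim <- simulate_evoked(evoked_params(), seed = seed + 7L)
  evoked <- nmda_ampa_ratio(ev_sim$neg70, ev_sim$pos40)

  sim_counts <- simulate_counts(cfg$counts, seed = seed + 13L)
  funnel <- run_funnel(sim_counts$counts, sim_counts$curated_genes,
                       cfg$funnel, seed = seed)

  report <- assemble_report(
    cells[, c("cell_id", "animal_id", "condition", "rheobase_pA",
              "adaptation_ratio")],
    cfg,
    exclusions = if (any(!ok)) data.frame(
      cell_id = cells$cell_id[!ok],
      reason = "no 16-18-spike sweep") else NULL)

  manifest <- list(
    stages = c("simulate", "features", "stats", "funnel"),
    seed = seed,
    n_cells = nrow(cells),
    protocol = unclass(protocol),
    package_version = as.character(utils::packageVersion("epiphys")))
  out <- structure(list(cells = cells, rm_anova = rm_res,
                        adaptation_t = ad_t, ei = ei, evoked = evoked,
                        funnel = funnel, report = report,
                        manifest = manifest),
                   class = "study_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cells, file.path(out_dir, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(rm_anova = rm_res, adaptation_t = ad_t,
           stage_counts = as.list(funnel$stage_counts),
           n_up = funnel$n_up, n_down = funnel$n_down, n_de = funnel$n_de,
           evoked_ratio = evoked$ratio,
           manifest = manifest),
      file.path(out_dir, "study.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    write_count_sim(sim_counts, file.path(out_dir, "counts"))
  }
  out
}
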