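# Data model for episodic patch-clamp recordings: a SweepSet is a sweeps x
# samples block of equally sampled traces (mV in current clamp, pA in voltage
# clamp) plus protocol metadata. On disk a SweepSet is a TSV (one column per
# sweep, one row per sample, no time column) with a JSON sidecar carrying
# mode, dt, holding potential, step protocol and free-form metadata. Time is
# implicit: sample i sits at (i - 1) * dt ms.

#' Square-step stimulation protocol
#'
#' Describes an episodic current-clamp protocol: from a fixed holding
#' potential, each sweep injects a square current step whose amplitude
#' increases linearly with the sweep index. The default values follow the
#' recording convention used throughout this package: 750 ms steps from a
#' -70 mV holding potential, starting at -300 pA with +20 pA increments.
#'
#' @param holding_potential_mV Holding potential between steps (mV).
#' @param step_start_pA Current injected at the first sweep (pA).
#' @param step_increment_pA Increment between consecutive sweeps (pA).
#' @param step_duration_ms Duration of the square step (ms).
#' @param pre_step_ms Baseline recorded before step onset (ms).
#' @param post_step_ms Recording after step offset (ms).
#' @param n_sweeps Number of sweeps (>= 1).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(holding_potential_mV = -70,
                          step_start_pA = -300,
                          step_increment_pA = 20,
                          step_duration_ms = 750,
                          pre_step_ms = 100,
                          post_step_ms = 100,
                          n_sweeps = 40,
                          sampling_rate_hz = 40000) {
  stopifnot(step_duration_ms > 0, sampling_rate_hz > 0, n_sweeps >= 1,
            pre_step_ms >= 0, post_step_ms >= 0)
  structure(list(
    holding_potential_mV = holding_potential_mV,
    step_start_pA = step_start_pA,
    step_increment_pA = step_increment_pA,
    step_duration_ms = step_duration_ms,
    pre_step_ms = pre_step_ms,
    post_step_ms = post_step_ms,
    n_sweeps = as.integer(n_sweeps),
    sampling_rate_hz = sampling_rate_hz
  ), class = "step_protocol")
}

#' Injected current at a given sweep
#'
#' @param protocol A [step_protocol()].
#' @param sweep_index Zero-based sweep index (0 is the first sweep).
#' @return Injected current (pA): `step_start + sweep_index * step_increment`.
#' @export
current_at <- function(protocol, sweep_index) {
  stopifnot(inherits(protocol, "step_protocol"))
  if (any(sweep_index < 0) || any(sweep_index >= protocol$n_sweeps)) {
    stop("sweep_index out of range [0, ", protocol$n_sweeps - 1, "]")
  }
  protocol$step_start_pA + sweep_index * protocol$step_increment_pA
}

#' Construct a sweep set
#'
#' @param data Numeric matrix, sweeps in rows and samples in columns (mV for
#'   current clamp, pA for voltage clamp).
#' @param dt_ms Sampling interval (ms per sample).
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param holding_mV Command holding potential; required for voltage clamp,
#'   must be absent (`NULL`) for current clamp.
#' @param protocol Optional [step_protocol()].
#' @param meta Named list of free-form metadata (cell id, condition label,
#'   experimental day, pharmacology tags, stimulus time, ...).
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(data, dt_ms, mode = c("current_clamp", "voltage_clamp"),
                      holding_mV = NULL, protocol = NULL, meta = list()) {
  mode <- match.arg(mode)
  data <- as.matrix(data)
  if (nrow(data) < 1L || ncol(data) < 1L) stop("sweep set must contain at least one sweep and one sample")
  if (!is.numeric(data)) stop("sweep data must be numeric")
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || dt_ms <= 0) stop("dt_ms must be a positive scalar")
  if (mode == "voltage_clamp" && is.null(holding_mV)) {
    stop("voltage_clamp sweep sets require a holding potential")
  }
  if (mode == "current_clamp" && !is.null(holding_mV)) {
    stop("holding_mV is only meaningful for voltage_clamp sweep sets")
  }
  if (!is.null(protocol)) stopifnot(inherits(protocol, "step_protocol"))
  structure(list(data = data, dt_ms = dt_ms, mode = mode,
                 holding_mV = holding_mV, protocol = protocol, meta = meta),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweep(s) x %d samples, dt = %g ms, %s%s\n",
              nrow(x$data), ncol(x$data), x$dt_ms, x$mode,
              if (!is.null(x$holding_mV)) sprintf(" (Vh %g mV)", x$holding_mV) else ""))
  invisible(x)
}

#' Sample times of a sweep set
#' @param s A [sweep_set()].
#' @return Numeric vector of sample times (ms), starting at 0.
#' @export
sweep_times <- function(s) {
  (seq_len(ncol(s$data)) - 1) * s$dt_ms
}

sidecar_path <- function(path) {
  sub("\\.tsv$", "", path) |> paste0(".json")
}

#' Write a sweep set to a TSV trace file with JSON sidecar
#'
#' The TSV holds one column per sweep (header `sweep_000`, `sweep_001`, ...)
#' and one row per sample; there is no time column. The sidecar
#' `<name>.json` records `mode`, `dt_ms`, `holding_mV`, `protocol` and
#' `meta`. The round trip through [read_sweepset()] is lossless at the
#' written precision (17 significant digits, i.e. exact for doubles).
#'
#' @param s A [sweep_set()].
#' @param path Path of the `.tsv` file to write.
#' @return Invisibly, `path`.
#' @export
write_sweepset <- function(s, path) {
  stopifnot(inherits(s, "sweep_set"))
  mat <- t(s$data)  # samples x sweeps on disk
  colnames(mat) <- sprintf("sweep_%03d", seq_len(nrow(s$data)) - 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(mat), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r) paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  writeLines(body, con)
  side <- list(mode = s$mode, dt_ms = s$dt_ms,
               holding_mV = s$holding_mV,
               protocol = if (is.null(s$protocol)) NULL else unclass(s$protocol),
               meta = s$meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a sweep set written by [write_sweepset()]
#'
#' @param path Path of the `.tsv` trace file; the `.json` sidecar must sit
#'   next to it.
#' @return A [sweep_set()].
#' @export
read_sweepset <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing JSON sidecar: ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(side$mode) || !side$mode %in% c("current_clamp", "voltage_clamp")) {
    stop("sidecar declares unknown recording mode: ", side$mode)
  }
  lines <- readLines(path)
  if (length(lines) < 2L) stop("trace file has no samples: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != length(header))) stop("ragged sweep lengths in ", path)
  mat <- matrix(as.numeric(unlist(rows, use.names = FALSE)),
                nrow = length(rows), ncol = length(header), byrow = TRUE)
  proto <- NULL
  if (!is.null(side$protocol)) {
    proto <- do.call(step_protocol, side$protocol)
  }
  sweep_set(t(mat), dt_ms = side$dt_ms, mode = side$mode,
            holding_mV = side$holding_mV,
            protocol = proto,
            meta = if (is.null(side$meta)) list() else as.list(side$meta))
}

#' Recording metadata constructor
#'
#' @param cell_id,animal_id Identifiers.
#' @param condition One of `"Cre-"`, `"Cre+d4"`, `"Cre+d6"`, `"Cre+d8"`,
#'   `"Cre+d12"`, `"Cre+Rap4"`, `"Cre+Rap8"` (genotype x experimental day,
#'   with rapamycin-treated arms).
#' @param pharmacology Character vector of bath-application tags
#'   (e.g. `"TTX"`, `"CNQX"`, `"bicuculline"`).
#' @param rs_stable Logical series-resistance quality flag (raw Rs traces are
#'   not part of the data model; stability below 20 MOhm is recorded as
#'   metadata only).
#' @return Named list usable as the `meta` field of a [sweep_set()].
#' @export
recording_metadata <- function(cell_id, animal_id = NA_character_,
                               condition = c("Cre-", "Cre+d4", "Cre+d6", "Cre+d8",
                                             "Cre+d12", "Cre+Rap4", "Cre+Rap8"),
                               pharmacology = character(), rs_stable = TRUE) {
  condition <- match.arg(condition)
  list(cell_id = cell_id, animal_id = animal_id, condition = condition,
       pharmacology = pharmacology, rs_stable = rs_stable)
}
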