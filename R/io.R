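#' File interfaces
#'
#' Sweeps travel as plain CSV (`time_s`, `signal`) with one JSON sidecar
#' per protocol carrying stimulus metadata, clamp mode and sampling rate;
#' feature tables are CSV with full-precision numerics so that write/read
#' round-trips are bit-exact.
#'
#' @name io
NULL

#' Write a cohort feature table
#'
#' Numeric fields are serialised with 17 significant digits (bit-exact
#' round trip); missing features are written as explicit `NA`.
#'
#' @param records a data frame of per-cell features.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  df <- as.data.frame(records)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), NA_character_,
                        sprintf("%.17g", df[[j]]))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a cohort feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data frame of class `px_features`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  char_cols <- c("cell_id", "group", "treatment")
  for (j in names(df)) {
    if (j %in% char_cols) next
    v <- df[[j]]
    if (is.logical(v)) next
    if (all(is.na(v) | v %in% c("TRUE", "FALSE"))) df[[j]] <- as.logical(v)
    else df[[j]] <- as.numeric(v)
  }
  class(df) <- c("px_features", "data.frame")
  df
}

#' Write one protocol recording as CSV sweeps plus a JSON sidecar
#'
#' Layout: `<dir>/<cell>/<protocol>_sweep<k>.csv` with columns `time_s`,
#' `signal`, and `<dir>/<cell>/<protocol>.json` describing clamp mode,
#' sampling rate, holding level and per-sweep stimuli.
#'
#' @param rec a [protocol_recording()].
#' @param dir cohort directory.
#' @return the cell directory, invisibly.
#' @export
write_recording <- function(rec, dir) {
  cd <- file.path(dir, rec$cell_id)
  dir.create(cd, recursive = TRUE, showWarnings = FALSE)
  meta <- list(protocol = rec$kind, cell_id = rec$cell_id, group = rec$group,
               treatment = rec$treatment,
               clamp_mode = if (length(rec$sweeps)) rec$sweeps[[1]]$mode else NA,
               sampling_rate = if (length(rec$sweeps)) rec$sweeps[[1]]$rate else NA,
               holding = if (length(rec$sweeps)) rec$sweeps[[1]]$holding else NA,
               n_sweeps = length(rec$sweeps),
               stimuli = lapply(rec$sweeps, function(s)
                 if (is.null(s$stim)) NULL else unclass(s$stim)))
  jsonlite::write_json(meta, file.path(cd, paste0(rec$kind, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  for (k in seq_along(rec$sweeps)) {
    s <- rec$sweeps[[k]]
    utils::write.csv(data.frame(time_s = sprintf("%.9f", s$t),
                                signal = sprintf("%.9g", s$y)),
                     file.path(cd, sprintf("%s_sweep%03d.csv", rec$kind, k)),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(cd)
}

#' Read one protocol recording from the CSV/JSON layout
#'
#' @param cell_dir directory of one cell.
#' @param kind protocol kind.
#' @return a [protocol_recording()].
#' @export
read_recording <- function(cell_dir, kind) {
  jf <- file.path(cell_dir, paste0(kind, ".json"))
  if (!file.exists(jf)) stop("no sidecar for protocol ", kind, " in ", cell_dir)
  meta <- jsonlite::read_json(jf, simplifyVector = FALSE)
  files <- sort(list.files(cell_dir, sprintf("^%s_sweep[0-9]+\\.csv$", kind),
                           full.names = TRUE))
  sweeps <- lapply(seq_along(files), function(k) {
    d <- utils::read.csv(files[k])
    st <- meta$stimuli[[k]]
    stim <- if (is.null(st)) NULL else
      step_stimulus(st$onset, st$duration, st$amplitude,
                    pulse_width = st$pulse_width, n_pulses = st$n_pulses,
                    frequency = st$frequency)
    sweep_ts(d$time_s, d$signal, meta$sampling_rate[[1]], meta$clamp_mode[[1]],
             stim,
             holding = if (is.null(meta$holding)) NA_real_ else meta$holding[[1]])
  })
  as_chr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  protocol_recording(kind, sweeps, cell_id = as_chr(meta$cell_id),
                     group = as_chr(meta$group),
                     treatment = as_chr(meta$treatment))
}

#' Read every protocol of one cell directory
#'
#' @param cell_dir directory of one cell.
#' @return named list of [protocol_recording()] objects.
#' @export
read_cell_dir <- function(cell_dir) {
  kinds <- sub("\\.json$", "", list.files(cell_dir, "\\.json$"))
  kinds <- intersect(kinds, PROTOCOL_KINDS)
  stats::setNames(lapply(kinds, function(k) read_recording(cell_dir, k)), kinds)
}

#' Write a whole cohort in the CSV/JSON sweep layout
#'
#' Also writes `ground_truth.csv` when the cohort carries generator truth.
#'
#' @param cohort a `px_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in cohort$cells)
    for (rec in b$recordings) write_recording(rec, dir)
  if (!is.null(cohort$ground_truth))
    write_feature_table(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Reader hooks for acquisition-native formats
#'
#' Interface points for Axon Binary Format and Neurodata Without Borders
#' sweep files.  Conversion to the CSV/JSON layout is expected upstream;
#' these hooks exist so a binding can be dropped in without touching the
#' pipeline.
#'
#' @param path input file.
#' @return never returns; raises a not-implemented error.
#' @export
read_abf <- function(path) {
  stop("ABF reading is an interface hook only; convert sweeps to the ",
       "CSV/JSON layout (see write_recording)")
}

#' @rdname read_abf
#' @export
read_nwb <- function(path) {
  stop("NWB reading is an interface hook only; convert sweeps to the ",
       "CSV/JSON layout (see write_recording)")
}
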