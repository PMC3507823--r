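#' CSV schemas used by the pipeline
#'
#' Named list mapping schema name to required column names and types. All
#' event times are stored in ms (3 decimals) signed relative to projected
#' collision.
#'
#' @export
loomglide_schemas <- list(
  stimuli = c(stim_id = "character", half_size_m = "numeric",
              speed_m_s = "numeric", start_m = "numeric", end_m = "numeric",
              wing_span_m = "numeric", wing_height_m = "numeric",
              wing_offset_m = "numeric"),
  tracks = c(kite_id = "character", attack_id = "character",
             segment_id = "character", frame = "numeric",
             x_px = "numeric", y_px = "numeric"),
  spikes = c(individual_id = "character", stim_id = "character",
             presentation = "numeric", t_ms = "numeric"),
  wingbeats = c(individual_id = "character", stim_id = "character",
                presentation = "numeric", t_ms = "numeric",
                valid_flight = "logical"),
  glides = c(individual_id = "character", stim_id = "character",
             presentation = "numeric", onset_ms = "numeric",
             gap_ms = "numeric", before_collision = "logical"),
  frame_schedule = c(frame = "numeric", t_to_collision_s = "numeric",
                     theta_deg = "numeric", radius_px = "numeric",
                     wing_w_px = "numeric", wing_h_px = "numeric",
                     clipped = "logical")
)

#' Read and validate a pipeline CSV
#'
#' Checks the header against the named schema, coerces and checks column
#' types, and (for event tables) checks that times are strictly increasing
#' within each individual x stimulus x presentation group. Errors name the
#' offending column and data row. An empty file with a valid header yields an
#' empty table, not an error.
#'
#' @param path CSV file path.
#' @param schema One of `names(loomglide_schemas)`.
#' @return A validated data frame.
#' @export
read_table_checked <- function(path, schema) {
  if (!schema %in% names(loomglide_schemas))
    stop("unknown schema '", schema, "'", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- loomglide_schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(spec), names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- df[names(spec)]
  for (col in names(spec)) {
    if (spec[[col]] == "numeric") {
      v <- df[[col]]
      if (is.character(v)) {
        suppressWarnings(vn <- as.numeric(v))
        bad <- which(is.na(vn) & !is.na(v) & nzchar(v))
        if (length(bad))
          stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                       path, col, bad[1]), call. = FALSE)
        df[[col]] <- vn
      }
    } else if (spec[[col]] == "logical") {
      df[[col]] <- as.logical(df[[col]])
      if (anyNA(df[[col]]) && nrow(df))
        stop(sprintf("%s: non-logical value in column '%s'", path, col),
             call. = FALSE)
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  time_col <- switch(schema, spikes = "t_ms", wingbeats = "t_ms", NULL)
  if (!is.null(time_col) && nrow(df) > 1L) {
    key <- paste(df$individual_id, df$stim_id, df$presentation, sep = "\r")
    for (k in unique(key)) {
      tt <- df[[time_col]][key == k]
      if (length(tt) > 1L && any(diff(tt) <= 0)) {
        bad <- which(key == k)[which(diff(tt) <= 0)[1] + 1L]
        stop(sprintf("%s: column '%s' not strictly increasing at data row %d",
                     path, time_col, bad), call. = FALSE)
      }
    }
  }
  df
}

write_table_ms <- function(df, path, ms_cols = intersect(names(df),
                                                         c("t_ms", "onset_ms", "gap_ms"))) {
  for (col in ms_cols) df[[col]] <- round(df[[col]], 3)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

stimuli_to_df <- function(stimuli) {
  do.call(rbind, lapply(stimuli, function(s) data.frame(
    stim_id = s$stim_id, half_size_m = s$half_size, speed_m_s = s$speed,
    start_m = s$start_distance, end_m = s$end_distance,
    wing_span_m = if (is.null(s$wing)) NA_real_ else s$wing$span,
    wing_height_m = if (is.null(s$wing)) NA_real_ else s$wing$bar_height,
    wing_offset_m = if (is.null(s$wing)) NA_real_ else s$wing$vertical_offset,
    stringsAsFactors = FALSE)))
}

#' Write stimulus definitions to CSV
#'
#' @param stimuli List of [looming_stimulus()] objects.
#' @param path Output CSV path. Empty wing columns mean no wing.
#' @export
write_stimuli <- function(stimuli, path) {
  utils::write.csv(stimuli_to_df(stimuli), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read stimulus definitions from CSV
#'
#' @param path CSV with the `stimuli` schema.
#' @return A list of [looming_stimulus()] objects.
#' @export
read_stimuli <- function(path) {
  df <- read_table_checked(path, "stimuli")
  lapply(seq_len(nrow(df)), function(i) {
    wing <- if (is.na(df$wing_span_m[i])) NULL else
      wing_spec(df$wing_span_m[i], df$wing_height_m[i], df$wing_offset_m[i])
    looming_stimulus(df$half_size_m[i], df$speed_m_s[i], df$start_m[i],
                     df$end_m[i], wing = wing, stim_id = df$stim_id[i])
  })
}

#' Read digitized tracks from CSV
#'
#' @param path CSV with the `tracks` schema.
#' @param cal_len_px,cal_len_m Calibration pair applied to every segment.
#' @param fps Frame rate. Default 25.
#' @return A list of [track_segment()] objects (one per kite x attack x
#'   segment).
#' @export
read_tracks <- function(path, cal_len_px, cal_len_m, fps = 25) {
  df <- read_table_checked(path, "tracks")
  key <- paste(df$kite_id, df$attack_id, df$segment_id, sep = "\r")
  lapply(unique(key), function(k) {
    d <- df[key == k, ]
    track_segment(d$frame, d$x_px, d$y_px, fps = fps,
                  cal_len_px = cal_len_px, cal_len_m = cal_len_m,
                  kite_id = d$kite_id[1], attack_id = d$attack_id[1],
                  segment_id = d$segment_id[1])
  })
}

#' Write track segments to CSV
#' @param segments List of [track_segment()] objects.
#' @param path Output CSV path.
#' @export
write_tracks <- function(segments, path) {
  df <- do.call(rbind, lapply(segments, function(s) data.frame(
    kite_id = s$kite_id, attack_id = s$attack_id, segment_id = s$segment_id,
    frame = s$frame, x_px = s$x_px, y_px = s$y_px, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#' @param path CSV with the `spikes` schema.
#' @return A list of [spike_train()] objects.
#' @export
read_spikes <- function(path) {
  df <- read_table_checked(path, "spikes")
  split_trains(df, function(d)
    spike_train(d$t_ms, d$individual_id[1], d$stim_id[1], d$presentation[1]))
}

#' Read wingbeat trains from CSV
#' @param path CSV with the `wingbeats` schema.
#' @return A list of [wingbeat_train()] objects.
#' @export
read_wingbeats <- function(path) {
  df <- read_table_checked(path, "wingbeats")
  split_trains(df, function(d)
    wingbeat_train(d$t_ms, d$individual_id[1], d$stim_id[1], d$presentation[1],
                   all(d$valid_flight)))
}

split_trains <- function(df, build) {
  if (nrow(df) == 0L) return(list())
  key <- paste(df$individual_id, df$stim_id, df$presentation, sep = "\r")
  lapply(unique(key), function(k) build(df[key == k, ]))
}

#' Write spike trains (or a spikes data frame) to CSV
#' @param x List of [spike_train()] or a data frame with the `spikes` schema.
#' @param path Output CSV path.
#' @export
write_spikes <- function(x, path) {
  if (!is.data.frame(x))
    x <- do.call(rbind, lapply(x, function(tr) data.frame(
      individual_id = tr$individual_id, stim_id = tr$stim_id,
      presentation = tr$presentation, t_ms = tr$t_ms, stringsAsFactors = FALSE)))
  write_table_ms(x, path)
}

#' Write wingbeat trains (or a wingbeats data frame) to CSV
#' @param x List of [wingbeat_train()] or a data frame with the `wingbeats`
#'   schema.
#' @param path Output CSV path.
#' @export
write_wingbeats <- function(x, path) {
  if (!is.data.frame(x))
    x <- do.call(rbind, lapply(x, function(tr) data.frame(
      individual_id = tr$individual_id, stim_id = tr$stim_id,
      presentation = tr$presentation, t_ms = tr$t_ms,
      valid_flight = tr$valid_flight, stringsAsFactors = FALSE)))
  write_table_ms(x, path)
}

#' Write a synthetic battery to a directory
#'
#' Emits `spikes.csv`, `wingbeats.csv` and `stimuli.csv` (plus
#' `presentation_order.csv`) in the pipeline schemas.
#'
#' @param battery A [scenario_battery()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_battery <- function(battery, dir) {
  stopifnot(inherits(battery, "loom_battery"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spikes(battery$spikes, file.path(dir, "spikes.csv"))
  write_wingbeats(battery$wingbeats, file.path(dir, "wingbeats.csv"))
  utils::write.csv(battery$stimuli, file.path(dir, "stimuli.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(battery$presentation_order,
                   file.path(dir, "presentation_order.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
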