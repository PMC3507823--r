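#' Digitized predator track segment
#'
#' One analysable stretch of a predator attack digitized from video: beak
#' positions in pixels at known frame indices, plus the calibration pair that
#' converts pixels to metres. Frame indices may skip frames; elapsed time is
#' divided accordingly when speeds are computed.
#'
#' @param frame Integer frame indices, strictly increasing, length >= 2.
#' @param x_px,y_px Pixel coordinates, same length as `frame`.
#' @param fps Frame rate of the footage in Hz. Default 25.
#' @param cal_len_px,cal_len_m Calibration pair: a feature of known physical
#'   length measured in pixels and metres (e.g. mean predator body length).
#' @param kite_id,attack_id,segment_id Labels placing the segment in the
#'   individual > attack > segment hierarchy.
#' @return An object of class `track_segment`.
#' @export
#' @examples
#' track_segment(1:5, seq(0, 40, 10), rep(0, 5),
#'               cal_len_px = 69.5, cal_len_m = 0.56)
track_segment <- function(frame, x_px, y_px, fps = 25,
                          cal_len_px, cal_len_m,
                          kite_id = "k1", attack_id = "a1", segment_id = "s1") {
  frame <- as.numeric(frame)
  if (length(frame) < 2L) stop("a track segment needs >= 2 samples", call. = FALSE)
  if (length(x_px) != length(frame) || length(y_px) != length(frame))
    stop("'frame', 'x_px' and 'y_px' must have equal length", call. = FALSE)
  if (anyDuplicated(frame)) stop("duplicate frame index in track segment", call. = FALSE)
  if (is.unsorted(frame, strictly = TRUE))
    stop("'frame' must be strictly increasing", call. = FALSE)
  if (fps <= 0) stop("'fps' must be > 0", call. = FALSE)
  scale <- calibration_scale(cal_len_px, cal_len_m)
  structure(list(frame = frame, x_px = as.numeric(x_px), y_px = as.numeric(y_px),
                 fps = fps, cal_len_px = cal_len_px, cal_len_m = cal_len_m,
                 scale_m_per_px = scale, kite_id = as.character(kite_id),
                 attack_id = as.character(attack_id),
                 segment_id = as.character(segment_id)),
            class = "track_segment")
}

#' Pixel-to-metre calibration scale
#'
#' @param length_px Length of a reference feature in pixels (> 0).
#' @param length_m The same length in metres (> 0).
#' @return Scale in metres per pixel.
#' @export
#' @examples
#' calibration_scale(69.5, 0.56)  # mean kite length in frame vs published
calibration_scale <- function(length_px, length_m) {
  if (!is.finite(length_px) || length_px <= 0)
    stop("'length_px' must be positive", call. = FALSE)
  if (!is.finite(length_m) || length_m <= 0)
    stop("'length_m' must be positive", call. = FALSE)
  length_m / length_px
}

#' Per-frame speed estimates along a track segment
#'
#' Speed between consecutive digitized positions:
#' `euclidean pixel distance * scale * fps / frame gap`. Returns one value per
#' consecutive pair (length `n - 1`). The result carries a `smoothed = FALSE`
#' provenance flag; only [smooth_for_display()] may set it, and
#' [hierarchical_mean()] never consumes smoothed values.
#'
#' @param segment A [track_segment()].
#' @return Numeric vector of speeds (m/s) with attributes `smoothed` and
#'   `t_s` (time of the later frame of each pair, seconds).
#' @export
frame_speeds <- function(segment) {
  stopifnot(inherits(segment, "track_segment"))
  gap <- diff(segment$frame)
  disp_px <- sqrt(diff(segment$x_px)^2 + diff(segment$y_px)^2)
  speeds <- disp_px * segment$scale_m_per_px * segment$fps / gap
  attr(speeds, "smoothed") <- FALSE
  attr(speeds, "t_s") <- segment$frame[-1] / segment$fps
  speeds
}

#' Three-point smoothing for display only
#'
#' Centred mean over each value and its two neighbours; endpoints pass through
#' unchanged. Intended for plotting only: the output is flagged
#' `smoothed = TRUE` and is rejected by the averaging pipeline, mirroring the
#' practice of quoting unsmoothed means.
#'
#' @param speeds Numeric vector of length >= 3.
#' @return Smoothed vector with attribute `smoothed = TRUE`.
#' @export
#' @examples
#' smooth_for_display(c(1, 4, 1))  # 1 2 1
smooth_for_display <- function(speeds) {
  n <- length(speeds)
  if (n < 3L) stop("need >= 3 values to smooth", call. = FALSE)
  out <- speeds
  mid <- 2:(n - 1)
  out[mid] <- (speeds[mid - 1] + speeds[mid] + speeds[mid + 1]) / 3
  attributes(out) <- NULL
  attr(out, "smoothed") <- TRUE
  out
}

#' Hierarchical speed summary (segment -> attack -> individual)
#'
#' Averages per-frame speeds up the sampling hierarchy with unweighted means
#' at every level, so that repeated measures of one individual cannot inflate
#' the sample: segment means average frames, attack means average segments,
#' individual (kite) means average attacks, and the grand mean and sample SD
#' are computed across individuals only.
#'
#' @param segments A list of [track_segment()] objects.
#' @param trim_s Keep only per-frame speeds within the final `trim_s` seconds
#'   of each attack (measured against the latest frame in that attack) before
#'   averaging. Default 1.25; use `Inf` for no trim.
#' @return An object of class `speed_summary`: data frames `segments`,
#'   `attacks`, `kites` with their level means, plus `grand_mean`, `grand_sd`
#'   (sample SD across kites, `NA` for a single kite) and `n_kites`.
#' @export
hierarchical_mean <- function(segments, trim_s = 1.25) {
  if (length(segments) == 0L) stop("no track segments supplied", call. = FALSE)
  stopifnot(all(vapply(segments, inherits, TRUE, "track_segment")))
  if (!is.numeric(trim_s) || trim_s <= 0) stop("'trim_s' must be > 0", call. = FALSE)

  kite <- vapply(segments, `[[`, "", "kite_id")
  attack <- vapply(segments, `[[`, "", "attack_id")
  seg_id <- vapply(segments, `[[`, "", "segment_id")
  sp <- lapply(segments, frame_speeds)
  ts <- lapply(sp, attr, "t_s")

  akey <- paste(kite, attack, sep = "\r")
  t_end <- tapply(vapply(ts, max, 0), akey, max)

  seg_mean <- vapply(seq_along(segments), function(i) {
    keep <- ts[[i]] >= t_end[[akey[i]]] - trim_s
    if (!any(keep)) keep <- seq_along(sp[[i]]) == length(sp[[i]])
    mean(sp[[i]][keep])
  }, 0)

  seg_df <- data.frame(kite_id = kite, attack_id = attack, segment_id = seg_id,
                       mean_speed = seg_mean, stringsAsFactors = FALSE)
  att_mean <- tapply(seg_df$mean_speed, akey, mean)
  att_df <- data.frame(
    kite_id = vapply(strsplit(names(att_mean), "\r"), `[[`, "", 1L),
    attack_id = vapply(strsplit(names(att_mean), "\r"), `[[`, "", 2L),
    mean_speed = as.numeric(att_mean), stringsAsFactors = FALSE)
  kite_mean <- tapply(att_df$mean_speed, att_df$kite_id, mean)
  kite_df <- data.frame(kite_id = names(kite_mean),
                        mean_speed = as.numeric(kite_mean),
                        stringsAsFactors = FALSE)

  structure(list(segments = seg_df, attacks = att_df, kites = kite_df,
                 grand_mean = mean(kite_df$mean_speed),
                 grand_sd = if (nrow(kite_df) > 1) stats::sd(kite_df$mean_speed)
                            else NA_real_,
                 n_kites = nrow(kite_df), trim_s = trim_s),
            class = "speed_summary")
}

#' @export
print.speed_summary <- function(x, ...) {
  cat(sprintf("Attack speeds: %.2f +/- %.2f m/s (mean +/- SD across N = %d individuals)\n",
              x$grand_mean, x$grand_sd, x$n_kites))
  cat(sprintf("  %d attacks, %d segments; trim = %g s\n",
              nrow(x$attacks), nrow(x$segments), x$trim_s))
  invisible(x)
}
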