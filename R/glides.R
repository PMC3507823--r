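#' Wingbeat sensor event train for one presentation
#'
#' Times (ms, signed relative to projected collision) at which a wing crossed
#' the sensor line. Presentations in which the animal did not fly strongly are
#' flagged `valid_flight = FALSE` and excluded from all summaries.
#'
#' @param t_ms Strictly increasing event times in ms.
#' @param individual_id,stim_id Labels.
#' @param presentation Presentation number.
#' @param valid_flight Logical flag; default `TRUE`.
#' @return An object of class `wingbeat_train`.
#' @export
wingbeat_train <- function(t_ms, individual_id = "ind1", stim_id = NA_character_,
                           presentation = 1L, valid_flight = TRUE) {
  t_ms <- as.numeric(t_ms)
  if (any(!is.finite(t_ms))) stop("wingbeat times must be finite", call. = FALSE)
  if (length(t_ms) > 1L && any(diff(t_ms) <= 0))
    stop("wingbeat times must be strictly increasing", call. = FALSE)
  structure(list(t_ms = t_ms, individual_id = as.character(individual_id),
                 stim_id = as.character(stim_id),
                 presentation = as.integer(presentation),
                 valid_flight = isTRUE(valid_flight)),
            class = "wingbeat_train")
}

#' Intervals between consecutive wingbeats
#'
#' @param train A [wingbeat_train()].
#' @return Numeric vector of `n - 1` interval durations (ms); empty for fewer
#'   than two events.
#' @export
wingbeat_intervals <- function(train) {
  stopifnot(inherits(train, "wingbeat_train"))
  if (length(train$t_ms) < 2L) return(numeric())
  diff(train$t_ms)
}

#' Detect glides in a wingbeat train
#'
#' A glide is a pause between consecutive wingbeats longer than `k` times the
#' mean duration of the preceding `n_history` wingbeat intervals. The first
#' `n_history` intervals are ineligible (the rule needs a full history;
#' animals fly before stimulus onset, so this burn-in is benign). After a
#' detected glide the history buffer is reset and must refill before another
#' detection, so the long glide interval cannot inflate the baseline. Glide
#' onset is the time of the last wingbeat event preceding the gap.
#'
#' @param train A [wingbeat_train()].
#' @param k Threshold multiplier (> 1). Default 1.25.
#' @param n_history Number of preceding intervals averaged (>= 1). Default 10.
#' @return A data frame of class `glide_events` with columns `onset_ms`,
#'   `gap_ms`, `threshold_ms` (the k * mean history that was exceeded) and
#'   `before_collision` (strictly `onset_ms < 0`). Zero rows when no glide.
#' @export
#' @examples
#' beats <- c(seq(0, 500, by = 50), 570)  # ten 50 ms beats then a 70 ms gap
#' detect_glides(wingbeat_train(beats))
detect_glides <- function(train, k = 1.25, n_history = 10) {
  stopifnot(inherits(train, "wingbeat_train"))
  if (!is.numeric(k) || k <= 1) stop("'k' must be > 1", call. = FALSE)
  if (!is.numeric(n_history) || n_history < 1)
    stop("'n_history' must be >= 1", call. = FALSE)
  ev <- train$t_ms
  iv <- if (length(ev) >= 2L) diff(ev) else numeric()
  onset <- gap <- thr <- numeric()
  hist_buf <- numeric()
  for (i in seq_along(iv)) {
    if (length(hist_buf) >= n_history) {
      threshold <- k * mean(hist_buf[(length(hist_buf) - n_history + 1):length(hist_buf)])
      if (iv[i] > threshold) {
        onset <- c(onset, ev[i])
        gap <- c(gap, iv[i])
        thr <- c(thr, threshold)
        hist_buf <- numeric()  # refill before the next detection
        next
      }
    }
    hist_buf <- c(hist_buf, iv[i])
  }
  out <- data.frame(onset_ms = onset, gap_ms = gap, threshold_ms = thr,
                    before_collision = onset < 0)
  class(out) <- c("glide_events", "data.frame")
  attr(out, "k") <- k
  attr(out, "n_history") <- n_history
  out
}

#' Classify a glide onset against the projected collision
#'
#' A glide counts as initiated before collision only when its onset is
#' strictly negative on the collision-referenced axis (onset exactly at
#' collision is "not before"). When a stimulus is supplied, its identity must
#' match the train the glide came from; this guards against mixing time
#' references.
#'
#' @param onset_ms Glide onset in ms relative to projected collision.
#' @param stim Optional [looming_stimulus()] whose `stim_id` must equal
#'   `stim_id`.
#' @param stim_id Optional stimulus label carried by the glide's train.
#' @return Logical: initiated before collision?
#' @export
glide_before_collision <- function(onset_ms, stim = NULL, stim_id = NULL) {
  if (!is.null(stim)) {
    stopifnot(inherits(stim, "looming_stimulus"))
    if (!is.null(stim_id) && !is.na(stim_id) && !identical(stim$stim_id, stim_id))
      stop(sprintf("stimulus reference mismatch: glide from '%s', stimulus '%s'",
                   stim_id, stim$stim_id), call. = FALSE)
  }
  onset_ms < 0
}

#' Drop presentations without strong flight
#'
#' @param trains List of [wingbeat_train()] objects.
#' @return The subset with `valid_flight = TRUE`; the number excluded is
#'   reported via `message()` and attached as attribute `n_excluded`.
#' @export
exclude_weak_flight <- function(trains) {
  stopifnot(all(vapply(trains, inherits, TRUE, "wingbeat_train")))
  keep <- vapply(trains, `[[`, TRUE, "valid_flight")
  if (any(!keep))
    message(sprintf("excluded %d presentation(s) without strong flight", sum(!keep)))
  out <- trains[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Glide occurrence and timing summary
#'
#' Per-individual glide metrics for one stimulus, aggregated with
#' [group_summary()]:
#' occurrence (presentations with at least one glide / valid presentations),
#' the proportion of glides initiated before collision (computed over
#' individuals that glided at least once -- individuals with no glides are
#' excluded from this metric, not scored 0), the proportion of presentations
#' with a pre-collision glide, and the mean glide onset. By default only the
#' first glide of each presentation enters timing and proportion metrics.
#'
#' @param trains List of [wingbeat_train()] objects for one stimulus (several
#'   individuals, several presentations). Invalid-flight presentations are
#'   excluded first.
#' @param k,n_history Glide detection parameters, see [detect_glides()].
#' @param first_glide_only If `TRUE` (default) only the first glide per
#'   presentation is used for the timing metrics.
#' @return An object of class `glide_summary`: `per_individual` data frame and
#'   group-level `occurrence`, `before_given_glide`, `preglide_per_presentation`,
#'   `mean_onset_ms` (each a [group_summary()] list).
#' @export
glide_proportions <- function(trains, k = 1.25, n_history = 10,
                              first_glide_only = TRUE) {
  trains <- exclude_weak_flight(trains)
  if (length(trains) == 0L)
    stop("no valid presentations to summarise", call. = FALSE)
  ids <- vapply(trains, `[[`, "", "individual_id")

  per_ind <- lapply(unique(ids), function(id) {
    trs <- trains[ids == id]
    g <- lapply(trs, detect_glides, k = k, n_history = n_history)
    if (first_glide_only) g <- lapply(g, utils::head, 1L)
    has_glide <- vapply(g, nrow, 0L) > 0L
    onsets <- unlist(lapply(g, `[[`, "onset_ms"))
    before <- unlist(lapply(g, `[[`, "before_collision"))
    pre_per_pres <- vapply(g, function(gi)
      nrow(gi) > 0L && any(gi$before_collision), TRUE)
    data.frame(
      individual_id = id,
      n_presentations = length(trs),
      n_glide_presentations = sum(has_glide),
      occurrence = mean(has_glide),
      prop_before_given_glide = if (length(before)) mean(before) else NA_real_,
      prop_presentations_preglide = mean(pre_per_pres),
      mean_onset_ms = if (length(onsets)) mean(onsets) else NA_real_,
      stringsAsFactors = FALSE)
  })
  per_ind <- do.call(rbind, per_ind)

  structure(list(
    per_individual = per_ind,
    occurrence = group_summary(per_ind$occurrence),
    before_given_glide = if (all(is.na(per_ind$prop_before_given_glide))) NULL
      else group_summary(per_ind$prop_before_given_glide),
    preglide_per_presentation = group_summary(per_ind$prop_presentations_preglide),
    mean_onset_ms = if (all(is.na(per_ind$mean_onset_ms))) NULL
      else group_summary(per_ind$mean_onset_ms),
    k = k, n_history = n_history, first_glide_only = first_glide_only),
    class = "glide_summary")
}

#' @export
print.glide_summary <- function(x, ...) {
  cat(sprintf("Glide summary over %d individuals:\n", nrow(x$per_individual)))
  cat(sprintf("  occurrence: %.3f +/- %.3f (SEM, n = %d)\n",
              x$occurrence$mean, x$occurrence$sem, x$occurrence$n))
  if (!is.null(x$before_given_glide))
    cat(sprintf("  before collision | glide: %.3f +/- %.3f (n = %d gliders)\n",
                x$before_given_glide$mean, x$before_given_glide$sem,
                x$before_given_glide$n))
  if (!is.null(x$mean_onset_ms))
    cat(sprintf("  mean onset: %.1f ms relative to collision\n",
                x$mean_onset_ms$mean))
  invisible(x)
}
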