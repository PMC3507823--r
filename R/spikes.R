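#' Spike train for one stimulus presentation
#'
#' Spike event times in milliseconds, signed relative to the projected time of
#' collision (negative = before collision). Times must be strictly increasing;
#' duplicates are rejected.
#'
#' @param t_ms Numeric vector of spike times (ms, signed).
#' @param individual_id,stim_id Labels.
#' @param presentation Presentation number within individual x stimulus.
#' @return An object of class `spike_train`.
#' @export
#' @examples
#' spike_train(c(-120, -80, -41, -40.2, -12))
spike_train <- function(t_ms, individual_id = "ind1", stim_id = NA_character_,
                        presentation = 1L) {
  t_ms <- as.numeric(t_ms)
  if (any(!is.finite(t_ms))) stop("spike times must be finite", call. = FALSE)
  if (length(t_ms) > 1L && any(diff(t_ms) <= 0))
    stop("spike times must be strictly increasing (duplicates rejected)",
         call. = FALSE)
  structure(list(t_ms = t_ms, individual_id = as.character(individual_id),
                 stim_id = as.character(stim_id),
                 presentation = as.integer(presentation)),
            class = "spike_train")
}

#' Construct a rate series directly
#'
#' @param t Times in ms (signed relative to projected collision), increasing.
#' @param rate Non-negative rates in Hz, same length as `t`.
#' @param window_ms Window annotation, if the series came from a windowed
#'   estimate.
#' @return A data frame of class `rate_series`.
#' @export
rate_series <- function(t, rate, window_ms = NA_real_) {
  if (length(t) != length(rate)) stop("'t' and 'rate' lengths differ", call. = FALSE)
  if (length(t) > 1L && is.unsorted(t)) stop("'t' must be increasing", call. = FALSE)
  if (any(rate < 0)) stop("rates must be >= 0", call. = FALSE)
  out <- data.frame(t = as.numeric(t), rate = as.numeric(rate))
  class(out) <- c("rate_series", "data.frame")
  attr(out, "window_ms") <- window_ms
  out
}

#' Windowed spike rate computed at each spike event
#'
#' At each spike time t the rate is the number of spikes in the half-open
#' window (t - window_ms, t], divided by the window duration. The anchoring
#' spike itself is counted, so every spike event has a nonzero rate; this
#' inclusive convention adds a bias of exactly 1/window (40 Hz for the default
#' 25 ms window) to the expected rate of a homogeneous train, which is
#' documented and tested rather than hidden. 25 ms is one half wingbeat.
#'
#' @param train A [spike_train()].
#' @param window_ms Averaging window in ms (> 0). Default 25.
#' @return A [rate_series()] with one point per spike; empty train gives an
#'   empty series. Attribute `inclusive = TRUE` records the convention.
#' @export
#' @examples
#' rate_at_spikes(spike_train(seq(-100, 0, by = 5)))  # steady 200 Hz train
rate_at_spikes <- function(train, window_ms = 25) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(window_ms) || window_ms <= 0)
    stop("'window_ms' must be > 0", call. = FALSE)
  t <- train$t_ms
  n <- length(t)
  if (n == 0L) {
    out <- rate_series(numeric(), numeric(), window_ms)
    attr(out, "inclusive") <- TRUE
    return(out)
  }
  # spikes are sorted: count via two binary searches per spike
  lo <- findInterval(t - window_ms, t)        # spikes at or before t - w (excluded)
  counts <- seq_len(n) - lo
  out <- rate_series(t, counts / (window_ms / 1000), window_ms)
  attr(out, "inclusive") <- TRUE
  out
}

#' Peak of a rate series
#'
#' Maximum rate and the time at which it occurs; ties are broken toward the
#' latest time (closest to collision), a conservative choice when comparing
#' "peak occurs earlier at higher l/|v|".
#'
#' @param series A [rate_series()].
#' @return A list with `peak_rate` (Hz) and `peak_time` (ms, signed).
#' @export
peak_response <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  if (nrow(series) == 0L) stop("empty rate series has no peak", call. = FALSE)
  pk <- max(series$rate)
  i <- max(which(series$rate == pk))
  list(peak_rate = pk, peak_time = series$t[i])
}

#' Mean peak rate across presentations for one individual
#'
#' An individual's peak response to a stimulus is the unweighted mean of the
#' per-presentation peak rates.
#'
#' @param trains List of [spike_train()] objects (one individual x stimulus).
#' @param window_ms Window for [rate_at_spikes()]. Default 25.
#' @return Mean peak rate in Hz. Presentations with no spikes contribute 0.
#' @export
individual_mean_peak <- function(trains, window_ms = 25) {
  if (length(trains) == 0L) stop("no trains supplied", call. = FALSE)
  peaks <- vapply(trains, function(tr) {
    rs <- rate_at_spikes(tr, window_ms)
    if (nrow(rs) == 0L) 0 else peak_response(rs)$peak_rate
  }, 0)
  mean(peaks)
}

#' Peristimulus time histogram across presentations and individuals
#'
#' Bins spike counts into contiguous fixed-width bins (left-closed,
#' right-open) and aggregates rates hierarchically: per presentation the rate
#' in a bin is count / bin duration; each individual contributes the mean over
#' its presentations; the grand mean and SEM are computed across individuals.
#'
#' @param trains List of [spike_train()] objects; `individual_id` groups them.
#' @param bin_ms Bin width in ms (> 0). Default 25.
#' @param t_range Length-2 vector covering all spikes considered; the last bin
#'   is extended to cover `t_range[2]` if the span is not a multiple of
#'   `bin_ms`.
#' @return An object of class `psth`: `bin_edges` (ms), `t` (bin starts),
#'   `mean_rate` (Hz), `sem` (Hz, 0 when a single individual), `n`
#'   (individuals).
#' @export
psth <- function(trains, bin_ms = 25, t_range) {
  if (length(trains) == 0L) stop("no trains supplied", call. = FALSE)
  if (!is.numeric(bin_ms) || bin_ms <= 0) stop("'bin_ms' must be > 0", call. = FALSE)
  if (missing(t_range) || length(t_range) != 2L || t_range[2] <= t_range[1])
    stop("'t_range' must be an increasing length-2 vector", call. = FALSE)
  edges <- seq(t_range[1], t_range[2], by = bin_ms)
  if (edges[length(edges)] < t_range[2]) edges <- c(edges, edges[length(edges)] + bin_ms)
  nb <- length(edges) - 1L
  if (nb < 1L) stop("empty bin set", call. = FALSE)

  ids <- vapply(trains, `[[`, "", "individual_id")
  rate_one <- function(tr) {
    if (any(tr$t_ms < edges[1] | tr$t_ms >= edges[length(edges)]))
      stop("'t_range' does not cover all spikes", call. = FALSE)
    idx <- findInterval(tr$t_ms, edges)  # left-closed right-open
    tabulate(idx, nbins = nb) / (bin_ms / 1000)
  }
  rates <- vapply(trains, rate_one, numeric(nb))
  rates <- matrix(rates, nrow = nb)
  ind_means <- vapply(unique(ids), function(id)
    rowMeans(rates[, ids == id, drop = FALSE]), numeric(nb))
  ind_means <- matrix(ind_means, nrow = nb)
  n <- ncol(ind_means)
  mean_rate <- rowMeans(ind_means)
  sem <- if (n > 1) apply(ind_means, 1, stats::sd) / sqrt(n) else rep(0, nb)
  structure(list(bin_edges = edges, t = edges[-length(edges)],
                 bin_ms = bin_ms, mean_rate = mean_rate, sem = sem, n = n),
            class = "psth")
}

#' Threshold crossings of a rate series
#'
#' Locates the first time the rate reaches `threshold_hz` (the approximate
#' 150 Hz level above which looming-detector spikes summate to trigger a
#' glide) and the span between first and last suprathreshold points.
#'
#' @param series A [rate_series()].
#' @param threshold_hz Threshold in Hz (> 0). Default 150.
#' @return List with `first_crossing` (ms, `NA` if never crossed) and
#'   `time_above` (ms, 0 if never crossed).
#' @export
threshold_crossings <- function(series, threshold_hz = 150) {
  stopifnot(inherits(series, "rate_series"))
  if (threshold_hz <= 0) stop("'threshold_hz' must be > 0", call. = FALSE)
  above <- which(series$rate >= threshold_hz)
  if (length(above) == 0L)
    return(list(first_crossing = NA_real_, time_above = 0))
  list(first_crossing = series$t[above[1]],
       time_above = series$t[above[length(above)]] - series$t[above[1]])
}

#' Group mean, SEM and n
#'
#' @param x Numeric vector of per-individual values (NAs dropped).
#' @return List with `mean`, `sem` (sample SD / sqrt(n); 0 by convention for a
#'   single value) and `n`.
#' @export
#' @examples
#' group_summary(c(1, 2, 3))
group_summary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1L) stop("no values to summarise", call. = FALSE)
  list(mean = mean(x), sem = if (n > 1) stats::sd(x) / sqrt(n) else 0, n = n)
}
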