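#' Poisson-null visual responsiveness test
#'
#' A unit counts as responsive to a stimulus class when its mean evoked
#' spike count in the response window (default 0–100 ms after onset)
#' exceeds the expectation of a Poisson model trained on the baseline
#' window (default −50–0 ms before onset of the same events) by at least
#' `threshold_sd` standard deviations.  The baseline expectation is scaled
#' to the response-window length, and the standard deviation of the mean of
#' `N` Poisson counts is taken as `sqrt(lambda / N)`.
#'
#' @param spikes Spike table (`unit_id`, `time_s`).
#' @param events Events of one stimulus class (>= 10 rows).
#' @param threshold_sd Responsiveness threshold in SD units; default 5.
#' @param response_window,baseline_window Windows in seconds relative to
#'   onset.
#' @param stim_class Label recorded in the output.
#' @param units Unit ids; default all in `spikes`.
#' @return Data frame, one row per unit: `unit_id`, `stim_class`,
#'   `n_trials`, `lambda_baseline`, `mean_evoked`, `z`, `responsive`.
#' @export
test_responsive <- function(spikes, events, threshold_sd = 5,
                            response_window = c(0, 0.1),
                            baseline_window = c(-0.05, 0),
                            stim_class = NULL, units = NULL) {
  if (nrow(events) < 10) stop("need at least 10 events of the class")
  units <- units %||% sort(unique(spikes$unit_id))
  stim_class <- stim_class %||% (events$class[1] %||% "stimulus")
  scale <- diff(response_window) / diff(baseline_window)
  sp <- split(spikes$time_s, spikes$unit_id)
  n <- nrow(events)
  res <- lapply(units, function(u) {
    tt <- sort(sp[[as.character(u)]]); if (is.null(tt)) tt <- numeric(0)
    b <- count_in_windows(tt, events$onset_s + baseline_window[1],
                          events$onset_s + baseline_window[2])
    e <- count_in_windows(tt, events$onset_s + response_window[1],
                          events$onset_s + response_window[2])
    lam <- mean(b) * scale
    if (lam == 0) lam <- 0.5 / n     # floor: never divide by zero
    z <- (mean(e) - lam) / sqrt(lam / n)
    data.frame(unit_id = u, stim_class = stim_class, n_trials = n,
               lambda_baseline = lam, mean_evoked = mean(e), z = z,
               responsive = z >= threshold_sd)
  })
  do.call(rbind, res)
}

#' Overall visual responsiveness across stimulus classes
#'
#' A unit is visually responsive if it is responsive to any of the
#' presented stimulus classes.
#'
#' @param ... Data frames from [test_responsive], one per class.
#' @return Data frame `unit_id`, `responsive_any`.
#' @export
responsive_any <- function(...) {
  all <- do.call(rbind, list(...))
  agg <- stats::aggregate(responsive ~ unit_id, data = all, FUN = any)
  names(agg)[2] <- "responsive_any"
  agg[order(agg$unit_id), ]
}

#' Recording-stability block filter
#'
#' For long runs split into presentation blocks, flags blocks where a
#' unit's spike yield dropped, as happens when electrode drift shrinks the
#' waveform.  Per block the waveform amplitude is proxied by the mean
#' per-spike amplitude; the amplitude threshold is 0.6 times the
#' third-largest per-block amplitude; spikes above threshold are counted
#' per block; a block is excluded when its count falls more than two
#' standard deviations below the mean across blocks.
#'
#' @param spikes Spike table with `amplitude`.
#' @param block_windows Data frame `block`, `start`, `end` (seconds).
#' @param units Unit ids; default all.
#' @return Data frame, one row per unit x block: `unit_id`, `block`,
#'   `mean_amplitude`, `suprathreshold_count`, `kept`; attribute
#'   `"amplitude_threshold"` holds the per-unit thresholds.
#' @export
filter_stable_blocks <- function(spikes, block_windows, units = NULL) {
  units <- units %||% sort(unique(spikes$unit_id))
  nb <- nrow(block_windows)
  if (nb < 3) {
    warning("fewer than 3 blocks: stability filter skipped, all blocks kept")
    out <- expand.grid(unit_id = units, block = block_windows$block)
    out$mean_amplitude <- NA_real_
    out$suprathreshold_count <- NA_integer_
    out$kept <- TRUE
    return(out[order(out$unit_id, out$block), ])
  }
  thr_all <- numeric(length(units)); names(thr_all) <- units
  res <- lapply(seq_along(units), function(i) {
    u <- units[i]
    s <- spikes[spikes$unit_id == u, , drop = FALSE]
    bi <- findInterval(s$time_s, block_windows$start)
    ok <- bi >= 1 & s$time_s <= block_windows$end[pmax(bi, 1)]
    s <- s[ok, , drop = FALSE]; bi <- bi[ok]
    amp <- vapply(seq_len(nb), function(b)
      if (any(bi == b)) mean(s$amplitude[bi == b]) else 0, numeric(1))
    thr <- 0.6 * sort(amp, decreasing = TRUE)[3]
    thr_all[i] <<- thr
    cnt <- vapply(seq_len(nb), function(b)
      sum(bi == b & s$amplitude > thr), integer(1))
    kept <- cnt >= mean(cnt) - 2 * stats::sd(cnt)
    data.frame(unit_id = u, block = block_windows$block,
               mean_amplitude = amp, suprathreshold_count = cnt, kept = kept)
  })
  out <- do.call(rbind, res)
  attr(out, "amplitude_threshold") <- thr_all
  out
}

#' Half-peak response latency
#'
#' Builds a PSTH of trial-summed spike counts (default 5-ms bins, no
#' smoothing) over the average response to the supplied events.  A unit is
#' kept only when the peak bin count exceeds the 99.75th percentile of the
#' Poisson distribution predicted from its baseline firing; the half-peak
#' latency is then the left edge of the first bin whose rate reaches
#' halfway between the baseline rate and the peak rate.
#'
#' @param spikes Spike table.
#' @param events Event table (typically gratings plus texture/noise).
#' @param bin_s PSTH bin width, seconds; default 0.005.
#' @param window PSTH window relative to onset; default `c(0, 0.25)`.
#' @param baseline_window Baseline window; default `c(-0.05, 0)`.
#' @param percentile Poisson peak-test percentile; default 0.9975.
#' @param units Unit ids; default all.
#' @return Data frame per unit: `unit_id`, `r_baseline`, `r_peak`,
#'   `peak_time`, `passes_peak_test`, `latency_s` (`NA` unless the peak
#'   test passes and the half-peak level is reached).
#' @export
half_peak_latency <- function(spikes, events, bin_s = 0.005,
                              window = c(0, 0.25),
                              baseline_window = c(-0.05, 0),
                              percentile = 0.9975, units = NULL) {
  units <- units %||% sort(unique(spikes$unit_id))
  edges <- seq(window[1], window[2], by = bin_s)
  n_bins <- length(edges) - 1L
  n_tr <- nrow(events)
  sp <- split(spikes$time_s, spikes$unit_id)
  res <- lapply(units, function(u) {
    tt <- sort(sp[[as.character(u)]]); if (is.null(tt)) tt <- numeric(0)
    counts <- integer(n_bins)
    for (b in seq_len(n_bins)) {
      counts[b] <- sum(count_in_windows(tt, events$onset_s + edges[b],
                                        events$onset_s + edges[b + 1L]))
    }
    bl <- sum(count_in_windows(tt, events$onset_s + baseline_window[1],
                               events$onset_s + baseline_window[2]))
    r_b <- bl / (n_tr * diff(baseline_window))          # Hz
    lam_bin <- r_b * bin_s * n_tr                        # expected summed count/bin
    crit <- stats::qpois(percentile, lam_bin)
    rates <- counts / (bin_s * n_tr)
    pk <- which.max(counts)
    passes <- counts[pk] > crit
    lat <- NA_real_
    if (passes) {
      half <- (r_b + rates[pk]) / 2
      hit <- which(rates >= half)
      if (length(hit)) lat <- edges[hit[1]]
    }
    data.frame(unit_id = u, r_baseline = r_b, r_peak = rates[pk],
               peak_time = edges[pk] + bin_s / 2,
               passes_peak_test = passes, latency_s = lat)
  })
  do.call(rbind, res)
}
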