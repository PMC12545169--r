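#' Build ON/OFF receptive-field histograms from sparse noise
#'
#' Reverse-correlation 2D histogram of spike counts at each stimulated
#' location, computed separately for white-dot (ON) and black-dot (OFF)
#' frames.  Because several dots appear per frame, spikes falling in the
#' response window after a frame credit every dot location shown in that
#' frame; the decorrelated dot placement cancels off-field credits in the
#' average.  Presentation counts are tracked per location; locations never
#' stimulated are masked (absent), not zero-filled.
#'
#' @param spikes Spike table.
#' @param schedule A [make_sparse_noise_schedule] object.
#' @param response_window Window after frame onset in which spikes are
#'   credited, seconds. Default `c(0.05, 0.15)`.
#' @param units Unit ids; default all.
#' @return Named list (one element per unit) of lists with `ON` and `OFF`
#'   histograms of class `rf_histogram`: data frames `azimuth`,
#'   `elevation`, `count`, `n_pres`.
#' @export
build_rf_histogram <- function(spikes, schedule,
                               response_window = c(0.05, 0.15),
                               units = NULL) {
  stopifnot(inherits(schedule, "sparse_noise_schedule"))
  units <- units %||% sort(unique(spikes$unit_id))
  fr <- schedule$frames
  dots <- schedule$dots
  dots$key <- paste(dots$azimuth, dots$elevation, sep = "_")
  keys <- sort(unique(dots$key))
  loc <- do.call(rbind, strsplit(keys, "_"))
  loc <- data.frame(azimuth = as.numeric(loc[, 1]),
                    elevation = as.numeric(loc[, 2]))
  ki <- match(dots$key, keys)
  fi <- match(dots$frame_index, fr$frame_index)
  pol_of_frame <- fr$polarity
  sp <- split(spikes$time_s, spikes$unit_id)
  lo <- fr$onset_s + response_window[1]
  hi <- fr$onset_s + response_window[2]
  out <- lapply(units, function(u) {
    tt <- sort(sp[[as.character(u)]]); if (is.null(tt)) tt <- numeric(0)
    frame_counts <- count_in_windows(tt, lo, hi)
    per_pol <- lapply(c(ON = "white", OFF = "black"), function(p) {
      sel <- pol_of_frame[fi] == p
      cnt <- rowsum(frame_counts[fi[sel]], ki[sel])
      pres <- rowsum(rep(1L, sum(sel)), ki[sel])
      idx <- as.integer(rownames(cnt))
      h <- data.frame(azimuth = loc$azimuth[idx], elevation = loc$elevation[idx],
                      count = as.vector(cnt), n_pres = as.vector(pres))
      class(h) <- c("rf_histogram", class(h))
      attr(h, "unit_id") <- u
      attr(h, "polarity") <- names(which(c(ON = "white", OFF = "black") == p))
      h
    })
    names(per_pol) <- c("ON", "OFF")
    per_pol
  })
  names(out) <- units
  out
}

rf_model <- function(p, x, y) {
  p["B"] + p["A"] * exp(-((x - p["x0"])^2 + (y - p["y0"])^2) / (2 * p["sigma"]^2))
}

#' Fit a circular 2D Gaussian to a receptive-field histogram
#'
#' Nonlinear least squares of `B + A * exp(-((x-x0)^2+(y-y0)^2)/(2 sigma^2))`
#' to the per-location mean spike count (count / presentations).  The
#' Gaussian is forced to be circular (one sigma) to prevent overfitting.
#' Fits are started from the three highest histogram peaks and the best
#' converged solution is kept; bounds keep `sigma` in `[1, 40]` degrees and
#' the centre within the monitor plus a 10-degree margin.  The fit is
#' scored with [rf_quality]; a unit possesses a receptive field only when
#' the quality exceeds 5.
#'
#' @param hist An `rf_histogram` (one unit, one polarity).
#' @param quality_threshold Quality needed for `has_rf`; default 5.
#' @return Object of class `rf_fit`: `x0`, `y0`, `sigma`, `A`, `B`,
#'   `converged`, `Q`, `has_rf`, `size_deg` (FWHM), `polarity`, `unit_id`.
#' @export
fit_rf <- function(hist, quality_threshold = 5) {
  h <- hist[hist$n_pres > 0, , drop = FALSE]
  if (nrow(h) < 20) stop("need at least 20 stimulated locations")
  m <- h$count / h$n_pres
  x <- h$azimuth; y <- h$elevation
  lower <- c(x0 = MONITOR_AZ[1] - 10, y0 = MONITOR_EL[1] - 10,
             sigma = 1, A = 0, B = 0)
  upper <- c(x0 = MONITOR_AZ[2] + 10, y0 = MONITOR_EL[2] + 10,
             sigma = 40, A = Inf, B = Inf)
  peaks <- order(m, decreasing = TRUE)[1:3]
  B0 <- stats::median(m)
  best <- NULL
  for (pk in peaks) {
    start <- c(x0 = x[pk], y0 = y[pk], sigma = 5,
               A = max(m[pk] - B0, 1e-3), B = max(B0, 1e-6))
    fit <- try(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = function(p) m - rf_model(p, x, y),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$info %in% c(1, 2, 3, 4) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) {
    out <- list(unit_id = attr(hist, "unit_id"),
                polarity = attr(hist, "polarity"),
                x0 = NA, y0 = NA, sigma = NA, A = NA, B = NA,
                converged = FALSE, Q = NA_real_, has_rf = FALSE,
                size_deg = NA_real_)
    class(out) <- "rf_fit"
    return(out)
  }
  p <- best$par
  out <- list(unit_id = attr(hist, "unit_id"),
              polarity = attr(hist, "polarity"),
              x0 = unname(p["x0"]), y0 = unname(p["y0"]),
              sigma = unname(p["sigma"]), A = unname(p["A"]),
              B = unname(p["B"]), converged = TRUE)
  out$Q <- rf_quality(hist, out)
  out$has_rf <- isTRUE(out$Q > quality_threshold)
  out$size_deg <- if (out$has_rf) rf_size(out) else NA_real_
  class(out) <- "rf_fit"
  out
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("RF fit (%s, unit %s): centre (%.1f, %.1f) deg, sigma %.2f deg, Q = %.2f, has_rf = %s\n",
              x$polarity %||% "?", x$unit_id %||% "?",
              x$x0, x$y0, x$sigma, x$Q, x$has_rf))
  invisible(x)
}

#' Receptive-field quality statistic
#'
#' Compares the observed spike count at locations within 10 degrees of the
#' fitted centre against the expectation under the baseline-only null
#' model: `E = B * sum(presentations within radius)`, `Q = (O - E) /
#' sqrt(E)` — the number of baseline standard deviations by which the
#' observed count exceeds the null.
#'
#' @param hist An `rf_histogram`.
#' @param fit A list with `x0`, `y0`, `B` (e.g. an `rf_fit`).
#' @param radius_deg Radius around the centre; default 10.
#' @return Quality `Q` in SD units (`NA` when the expected count is 0).
#' @export
rf_quality <- function(hist, fit, radius_deg = 10) {
  d2 <- (hist$azimuth - fit$x0)^2 + (hist$elevation - fit$y0)^2
  sel <- d2 <= radius_deg^2 & hist$n_pres > 0
  E <- fit$B * sum(hist$n_pres[sel])
  if (!is.finite(E) || E <= 0) return(NA_real_)
  O <- sum(hist$count[sel])
  (O - E) / sqrt(E)
}

#' Receptive-field size from a fit
#'
#' @param fit An `rf_fit`.
#' @param convention `"fwhm"` (default; diameter `2 sqrt(2 ln 2) sigma`) or
#'   `"2sigma"`.
#' @return Size in degrees.
#' @export
rf_size <- function(fit, convention = c("fwhm", "2sigma")) {
  convention <- match.arg(convention)
  switch(convention,
         fwhm = 2 * sqrt(2 * log(2)) * fit$sigma,
         "2sigma" = 2 * fit$sigma)
}

#' @export
plot.rf_fit <- function(x, hist = NULL, ...) {
  if (is.null(hist)) stop("pass the rf_histogram used for the fit via 'hist'")
  az <- sort(unique(hist$azimuth)); el <- sort(unique(hist$elevation))
  z <- matrix(NA_real_, length(az), length(el))
  z[cbind(match(hist$azimuth, az), match(hist$elevation, el))] <-
    hist$count / pmax(hist$n_pres, 1)
  graphics::image(az, el, z, xlab = "azimuth (deg)", ylab = "elevation (deg)",
                  main = sprintf("unit %s %s  Q=%.1f", x$unit_id, x$polarity, x$Q),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  if (isTRUE(x$converged)) {
    th <- seq(0, 2 * pi, length.out = 100)
    graphics::lines(x$x0 + x$sigma * cos(th), x$y0 + x$sigma * sin(th), lwd = 2)
  }
  invisible(x)
}
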