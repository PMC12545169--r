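#' Simulate a recording session as an inhomogeneous Poisson process
#'
#' For every neuron the instantaneous firing rate is its baseline plus a
#' stimulus drive, delayed by the neuron's latency and sustained for the
#' stimulus duration:
#' \itemize{
#'   \item sparse-noise frames: a circular-Gaussian receptive-field term in
#'     dot position, gated by dot polarity (ON fields respond to white,
#'     OFF to black, `both` to either, `none` not at all);
#'   \item gratings: Von Mises tuning in orientation (period 180 deg)
#'     times a log-Gaussian in spatial frequency;
#'   \item texture/noise images: a texture-versus-noise offset plus a
#'     per-family weight (texture images only);
#'   \item object/face images: a ramp ("axis") term — the gain times a
#'     (rectified by default, optionally linear) projection of the image's
#'     feature principal-component scores onto the neuron's preferred
#'     axis, standardized to unit variance across the bank.
#' }
#' Rates that would fall below zero are clipped at zero (a message reports
#' how many windows were clipped).  Spikes are drawn as a piecewise-constant
#' inhomogeneous Poisson process; spike waveform amplitudes follow each
#' neuron's per-block amplitude profile with small lognormal jitter.
#'
#' @param neurons A [make_ground_truth_neurons] object.
#' @param sparse_noise Optional [make_sparse_noise_schedule] object.
#' @param gratings Optional [make_grating_schedule] object.
#' @param textures Optional list `list(bank, events)` from
#'   [make_texture_bank] and [make_presentation_schedule].
#' @param objects Optional list `list(bank, events, features)`; `features`
#'   is one [feature_bank] whose `pc_scores` define the axis drive.
#' @param object_nonlinearity `"rectified"` (default) or `"linear"` ramp.
#' @param tail_s Quiet time appended after the last event, seconds.
#' @param seed Integer seed; identical seeds give identical spike tables.
#' @return List of class `session`: `spikes` (data frame `unit_id`, `area`,
#'   `time_s`, `amplitude`), `events` (data frame `stim_id`, `class`,
#'   `onset_s`, `duration_s`, `block`), and `ground_truth` (the input
#'   neurons, for recovery tests only).
#' @export
simulate_session <- function(neurons,
                             sparse_noise = NULL,
                             gratings = NULL,
                             textures = NULL,
                             objects = NULL,
                             object_nonlinearity = c("rectified", "linear"),
                             tail_s = 0.5,
                             seed = 1L) {
  stopifnot(inherits(neurons, "ground_truth_neurons"))
  object_nonlinearity <- match.arg(object_nonlinearity)
  un <- neurons$units
  n_units <- nrow(un)

  events <- list(); drives <- list()
  if (!is.null(sparse_noise)) {
    fr <- sparse_noise$frames
    ev <- data.frame(stim_id = fr$frame_index, class = "sparse_noise",
                     onset_s = fr$onset_s, duration_s = fr$duration_s,
                     block = 1L)
    gate <- matrix(0, n_units, nrow(fr))
    white <- fr$polarity == "white"
    gate[un$rf_polarity %in% c("ON", "both"), white] <- 1
    gate[un$rf_polarity %in% c("OFF", "both"), !white] <- 1
    d <- matrix(0, n_units, nrow(fr))
    dots <- sparse_noise$dots
    for (u in seq_len(n_units)) {
      if (un$rf_polarity[u] == "none" || un$rf_gain[u] == 0) next
      g <- exp(-((dots$azimuth - un$rf_x[u])^2 + (dots$elevation - un$rf_y[u])^2) /
                 (2 * un$rf_sigma[u]^2))
      d[u, ] <- un$rf_gain[u] *
        as.vector(rowsum(g, dots$frame_index)[as.character(fr$frame_index), 1])
    }
    events[[length(events) + 1L]] <- ev
    drives[[length(drives) + 1L]] <- d * gate
  }
  if (!is.null(gratings)) {
    ev <- gratings$events
    ev$block <- 1L
    cond <- gratings$conditions
    dth <- outer(un$pref_orientation, cond$orientation, function(p, o)
      cos(2 * (o - p) * pi / 180) - 1)
    dsf <- outer(seq_len(nrow(un)), seq_len(nrow(cond)), function(u, c)
      -(log(cond$spatial_frequency[c]) - log(un$pref_sf[u]))^2 /
        (2 * un$sf_logsigma[u]^2))
    dcond <- un$grating_gain * exp(un$vm_kappa * dth + dsf)
    events[[length(events) + 1L]] <- ev
    drives[[length(drives) + 1L]] <- dcond[, match(ev$stim_id, cond$condition_id),
                                           drop = FALSE]
  }
  if (!is.null(textures)) {
    ev <- textures$events
    if (is.null(ev$block)) ev$block <- 1L
    bank <- textures$bank
    idx <- match(ev$stim_id, bank$image_ids)
    is_tex <- as.numeric(bank$category[idx] == "texture")
    fam <- bank$family[idx]
    d <- outer(un$texture_gain, is_tex) +
      t(vapply(seq_len(n_units), function(u)
        ifelse(is.na(fam), 0, neurons$family_weights[u, fam]) * is_tex,
        numeric(length(idx))))
    events[[length(events) + 1L]] <- ev
    drives[[length(drives) + 1L]] <- d
  }
  if (!is.null(objects)) {
    ev <- objects$events
    if (is.null(ev$block)) ev$block <- 1L
    fb <- objects$features
    stopifnot(inherits(fb, "feature_bank"))
    scores <- fb$pc_scores
    npc <- min(ncol(scores), ncol(neurons$axis_true))
    proj <- scores[, seq_len(npc), drop = FALSE] %*%
      t(neurons$axis_true[, seq_len(npc), drop = FALSE])  # images x units
    proj <- scale(proj)                       # unit variance per neuron
    ramp <- if (object_nonlinearity == "rectified") pmax(proj, 0) else proj
    d <- t(ramp) * un$axis_gain               # units x images
    idx <- match(ev$stim_id, fb$image_ids)
    events[[length(events) + 1L]] <- ev
    drives[[length(drives) + 1L]] <- d[, idx, drop = FALSE]
  }
  if (length(events) == 0L) stop("no stimulus schedule supplied")
  events <- do.call(rbind, events)
  drive <- do.call(cbind, drives)
  ord <- order(events$onset_s)
  events <- events[ord, , drop = FALSE]
  drive <- drive[, ord, drop = FALSE]
  rownames(events) <- NULL

  t_end <- max(events$onset_s + events$duration_s) + tail_s
  # per-block time ranges of the object presentations, for amplitudes
  obj_ev <- events[events$class == "objects", , drop = FALSE]
  block_ranges <- NULL
  if (nrow(obj_ev) > 0) {
    block_ranges <- do.call(rbind, lapply(split(obj_ev, obj_ev$block), function(b)
      data.frame(block = b$block[1], start = min(b$onset_s),
                 end = max(b$onset_s + b$duration_s))))
  }

  n_clipped <- 0L
  spikes <- with_seed(seed, {
    out <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      lat <- un$latency[u]; base <- un$baseline_rate[u]
      ws <- events$onset_s + lat
      we <- pmin(events$onset_s + events$duration_s + lat,
                 c(ws[-1], Inf))        # truncate at the next drive window
      rate <- base + drive[u, ]
      n_clipped <- n_clipped + sum(rate < 0)
      rate <- pmax(rate, 0)
      cnt <- stats::rpois(length(ws), rate * (we - ws))
      st_stim <- rep(ws, cnt) + stats::runif(sum(cnt)) * rep(we - ws, cnt)
      gs <- c(0, we); ge <- c(ws, t_end)
      keep <- ge > gs
      gcnt <- stats::rpois(sum(keep), base * (ge[keep] - gs[keep]))
      st_gap <- rep(gs[keep], gcnt) +
        stats::runif(sum(gcnt)) * rep((ge - gs)[keep], gcnt)
      tt <- sort(c(st_stim, st_gap))
      amp <- un$amplitude_base[u] * exp(stats::rnorm(length(tt), 0, 0.05))
      if (!is.null(block_ranges)) {
        bi <- findInterval(tt, block_ranges$start)
        inb <- bi >= 1 & tt <= block_ranges$end[pmax(bi, 1)]
        amp[inb] <- amp[inb] *
          neurons$block_amplitude[u, block_ranges$block[bi[inb]]]
      }
      out[[u]] <- data.frame(unit_id = un$unit_id[u],
                             area = as.character(un$area[u]),
                             time_s = tt, amplitude = amp)
    }
    do.call(rbind, out)
  })
  if (n_clipped > 0L)
    message(sprintf("simulate_session: %d stimulus windows clipped at rate 0",
                    n_clipped))
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, events = events, ground_truth = neurons),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("Simulated session: %d spikes, %d units, %d events (%s)\n",
              nrow(x$spikes), length(unique(x$spikes$unit_id)),
              nrow(x$events), paste(unique(x$events$class), collapse = ", ")))
  invisible(x)
}

#' Evoked spike-count tensor
#'
#' Counts each unit's spikes in a fixed window around every event and
#' arranges them as a units x stimuli x repeats array — the hub object
#' consumed by the tuning, axis, decoding and selectivity analyses.
#'
#' @param spikes Spike table (`unit_id`, `time_s`, ...).
#' @param events Event table (`stim_id`, `onset_s`); typically one stimulus
#'   class.
#' @param window Response window relative to onset, seconds. Default
#'   `c(0, 0.1)`.
#' @param units Unit ids to include; default all units present.
#' @return Numeric array `[units, stimuli, repeats]` with dimnames; `NA`
#'   where a stimulus has fewer repeats than the maximum.
#' @export
response_tensor <- function(spikes, events, window = c(0, 0.1), units = NULL) {
  units <- units %||% sort(unique(spikes$unit_id))
  stim <- sort(unique(events$stim_id))
  rep_idx <- stats::ave(seq_len(nrow(events)), events$stim_id, FUN = seq_along)
  n_rep <- max(rep_idx)
  arr <- array(NA_real_, c(length(units), length(stim), n_rep),
               dimnames = list(unit = units, stim = stim, rep = seq_len(n_rep)))
  sp <- split(spikes$time_s, spikes$unit_id)
  lo <- events$onset_s + window[1]; hi <- events$onset_s + window[2]
  si <- match(events$stim_id, stim)
  for (ui in seq_along(units)) {
    tt <- sort(sp[[as.character(units[ui])]])
    if (is.null(tt)) tt <- numeric(0)
    cnt <- count_in_windows(tt, lo, hi)
    arr[cbind(ui, si, rep_idx)] <- cnt
  }
  arr
}

#' Per-image mean responses
#'
#' Mean over repeats of a [response_tensor] array, giving a units x images
#' matrix.
#'
#' @param tensor Array from [response_tensor].
#' @return Matrix units x stimuli.
#' @export
image_means <- function(tensor) {
  apply(tensor, c(1, 2), mean, na.rm = TRUE)
}
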