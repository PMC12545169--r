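#' Generate a local sparse-noise schedule
#'
#' Builds the frame sequence used for receptive-field mapping: the screen is
#' divided into a coarse grid of cells (default 4 columns x 3 rows) and on
#' every 100-ms frame one square dot is placed pseudo-randomly inside each
#' cell, all dots sharing a single polarity (all white or all black on a grey
#' field).  Polarities follow a balanced shuffled sequence so ON and OFF maps
#' can be reconstructed independently.  Dot centres are drawn from a finer
#' candidate lattice (default 32 x 18 positions across the monitor) so that
#' distant parts of the visual field are stimulated in a decorrelated way.
#'
#' @param grid_shape Integer vector `(cols, rows)` of scheduling grid cells.
#' @param dot_size_deg Side of the square dots, degrees. Default 5.
#' @param frame_duration_s Duration of each frame in seconds. Default 0.1.
#' @param n_frames Number of frames; must be even so white and black frame
#'   counts balance.
#' @param lattice Integer vector `(n_az, n_el)` of candidate dot positions
#'   spanning the monitor. Default `c(32, 18)`.
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return An object of class `sparse_noise_schedule`: a list with `frames`
#'   (data frame: `frame_index`, `polarity`, `onset_s`, `duration_s`),
#'   `dots` (data frame: `frame_index`, `azimuth`, `elevation`),
#'   `dot_size_deg`, and the lattice coordinates.
#' @export
make_sparse_noise_schedule <- function(grid_shape = c(4, 3),
                                       dot_size_deg = 5,
                                       frame_duration_s = 0.1,
                                       n_frames = 200,
                                       lattice = c(32, 18),
                                       seed = 1L) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1),
            dot_size_deg > 0, frame_duration_s > 0, n_frames >= 2)
  if (n_frames %% 2L != 0L)
    stop("n_frames must be even so white and black frames balance")
  cell_w <- diff(MONITOR_AZ) / grid_shape[1]
  cell_h <- diff(MONITOR_EL) / grid_shape[2]
  if (dot_size_deg > min(cell_w, cell_h))
    stop(sprintf("dot_size_deg = %g exceeds the grid cell size (%.1f x %.1f deg)",
                 dot_size_deg, cell_w, cell_h))

  az_pos <- MONITOR_AZ[1] + (seq_len(lattice[1]) - 0.5) * diff(MONITOR_AZ) / lattice[1]
  el_pos <- MONITOR_EL[1] + (seq_len(lattice[2]) - 0.5) * diff(MONITOR_EL) / lattice[2]
  # candidate positions grouped by scheduling cell
  cand <- expand.grid(azimuth = az_pos, elevation = el_pos)
  col_of <- pmin(grid_shape[1], 1L + floor((cand$azimuth - MONITOR_AZ[1]) / cell_w))
  row_of <- pmin(grid_shape[2], 1L + floor((cand$elevation - MONITOR_EL[1]) / cell_h))
  cell_id <- (row_of - 1L) * grid_shape[1] + col_of
  n_cells <- grid_shape[1] * grid_shape[2]
  by_cell <- split(seq_len(nrow(cand)), cell_id)
  if (length(by_cell) != n_cells)
    stop("candidate lattice too coarse: some scheduling cells have no positions")

  with_seed(seed, {
    polarity <- sample(rep(c("white", "black"), n_frames / 2L))
    picks <- vapply(seq_len(n_frames), function(f) {
      vapply(by_cell, function(idx) idx[sample.int(length(idx), 1L)], integer(1))
    }, integer(n_cells))
    dots <- data.frame(
      frame_index = rep(seq_len(n_frames), each = n_cells),
      azimuth = cand$azimuth[as.vector(picks)],
      elevation = cand$elevation[as.vector(picks)]
    )
    frames <- data.frame(
      frame_index = seq_len(n_frames),
      polarity = polarity,
      onset_s = (seq_len(n_frames) - 1L) * frame_duration_s,
      duration_s = frame_duration_s
    )
    structure(list(frames = frames, dots = dots,
                   dot_size_deg = dot_size_deg,
                   grid_shape = grid_shape,
                   lattice_az = az_pos, lattice_el = el_pos),
              class = "sparse_noise_schedule")
  })
}

#' @export
print.sparse_noise_schedule <- function(x, ...) {
  cat(sprintf("Sparse-noise schedule: %d frames x %d dots (%g deg, %g s/frame)\n",
              nrow(x$frames), prod(x$grid_shape), x$dot_size_deg,
              x$frames$duration_s[1]))
  invisible(x)
}

#' Generate a static-grating schedule
#'
#' Full factorial design over orientation, spatial frequency and phase,
#' each condition repeated `n_repeats` times in one shuffled sequence.
#' Defaults reproduce the standard design: 6 evenly spread orientations x
#' 5 spatial frequencies between 0.1 and 1.6 cycles/degree x 4 phases =
#' 120 conditions, 5 repeats each, presented at 3 Hz (167 ms on, 167 ms
#' grey screen).
#'
#' @param n_orientations Number of evenly spread orientations in `[0, 180)`.
#' @param sf_values Spatial frequencies, cycles/degree.
#' @param n_phases Number of evenly spread phases.
#' @param n_repeats Repeats per condition (>= 1).
#' @param duration_s,isi_s Presentation time and inter-stimulus grey interval.
#' @param t0 Onset of the first event, seconds.
#' @param seed Integer seed for the shuffle.
#' @return Object of class `grating_schedule`: list with `conditions`
#'   (data frame: `condition_id`, `orientation`, `spatial_frequency`,
#'   `phase`) and `events` (data frame: `stim_id`, `class`, `onset_s`,
#'   `duration_s`).
#' @export
make_grating_schedule <- function(n_orientations = 6,
                                  sf_values = c(0.1, 0.2, 0.4, 0.8, 1.6),
                                  n_phases = 4,
                                  n_repeats = 5,
                                  duration_s = 0.167,
                                  isi_s = 0.167,
                                  t0 = 0,
                                  seed = 1L) {
  stopifnot(n_orientations >= 1, n_phases >= 1, all(sf_values > 0))
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  conditions <- expand.grid(
    orientation = seq(0, 180, length.out = n_orientations + 1)[seq_len(n_orientations)],
    spatial_frequency = sf_values,
    phase = seq(0, 360, length.out = n_phases + 1)[seq_len(n_phases)]
  )
  conditions$condition_id <- seq_len(nrow(conditions))
  order <- with_seed(seed, sample(rep(conditions$condition_id, n_repeats)))
  events <- data.frame(
    stim_id = order,
    class = "gratings",
    onset_s = t0 + (seq_along(order) - 1L) * (duration_s + isi_s),
    duration_s = duration_s
  )
  structure(list(conditions = conditions, events = events),
            class = "grating_schedule")
}

#' @export
print.grating_schedule <- function(x, ...) {
  cat(sprintf("Grating schedule: %d conditions x %d repeats (%d events)\n",
              nrow(x$conditions), nrow(x$events) / nrow(x$conditions),
              nrow(x$events)))
  invisible(x)
}

#' Build a presentation schedule for an image bank
#'
#' Shuffled sequence of all images repeated `n_repeats` times, optionally
#' organized into repeat blocks (each block presents every image once, in a
#' fresh shuffled order), as used for the long object-set runs where
#' recording stability is assessed per block.
#'
#' @param bank An [image_bank] object.
#' @param n_repeats Repeats per image; defaults to the bank's `repeats`.
#' @param duration_s,isi_s Presentation and grey-screen interval, seconds.
#' @param t0 Onset of the first event.
#' @param blocked If `TRUE` (default) repeats are organized as blocks.
#' @param seed Integer seed.
#' @return Data frame of events: `stim_id`, `class`, `onset_s`,
#'   `duration_s`, `block`.
#' @export
make_presentation_schedule <- function(bank, n_repeats = NULL,
                                       duration_s = 0.167, isi_s = 0.167,
                                       t0 = 0, blocked = TRUE, seed = 1L) {
  stopifnot(inherits(bank, "image_bank"))
  n_repeats <- n_repeats %||% bank$repeats[1]
  ids <- bank$image_ids
  cls <- if (any(bank$category %in% c("texture", "noise"))) "texture_noise" else "objects"
  with_seed(seed, {
    if (blocked) {
      order <- unlist(lapply(seq_len(n_repeats), function(b) sample(ids)))
      block <- rep(seq_len(n_repeats), each = length(ids))
    } else {
      order <- sample(rep(ids, n_repeats))
      block <- rep(1L, length(order))
    }
    data.frame(
      stim_id = order,
      class = cls,
      onset_s = t0 + (seq_along(order) - 1L) * (duration_s + isi_s),
      duration_s = duration_s,
      block = block
    )
  })
}
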