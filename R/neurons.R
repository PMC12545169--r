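#' Generate ground-truth neurons for simulation
#'
#' Draws a population of model neurons with hidden parameters mirroring
#' every quantity the pipeline later estimates: baseline rate, response
#' latency, a circular-Gaussian receptive field (ON, OFF, both or none),
#' Von Mises orientation tuning crossed with log-Gaussian spatial-frequency
#' tuning, a ramp ("axis") tuning direction in the reduced feature space,
#' a texture-versus-noise response difference, per-family texture weights,
#' and a per-block waveform-amplitude profile for the stability filter.
#'
#' Areas form a posterior-to-anterior ladder: receptive-field size,
#' response latency and texture modulation all increase along
#' `areas` in the order given, mirroring hierarchical organization.
#'
#' @param n_per_area Units per area.
#' @param areas Area labels, posterior to anterior.
#' @param n_pcs Dimension of the feature space the axis lives in.
#' @param n_blocks Number of presentation blocks for the amplitude profile.
#' @param baseline_hz Mean baseline rate (gamma-distributed across units).
#' @param latency_s Mean latency per area; defaults ramp 40 -> 100 ms.
#' @param rf_sigma_deg Mean RF sigma per area; defaults ramp 3 -> 16 deg.
#' @param rf_gain_hz,grating_gain_hz,axis_gain_hz,texture_gain_hz Mean
#'   response gains (Hz) of each stimulus term; `texture_gain_hz` may be a
#'   per-area vector.
#' @param family_gain_hz Gain of the per-family texture signal.
#' @param seed Integer seed.
#' @return Object of class `ground_truth_neurons`: list with `units`
#'   (one row per unit), `axis_true` (`n x n_pcs`, unit rows),
#'   `family_weights` (`n x 15`), `block_amplitude` (`n x n_blocks`).
#' @export
make_ground_truth_neurons <- function(n_per_area = 40,
                                      areas = c("V1", "V2", "TD", "TI", "TP"),
                                      n_pcs = 50,
                                      n_blocks = 10,
                                      baseline_hz = 5,
                                      latency_s = NULL,
                                      rf_sigma_deg = NULL,
                                      rf_gain_hz = 25,
                                      grating_gain_hz = 20,
                                      axis_gain_hz = 12,
                                      texture_gain_hz = NULL,
                                      family_gain_hz = 3,
                                      seed = 1L) {
  n_areas <- length(areas)
  latency_s <- latency_s %||% seq(0.04, 0.10, length.out = n_areas)
  rf_sigma_deg <- rf_sigma_deg %||% seq(3, 16, length.out = n_areas)
  texture_gain_hz <- rep_len(texture_gain_hz %||% seq(2, 8, length.out = n_areas),
                             n_areas)
  n <- n_per_area * n_areas
  with_seed(seed, {
    area <- rep(areas, each = n_per_area)
    ai <- rep(seq_len(n_areas), each = n_per_area)
    units <- data.frame(
      unit_id = seq_len(n),
      area = factor(area, levels = areas),
      baseline_rate = stats::rgamma(n, shape = 4, rate = 4 / baseline_hz),
      latency = pmax(0.02, stats::rnorm(n, latency_s[ai], 0.008)),
      rf_x = stats::runif(n, -30, 30),
      rf_y = stats::runif(n, -22, 22),
      rf_sigma = pmax(1, stats::rnorm(n, rf_sigma_deg[ai], rf_sigma_deg[ai] / 6)),
      rf_polarity = sample(c("ON", "OFF", "both", "none"), n, replace = TRUE,
                           prob = c(0.35, 0.35, 0.2, 0.1)),
      rf_gain = stats::rgamma(n, 4, 4 / rf_gain_hz),
      pref_orientation = stats::runif(n, 0, 180),
      vm_kappa = stats::rgamma(n, 4, 2),
      pref_sf = exp(stats::runif(n, log(0.1), log(1.6))),
      sf_logsigma = stats::runif(n, 0.5, 1.2),
      grating_gain = stats::rgamma(n, 4, 4 / grating_gain_hz),
      axis_gain = stats::rgamma(n, 4, 4 / axis_gain_hz),
      texture_gain = stats::rnorm(n, texture_gain_hz[ai], 1),
      amplitude_base = stats::runif(n, 50, 150),
      stringsAsFactors = FALSE
    )
    axis_true <- matrix(stats::rnorm(n * n_pcs), n, n_pcs)
    axis_true <- axis_true / sqrt(rowSums(axis_true^2))
    family_weights <- matrix(stats::rnorm(n * 15), n, 15) * family_gain_hz
    # slow multiplicative drift of waveform amplitude across blocks
    drift <- matrix(stats::rnorm(n * n_blocks, 0, 0.03), n, n_blocks)
    block_amplitude <- exp(t(apply(drift, 1, cumsum)))
    structure(list(units = units, axis_true = axis_true,
                   family_weights = family_weights,
                   block_amplitude = block_amplitude,
                   areas = areas),
              class = "ground_truth_neurons")
  })
}

#' @export
print.ground_truth_neurons <- function(x, ...) {
  cat(sprintf("Ground-truth neurons: %d units in %d areas (%s)\n",
              nrow(x$units), length(x$areas), paste(x$areas, collapse = ", ")))
  invisible(x)
}
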