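# Shared fixtures, all generated in code.

# Gaussian PC scores with geometrically decaying eigenvalue spectrum,
# mimicking the principal-subspace summary of a feature bank.
make_scores <- function(n_images, n_pcs = 20, decay = 0.9, seed = 1) {
  vstream:::with_seed(seed, {
    ev <- decay^(seq_len(n_pcs) - 1)
    matrix(rnorm(n_images * n_pcs), n_images, n_pcs) %*% diag(3 * ev)
  })
}

# Poisson sparse-noise histogram drawn directly from a circular-Gaussian
# rate surface on the standard placement lattice.
sim_rf_histogram <- function(x0, y0, sigma, A, B, n_pres = 30,
                             lattice = c(32, 18), seed = 1) {
  az <- seq(-54, 54, length.out = lattice[1] + 1)[-1] - 54 / lattice[1]
  el <- seq(-38, 38, length.out = lattice[2] + 1)[-1] - 38 / lattice[2]
  g <- expand.grid(azimuth = az, elevation = el)
  mu <- B + A * exp(-((g$azimuth - x0)^2 + (g$elevation - y0)^2) / (2 * sigma^2))
  cnt <- vstream:::with_seed(seed, rpois(nrow(g), mu * n_pres))
  h <- data.frame(azimuth = g$azimuth, elevation = g$elevation,
                  count = cnt, n_pres = n_pres)
  class(h) <- c("rf_histogram", class(h))
  attr(h, "unit_id") <- 1L
  attr(h, "polarity") <- "ON"
  h
}

# units x images x repeats Poisson tensor around per-image mean rates
sim_tensor <- function(rates, n_repeats, seed = 1) {
  # rates: units x images matrix of mean counts per trial
  d <- dim(rates)
  vstream:::with_seed(seed,
    array(rpois(d[1] * d[2] * n_repeats, rates), c(d[1], d[2], n_repeats)))
}

# spike table with constant rate for n units over [0, t_end]
sim_constant_spikes <- function(n_units, rate_hz, t_end, seed = 1) {
  vstream:::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_units), function(u) {
      n <- rpois(1, rate_hz * t_end)
      data.frame(unit_id = u, area = "A", time_s = sort(runif(n, 0, t_end)),
                 amplitude = 100)
    }))
  })
}

# regular event table
sim_events <- function(n_events, duration_s = 0.167, isi_s = 0.167, t0 = 1,
                       class = "gratings", stim_id = NULL) {
  data.frame(stim_id = stim_id %||% seq_len(n_events), class = class,
             onset_s = t0 + (seq_len(n_events) - 1) * (duration_s + isi_s),
             duration_s = duration_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
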