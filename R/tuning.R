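#' Fit orientation tuning with a modified Von Mises curve
#'
#' Least-squares fit of `R(theta) = B + A * exp(kappa * (cos(2 * (theta -
#' theta_pref)) - 1))` to responses grouped by grating orientation, the
#' 0–180 degree orientation space being treated as the full period.  Fits
#' are multi-started at every tested orientation.  A cell is `included`
#' (counts as orientation tuned) when the fitted peak amplitude is at
#' least half the cell's average firing rate across all grating responses.
#'
#' @param responses Per-trial responses (rate or count).
#' @param orientations Orientation of each trial, degrees.
#' @return Object of class `orientation_fit`: `theta_pref` (degrees in
#'   `[0, 180)`), `kappa`, `A`, `B`, `included`.
#' @export
fit_orientation <- function(responses, orientations) {
  ok <- is.finite(responses) & is.finite(orientations)
  responses <- responses[ok]; orientations <- orientations[ok] %% 180
  if (length(unique(orientations)) < 4)
    stop("need at least 4 distinct orientations")
  mean_rate <- mean(responses)
  out <- list(theta_pref = NA_real_, kappa = NA_real_, A = 0,
              B = mean_rate, included = FALSE, mean_rate = mean_rate)
  class(out) <- "orientation_fit"
  if (stats::sd(responses) == 0) return(out)       # degenerate: flat
  th <- orientations * pi / 180
  model <- function(p) p["B"] + p["A"] * exp(p["kappa"] * (cos(2 * (th - p["th0"])) - 1))
  lower <- c(B = 0, A = 0, kappa = 0.01, th0 = -pi)
  upper <- c(B = Inf, A = Inf, kappa = 50, th0 = 2 * pi)
  best <- NULL
  lev <- sort(unique(orientations))
  lev_means <- vapply(lev, function(o) mean(responses[orientations == o]),
                      numeric(1))
  for (o in lev) {
    start <- c(B = max(min(lev_means), 1e-3),
               A = max(max(lev_means) - min(lev_means), 1e-3),
               kappa = 2, th0 = o * pi / 180)
    fit <- try(minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                                  fn = function(p) responses - model(p),
                                  control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !fit$info %in% 1:4) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(out)
  p <- best$par
  out$theta_pref <- (p[["th0"]] * 180 / pi) %% 180
  out$kappa <- p[["kappa"]]
  out$A <- p[["A"]]
  out$B <- p[["B"]]
  out$included <- out$A >= 0.5 * mean_rate
  out
}

#' @export
print.orientation_fit <- function(x, ...) {
  cat(sprintf("Orientation fit: pref %.1f deg, kappa %.2f, A %.2f, B %.2f, included %s\n",
              x$theta_pref, x$kappa, x$A, x$B, x$included))
  invisible(x)
}

#' Circular orientation error (period 180 degrees)
#'
#' @param a,b Orientations in degrees.
#' @return Absolute circular difference in `[0, 90]`.
#' @export
orientation_error <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Fit spatial-frequency tuning with a log-Gaussian
#'
#' Least-squares fit of `R(f) = B + A * exp(-(ln f - ln f_pref)^2 /
#' (2 sigma_f^2))` to responses grouped by grating spatial frequency.  The
#' preferred frequency is bounded to the tested range; a fit landing on a
#' range edge (monotone responses) is flagged `unbounded`.  The same
#' half-mean-rate inclusion rule as [fit_orientation] applies.
#'
#' @param responses Per-trial responses.
#' @param sfs Spatial frequency of each trial, cycles/degree.
#' @return Object of class `sf_fit`: `f_pref`, `log_sigma`, `A`, `B`,
#'   `included`, `unbounded`.
#' @export
fit_spatial_frequency <- function(responses, sfs) {
  ok <- is.finite(responses) & is.finite(sfs) & sfs > 0
  responses <- responses[ok]; sfs <- sfs[ok]
  if (length(unique(sfs)) < 3) stop("need at least 3 distinct spatial frequencies")
  mean_rate <- mean(responses)
  out <- list(f_pref = NA_real_, log_sigma = NA_real_, A = 0, B = mean_rate,
              included = FALSE, unbounded = FALSE, mean_rate = mean_rate)
  class(out) <- "sf_fit"
  if (stats::sd(responses) == 0) return(out)
  lf <- log(sfs)
  rng <- range(lf)
  model <- function(p) p["B"] + p["A"] * exp(-(lf - p["lf0"])^2 / (2 * p["sig"]^2))
  lower <- c(B = 0, A = 0, lf0 = rng[1], sig = 0.05)
  upper <- c(B = Inf, A = Inf, lf0 = rng[2], sig = 10)
  lev <- sort(unique(lf))
  lev_means <- vapply(lev, function(l) mean(responses[lf == l]), numeric(1))
  best <- NULL
  for (l0 in lev) {
    start <- c(B = max(min(lev_means), 1e-3),
               A = max(max(lev_means) - min(lev_means), 1e-3),
               lf0 = l0, sig = 0.7)
    fit <- try(minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                                  fn = function(p) responses - model(p),
                                  control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !fit$info %in% 1:4) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(out)
  p <- best$par
  out$f_pref <- exp(p[["lf0"]])
  out$log_sigma <- p[["sig"]]
  out$A <- p[["A"]]
  out$B <- p[["B"]]
  out$included <- out$A >= 0.5 * mean_rate
  out$unbounded <- p[["lf0"]] <= rng[1] + 1e-6 || p[["lf0"]] >= rng[2] - 1e-6
  out
}

#' @export
print.sf_fit <- function(x, ...) {
  cat(sprintf("Spatial-frequency fit: pref %.3f cpd, log-sigma %.2f, A %.2f, included %s%s\n",
              x$f_pref, x$log_sigma, x$A, x$included,
              if (isTRUE(x$unbounded)) " (unbounded)" else ""))
  invisible(x)
}

#' Percentage of response variance explained by a categorical variable
#'
#' Regresses trial responses onto a categorical variable with `k` levels
#' (`k - 1` additional degrees of freedom) and reports `100 * (V_total -
#' V_residual) / V_total`, where `V_total` is the variance of the trial
#' responses and `V_residual` the variance around the level means (both
#' population variances, divide by `n`).  At area scope, total and
#' residual variances are summed across all cells before normalizing, so
#' the result is the percentage of all variance in the area explained by
#' the variable rather than a per-cell average.
#'
#' @param responses For `scope = "cell"` a vector of trial responses; for
#'   `scope = "area"` a matrix cells x trials.
#' @param labels Categorical label per trial.
#' @param scope `"cell"` or `"area"`.
#' @return List of class `variance_decomposition`: `V_total`,
#'   `V_residual`, `pct_explained`, `k`, `scope`.
#' @export
variance_explained_categorical <- function(responses, labels,
                                           scope = c("cell", "area")) {
  scope <- match.arg(scope)
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < 2)) warning("some levels have fewer than 2 trials")
  one_cell <- function(x) {
    vt <- pop_var(x)
    lm_means <- stats::ave(x, labels, FUN = mean)
    vr <- mean((x - lm_means)^2)
    c(vt, vr)
  }
  if (scope == "cell") {
    stopifnot(is.numeric(responses), length(responses) == length(labels))
    v <- one_cell(responses)
  } else {
    stopifnot(is.matrix(responses), ncol(responses) == length(labels))
    vs <- t(apply(responses, 1, one_cell))
    v <- colSums(vs)
  }
  pct <- if (v[1] > 0) 100 * (v[1] - v[2]) / v[1] else NA_real_
  structure(list(V_total = v[1], V_residual = v[2], pct_explained = pct,
                 k = nlevels(labels), scope = scope),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Variance decomposition (%s scope, k = %d): %.1f%% explained\n",
              x$scope, x$k, x$pct_explained))
  invisible(x)
}

# Per-cell x per-trial counts in a sliding bin starting at `t0`.
bin_counts <- function(sp, events, t0, bin_s) {
  lo <- events$onset_s + t0; hi <- lo + bin_s
  t(vapply(sp, function(tt) count_in_windows(tt, lo, hi),
           numeric(nrow(events))))
}

#' Texture-versus-noise divergence latency
#'
#' Tracks the population response to naturalistic textures and to their
#' spectrally matched noise partners over time, and finds the latency at
#' which the two curves first differ significantly: per time bin, each
#' cell contributes its mean response to textures minus its mean response
#' to noise, and a paired two-tailed t-test across cells is evaluated at
#' `alpha` (no multiple-comparisons correction; an optional requirement of
#' `consecutive` significant bins is available).
#'
#' @param spikes Spike table.
#' @param events Texture/noise presentation events.
#' @param bank The [make_texture_bank] image bank (for category labels).
#' @param bin_s Time-bin width, seconds; default 0.01.
#' @param window Analysis window after onset; default `c(0, 0.25)`.
#' @param alpha Per-bin significance level; default 0.01.
#' @param consecutive Number of consecutive significant bins required;
#'   default 1.
#' @param units Unit ids; default all (>= 10 required).
#' @return Object of class `texture_divergence`: `time` (bin left edges),
#'   `mean_texture`, `mean_noise`, `se_texture`, `se_noise` (across-cell
#'   mean rates, Hz), `p` per bin, `divergence_latency` (s, `NA` if never
#'   significant).
#' @export
texture_divergence <- function(spikes, events, bank, bin_s = 0.01,
                               window = c(0, 0.25), alpha = 0.01,
                               consecutive = 1, units = NULL) {
  units <- units %||% sort(unique(spikes$unit_id))
  if (length(units) < 10) stop("need at least 10 cells in the area")
  idx <- match(events$stim_id, bank$image_ids)
  is_tex <- bank$category[idx] == "texture"
  is_noi <- bank$category[idx] == "noise"
  sp <- lapply(as.character(units), function(u)
    sort(spikes$time_s[spikes$unit_id == u]))
  t_edges <- seq(window[1], window[2] - bin_s, by = bin_s)
  nt <- length(t_edges)
  mt <- mn <- st <- sn <- pv <- numeric(nt)
  for (b in seq_len(nt)) {
    cc <- bin_counts(sp, events, t_edges[b], bin_s) / bin_s   # cells x trials, Hz
    ct <- rowMeans(cc[, is_tex, drop = FALSE])
    cn <- rowMeans(cc[, is_noi, drop = FALSE])
    mt[b] <- mean(ct); mn[b] <- mean(cn)
    st[b] <- stats::sd(ct) / sqrt(length(ct))
    sn[b] <- stats::sd(cn) / sqrt(length(cn))
    d <- ct - cn
    pv[b] <- if (stats::sd(d) > 0)
      stats::t.test(d, alternative = "two.sided")$p.value else 1
  }
  sig <- pv < alpha
  lat <- NA_real_
  if (consecutive > 1) {
    runs <- rle(sig)
    pos <- cumsum(c(1, runs$lengths))
    hit <- which(runs$values & runs$lengths >= consecutive)
    if (length(hit)) lat <- t_edges[pos[hit[1]]]
  } else if (any(sig)) lat <- t_edges[which(sig)[1]]
  structure(list(time = t_edges, mean_texture = mt, mean_noise = mn,
                 se_texture = st, se_noise = sn, p = pv,
                 divergence_latency = lat, alpha = alpha),
            class = "texture_divergence")
}

#' @export
print.texture_divergence <- function(x, ...) {
  cat(sprintf("Texture/noise divergence: latency %s (alpha = %g)\n",
              if (is.na(x$divergence_latency)) "undefined"
              else sprintf("%.0f ms", 1000 * x$divergence_latency), x$alpha))
  invisible(x)
}

#' Time course of variance explained by texture family
#'
#' Sliding-bin categorical variance decomposition (area scope) of trial
#' responses to texture images against the 15-level family label.
#'
#' @inheritParams texture_divergence
#' @return Data frame `time`, `pct_explained`.
#' @export
texture_family_variance_timecourse <- function(spikes, events, bank,
                                               bin_s = 0.01,
                                               window = c(0, 0.25),
                                               units = NULL) {
  units <- units %||% sort(unique(spikes$unit_id))
  idx <- match(events$stim_id, bank$image_ids)
  sel <- bank$category[idx] == "texture"
  fam <- bank$family[idx][sel]
  if (length(unique(fam)) < 2)
    stop("need at least 2 texture families (k >= 2)")
  ev <- events[sel, , drop = FALSE]
  sp <- lapply(as.character(units), function(u)
    sort(spikes$time_s[spikes$unit_id == u]))
  t_edges <- seq(window[1], window[2] - bin_s, by = bin_s)
  pct <- vapply(t_edges, function(t0) {
    cc <- bin_counts(sp, ev, t0, bin_s)
    variance_explained_categorical(cc, fam, scope = "area")$pct_explained
  }, numeric(1))
  data.frame(time = t_edges, pct_explained = pct)
}
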