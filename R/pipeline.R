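#' Configuration for an end-to-end pipeline run
#'
#' Bundles every tunable of the simulate-to-report pipeline with seeded
#' determinism: all stage seeds are derived from the single `seed`.
#' Defaults are sized for a demonstration run; the stimulus-design
#' defaults of the individual generators (120 grating conditions, 150
#' texture/noise images, 1,593 objects) are kept unless overridden here.
#'
#' @param seed Master seed; every source of randomness derives from it.
#' @param areas Area labels, posterior to anterior.
#' @param n_per_area Units per area.
#' @param n_objects,n_faces Object-bank composition.
#' @param n_families,samples_per_family Texture-bank composition.
#' @param image_shape Image raster size, pixels.
#' @param n_sparse_frames Sparse-noise frames.
#' @param grating_repeats,texture_repeats,object_repeats Presentation
#'   repeats per condition/image.
#' @param n_blocks Object presentation blocks.
#' @param layers Extractor layers.
#' @param n_pcs Feature principal components.
#' @param out_dim Extractor output dimension.
#' @param response_window,baseline_window Analysis windows, seconds.
#' @param threshold_sd Responsiveness threshold (SD).
#' @param rf_quality_threshold RF quality threshold.
#' @param n_cells_decode Cells per decoding resample.
#' @param n_resamples_decode PC-decoding resamples.
#' @param gnb_resamples `c(neuron, split)` resample counts for identity
#'   decoding.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            areas = c("V1", "V2", "TD", "TI", "TP"),
                            n_per_area = 40,
                            n_objects = 250, n_faces = 60,
                            n_families = 15, samples_per_family = 5,
                            image_shape = c(32, 32),
                            n_sparse_frames = 300,
                            grating_repeats = 5,
                            texture_repeats = 5,
                            object_repeats = 10,
                            n_blocks = 10,
                            layers = 1:3,
                            n_pcs = 50,
                            out_dim = 512,
                            response_window = c(0, 0.1),
                            baseline_window = c(-0.05, 0),
                            threshold_sd = 5,
                            rf_quality_threshold = 5,
                            n_cells_decode = 100,
                            n_resamples_decode = 5,
                            gnb_resamples = c(5, 5)) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage in dependency order on one simulated multi-area
#' session: stimulus/bank generation, feature extraction, spiking
#' simulation, responsiveness QC, receptive-field mapping, orientation /
#' spatial-frequency tuning, texture divergence, explainable variance and
#' preferred-axis fits, PC decoding with reconstruction, face selectivity
#' and identity decoding, and the hierarchy summary.  With a fixed config
#' (including its seed) the returned report is fully deterministic.
#'
#' @param config A [pipeline_config].
#' @param out_dir Optional directory; when given, per-stage CSV artifacts
#'   and a manifest are written there.
#' @return List of class `area_report` with one element per stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  s <- config$seed
  areas <- config$areas

  neurons <- make_ground_truth_neurons(
    n_per_area = config$n_per_area, areas = areas, n_pcs = config$n_pcs,
    n_blocks = config$n_blocks, seed = s + 1L)

  sn <- make_sparse_noise_schedule(n_frames = config$n_sparse_frames,
                                   seed = s + 2L)
  t_gr <- max(sn$frames$onset_s + sn$frames$duration_s) + 1
  gr <- make_grating_schedule(n_repeats = config$grating_repeats, t0 = t_gr,
                              seed = s + 3L)
  tb <- make_texture_bank(n_families = config$n_families,
                          samples_per_family = config$samples_per_family,
                          image_shape = config$image_shape,
                          repeats = config$texture_repeats, seed = s + 4L)
  t_tx <- max(gr$events$onset_s + gr$events$duration_s) + 1
  te <- make_presentation_schedule(tb, t0 = t_tx, blocked = FALSE,
                                   seed = s + 5L)
  ob <- make_object_bank(n_objects = config$n_objects, n_faces = config$n_faces,
                         image_shape = config$image_shape,
                         repeats = config$object_repeats, seed = s + 6L)
  t_ob <- max(te$onset_s + te$duration_s) + 1
  oe <- make_presentation_schedule(ob, t0 = t_ob, blocked = TRUE, seed = s + 7L)
  feats <- extract_features(ob, layers = config$layers, n_pcs = config$n_pcs,
                            out_dim = config$out_dim, seed = s + 8L)
  fb <- feats[[1]]

  sess <- simulate_session(neurons, sparse_noise = sn, gratings = gr,
                           textures = list(bank = tb, events = te),
                           objects = list(bank = ob, events = oe, features = fb),
                           seed = s + 9L)
  spikes <- sess$spikes
  ev <- sess$events

  # --- QC ---------------------------------------------------------------
  ev_gr <- ev[ev$class == "gratings", ]
  ev_tx <- ev[ev$class == "texture_noise", ]
  ev_ob <- ev[ev$class == "objects", ]
  resp <- list(
    gratings = test_responsive(spikes, ev_gr, config$threshold_sd,
                               config$response_window, config$baseline_window),
    texture_noise = test_responsive(spikes, ev_tx, config$threshold_sd,
                                    config$response_window, config$baseline_window),
    objects = test_responsive(spikes, ev_ob, config$threshold_sd,
                              config$response_window, config$baseline_window))
  vis <- responsive_any(resp$gratings, resp$texture_noise, resp$objects)
  lat <- half_peak_latency(spikes, rbind(ev_gr, ev_tx))
  blocks <- do.call(rbind, lapply(split(ev_ob, ev_ob$block), function(b)
    data.frame(block = b$block[1], start = min(b$onset_s),
               end = max(b$onset_s + b$duration_s))))
  stab <- filter_stable_blocks(spikes, blocks)

  # --- receptive fields --------------------------------------------------
  hists <- build_rf_histogram(spikes, sn)
  rf <- do.call(rbind, lapply(names(hists), function(u) {
    do.call(rbind, lapply(c("ON", "OFF"), function(p) {
      f <- fit_rf(hists[[u]][[p]], config$rf_quality_threshold)
      data.frame(unit_id = as.integer(u), polarity = p, x0 = f$x0, y0 = f$y0,
                 sigma_deg = f$sigma, A = f$A, B = f$B, Q = f$Q,
                 has_rf = f$has_rf, size_deg = f$size_deg)
    }))
  }))

  # --- tuning ------------------------------------------------------------
  tens_gr <- response_tensor(spikes, ev_gr, config$response_window)
  cond <- gr$conditions
  rate_gr <- tens_gr[, as.character(cond$condition_id), , drop = FALSE] /
    diff(config$response_window)
  units <- neurons$units
  tuning <- do.call(rbind, lapply(seq_len(nrow(units)), function(u) {
    rr <- as.vector(rate_gr[u, , ])
    oo <- rep(cond$orientation, dim(rate_gr)[3])
    ff <- rep(cond$spatial_frequency, dim(rate_gr)[3])
    of <- fit_orientation(rr, oo)
    sf <- fit_spatial_frequency(rr, ff)
    data.frame(unit_id = units$unit_id[u], theta_pref = of$theta_pref,
               kappa = of$kappa, ori_included = of$included,
               f_pref = sf$f_pref, sf_included = sf$included)
  }))

  # --- texture -----------------------------------------------------------
  tex <- lapply(areas, function(a) {
    uu <- units$unit_id[units$area == a]
    texture_divergence(spikes[spikes$unit_id %in% uu, ], ev_tx, tb,
                       units = uu)
  })
  names(tex) <- areas

  # --- axis model --------------------------------------------------------
  tens_ob <- response_tensor(spikes, ev_ob, config$response_window)
  expl <- explainable_variance(tens_ob)
  mm <- image_means(tens_ob)
  ids <- as.integer(dimnames(tens_ob)$stim)
  sc <- fb$pc_scores[match(ids, fb$image_ids), , drop = FALSE]
  axes <- lapply(seq_len(nrow(mm)), function(u)
    fit_preferred_axis(mm[u, ], sc, seed = s + 10L, min_images = 50))
  ev_cv <- vapply(axes, `[[`, numeric(1), "ev_cv")

  # --- decoding / reconstruction ----------------------------------------
  aux_bank <- make_object_bank(n_objects = max(500, config$n_objects),
                               n_faces = 0, image_shape = config$image_shape,
                               seed = s + 11L)
  aux_fb <- extract_features(aux_bank, layers = config$layers[1],
                             n_pcs = config$n_pcs, out_dim = config$out_dim,
                             seed = s + 8L)[[1]]
  recon <- lapply(areas, function(a) {
    uu <- which(units$area == a)
    area_reconstruction_summary(t(mm[uu, , drop = FALSE]),
                                bank_subset(fb, ids), aux_fb,
                                n_cells = min(config$n_cells_decode, length(uu)),
                                seed = s + 12L)
  })
  names(recon) <- areas
  decoding <- lapply(areas, function(a) {
    uu <- which(units$area == a)
    decode_pcs(t(mm[uu, , drop = FALSE]), sc,
               n_cells = min(config$n_cells_decode, length(uu)),
               n_resamples = config$n_resamples_decode, seed = s + 13L)
  })
  names(decoding) <- areas

  # --- selectivity -------------------------------------------------------
  is_face <- ob$category[match(ids, ob$image_ids)] == "face"
  sel <- face_selectivity(mm, is_face)
  sel$unit_id <- units$unit_id
  n_face_img <- sum(is_face)
  gnb <- lapply(areas, function(a) {
    uu <- which(units$area == a)
    gnb_identity_decoding(
      tens_ob[uu, is_face, , drop = FALSE],
      n_cells = min(config$n_cells_decode, length(uu)),
      n_images = min(201, n_face_img),
      n_neuron_resamples = config$gnb_resamples[1],
      n_split_resamples = config$gnb_resamples[2], seed = s + 14L)
  })
  names(gnb) <- areas

  # --- hierarchy ---------------------------------------------------------
  rf$area <- units$area[match(rf$unit_id, units$unit_id)]
  lat$area <- units$area[match(lat$unit_id, units$unit_id)]
  hier <- hierarchy_summary(rf, lat)

  report <- structure(list(
    config = config,
    responsiveness = resp, visually_responsive = vis,
    latency = lat, stability = stab, rf = rf, tuning = tuning,
    texture = tex, explainable = expl, ev_cv = ev_cv,
    decoding = decoding, reconstruction = recon,
    selectivity = sel, identity_decoding = gnb,
    hierarchy = hier), class = "area_report")

  if (!is.null(out_dir)) write_report(report, out_dir, sess)
  report
}

# subset a feature bank to a set of image ids (keeps the PC summary)
bank_subset <- function(fb, ids) {
  idx <- match(ids, fb$image_ids)
  out <- fb
  out$features <- fb$features[idx, , drop = FALSE]
  out$pc_scores <- fb$pc_scores[idx, , drop = FALSE]
  out$image_ids <- fb$image_ids[idx]
  out
}

write_report <- function(report, out_dir, sess = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files[[name]] <<- unname(tools::md5sum(p))
  }
  wr(do.call(rbind, report$responsiveness), "responsiveness.csv")
  wr(report$visually_responsive, "visually_responsive.csv")
  wr(report$latency, "latency.csv")
  wr(report$stability, "stability.csv")
  wr(report$rf, "rf.csv")
  wr(report$tuning, "tuning.csv")
  wr(report$selectivity, "selectivity.csv")
  wr(report$hierarchy$table, "hierarchy.csv")
  if (!is.null(sess)) {
    write_spike_table(sess$spikes, file.path(out_dir, "spikes.csv"))
    write_event_table(sess$events, file.path(out_dir, "events.csv"))
  }
  jsonlite::write_json(list(seed = report$config$seed, files = files),
                       file.path(out_dir, "MANIFEST.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.area_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  visually responsive: %d / %d units\n",
              sum(x$visually_responsive$responsive_any),
              nrow(x$visually_responsive)))
  print(x$hierarchy)
  invisible(x)
}

#' Hierarchy summary from receptive-field sizes and latencies
#'
#' Per-area medians of receptive-field size (ON and OFF separately and
#' combined) and half-peak latency, with the Spearman rank correlation
#' between the two area orderings.  Areas without any fitted receptive
#' field are excluded from the size ranking and noted.
#'
#' @param rf Data frame with `area`, `polarity`, `size_deg`, `has_rf`.
#' @param latency Data frame with `area`, `latency_s`.
#' @return Object of class `hierarchy_summary`: `table` (per area),
#'   `rank_correlation`, `excluded_areas`.
#' @export
hierarchy_summary <- function(rf, latency) {
  areas <- union(unique(as.character(rf$area)),
                 unique(as.character(latency$area)))
  if (length(areas) < 1) stop("no areas supplied")
  tab <- do.call(rbind, lapply(areas, function(a) {
    r <- rf[rf$area == a & rf$has_rf %in% TRUE, ]
    l <- latency[latency$area == a & is.finite(latency$latency_s), ]
    data.frame(
      area = a,
      median_size_on = stats::median(r$size_deg[r$polarity == "ON"]),
      median_size_off = stats::median(r$size_deg[r$polarity == "OFF"]),
      median_size = if (nrow(r)) stats::median(r$size_deg) else NA_real_,
      n_rf = nrow(r),
      median_latency_s = if (nrow(l)) stats::median(l$latency_s) else NA_real_,
      n_latency = nrow(l))
  }))
  excluded <- tab$area[tab$n_rf == 0]
  ok <- is.finite(tab$median_size) & is.finite(tab$median_latency_s)
  rc <- if (sum(ok) >= 2)
    stats::cor(tab$median_size[ok], tab$median_latency_s[ok],
               method = "spearman") else NA_real_
  structure(list(table = tab, rank_correlation = rc,
                 excluded_areas = excluded),
            class = "hierarchy_summary")
}

#' @export
print.hierarchy_summary <- function(x, ...) {
  cat("Hierarchy summary (median RF size vs latency):\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  Spearman rank correlation: %s\n",
              ifelse(is.na(x$rank_correlation), "undefined",
                     sprintf("%.2f", x$rank_correlation))))
  if (length(x$excluded_areas))
    cat("  excluded from size ranking (no RFs):",
        paste(x$excluded_areas, collapse = ", "), "\n")
  invisible(x)
}
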