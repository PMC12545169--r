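#' Low-level image indices
#'
#' Computes 13 scalar low-level descriptors per image, used as controls
#' against feature/identity coding.  The documented, versioned default
#' set (v1) is: mean luminance; RMS contrast; Michelson contrast;
#' foreground area (fraction of pixels deviating from the border-median
#' background by more than 0.1); foreground perimeter (4-neighbour
#' boundary pixel fraction); compactness (`4 pi area / perimeter^2` in
#' pixel units); bounding-box aspect ratio; foreground centroid x and y
#' (normalized to `[0, 1]`); spectral centroid and spectral bandwidth
#' (amplitude-weighted mean and SD of radial frequency, DC excluded);
#' orientation anisotropy (resultant length of spectral energy over
#' doubled orientation); and edge density (mean gradient magnitude).
#'
#' @param bank An [image_bank].
#' @return Matrix images x 13 with named columns; attribute
#'   `"version" = "v1"`.
#' @export
lowlevel_indices <- function(bank) {
  stopifnot(inherits(bank, "image_bank"))
  n <- n_images(bank)
  h <- dim(bank$pixels)[1]; w <- dim(bank$pixels)[2]
  fx <- (seq_len(w) - 1) / w; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  fy <- (seq_len(h) - 1) / h; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  FX <- matrix(fx, h, w, byrow = TRUE); FY <- matrix(fy, h, w)
  rad <- sqrt(FX^2 + FY^2); ang <- atan2(FY, FX)
  nz <- rad > 0
  out <- matrix(NA_real_, n, 13)
  colnames(out) <- c("mean_luminance", "rms_contrast", "michelson_contrast",
                     "foreground_area", "perimeter", "compactness",
                     "aspect_ratio", "centroid_x", "centroid_y",
                     "spectral_centroid", "spectral_bandwidth",
                     "orientation_anisotropy", "edge_density")
  for (i in seq_len(n)) {
    img <- bank$pixels[, , i]
    lum <- mean(img); rmsc <- stats::sd(img)
    mich <- if (max(img) + min(img) > 0)
      (max(img) - min(img)) / (max(img) + min(img)) else 0
    border <- c(img[1, ], img[h, ], img[, 1], img[, w])
    bg <- stats::median(border)
    fg <- abs(img - bg) > 0.1
    area <- mean(fg)
    if (any(fg)) {
      # 4-neighbour boundary pixels
      pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- fg
      interior <- pad[2:(h + 1), 2:(w + 1)] & pad[1:h, 2:(w + 1)] &
        pad[3:(h + 2), 2:(w + 1)] & pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
      per_px <- sum(fg & !interior)
      perim <- per_px / (h * w)
      comp <- if (per_px > 0) 4 * pi * sum(fg) / per_px^2 else NA_real_
      rc <- which(fg, arr.ind = TRUE)
      bb_w <- diff(range(rc[, 2])) + 1; bb_h <- diff(range(rc[, 1])) + 1
      aspect <- bb_w / bb_h
      cx <- mean(rc[, 2]) / w; cy <- mean(rc[, 1]) / h
    } else {
      perim <- 0; comp <- NA_real_; aspect <- 1; cx <- 0.5; cy <- 0.5
    }
    amp <- Mod(stats::fft(img)); amp[1, 1] <- 0
    wsum <- sum(amp[nz])
    sc <- sum(amp[nz] * rad[nz]) / wsum
    sb <- sqrt(sum(amp[nz] * (rad[nz] - sc)^2) / wsum)
    oa <- Mod(sum(amp[nz]^2 * exp(2i * ang[nz]))) / sum(amp[nz]^2)
    gx <- img[, -1] - img[, -w]; gy <- img[-1, ] - img[-h, ]
    ed <- (mean(abs(gx)) + mean(abs(gy))) / 2
    out[i, ] <- c(lum, rmsc, mich, area, perim, comp, aspect, cx, cy,
                  sc, sb, oa, ed)
  }
  attr(out, "version") <- "v1"
  out
}

#' Partition images into spectral-frequency groups
#'
#' Rank-based split of a bank's images into `n_groups` groups by spectral
#' centroid; group sizes differ by at most one.
#'
#' @param indices Matrix from [lowlevel_indices].
#' @param n_groups Number of groups; default 7.
#' @return Integer group label per image.
#' @export
spectral_groups <- function(indices, n_groups = 7) {
  r <- rank(indices[, "spectral_centroid"], ties.method = "first")
  as.integer(ceiling(r * n_groups / length(r)))
}

# fraction of a response vector's variance explained by a single
# continuous regressor (population-variance convention)
simple_reg_var <- function(y, x) {
  vt <- pop_var(y)
  if (!is.finite(vt) || vt == 0) return(c(vt = vt, vr = vt))
  fit <- stats::lm.fit(cbind(1, x), y)
  c(vt = vt, vr = mean(fit$residuals^2))
}

#' Low-level-feature control analyses
#'
#' Three controls against low-level confounds of feature/identity coding:
#' (a) for each low-level index, the percentage of response variance it
#' explains by simple regression, aggregated at area scope (summing total
#' and residual variances across cells before normalizing); (b) for cells
#' with a mapped receptive field, the variance explained by luminance and
#' contrast computed inside the RF (pixels Gaussian-weighted by the
#' fitted RF profile, the image covering `image_extent_deg` of visual
#' field centred on the RF); (c) the percentage of variance explained by
#' image identity within each of `n_groups` spectral-centroid groups.
#'
#' @param tensor Units x images x repeats response array.
#' @param bank The presented [image_bank].
#' @param indices Optional precomputed [lowlevel_indices] matrix.
#' @param rf_fits Optional list of `rf_fit` objects (one per unit, `NA`
#'   or missing entries allowed) for variant (b).
#' @param image_extent_deg Visual-field extent covered by the image;
#'   default 20.
#' @param n_groups Spectral groups; default 7.
#' @return List of class `lowlevel_controls`: `per_index` (data frame
#'   `index`, `pct_explained`), `rf_windowed` (data frame per unit:
#'   `unit_id`, `pct_luminance`, `pct_contrast`; `NULL` without RF fits),
#'   `n_excluded_no_rf`, `identity_by_group` (data frame `group`, `n_images`,
#'   `pct_identity`).
#' @export
lowlevel_variance_controls <- function(tensor, bank, indices = NULL,
                                       rf_fits = NULL,
                                       image_extent_deg = 20,
                                       n_groups = 7) {
  indices <- indices %||% lowlevel_indices(bank)
  mm <- image_means(tensor)                      # units x images
  n_units <- nrow(mm)
  # (a) per-index area-scope variance explained
  per_index <- vapply(colnames(indices), function(nm) {
    x <- indices[, nm]
    ok <- is.finite(x)
    vs <- t(vapply(seq_len(n_units), function(u)
      simple_reg_var(mm[u, ok], x[ok]), numeric(2)))
    100 * (sum(vs[, 1]) - sum(vs[, 2])) / sum(vs[, 1])
  }, numeric(1))
  per_index <- data.frame(index = colnames(indices),
                          pct_explained = unname(per_index))
  # (b) RF-windowed luminance/contrast
  rf_windowed <- NULL; n_excluded <- 0L
  if (!is.null(rf_fits)) {
    h <- dim(bank$pixels)[1]; w <- dim(bank$pixels)[2]
    px_per_deg <- w / image_extent_deg
    rows <- list()
    for (u in seq_len(n_units)) {
      f <- rf_fits[[u]]
      if (is.null(f) || !isTRUE(f$has_rf)) { n_excluded <- n_excluded + 1L; next }
      # image centred on the RF: Gaussian weight centred mid-image
      sig_px <- f$sigma * px_per_deg
      gx <- matrix(seq_len(w) - (w + 1) / 2, h, w, byrow = TRUE)
      gy <- matrix(seq_len(h) - (h + 1) / 2, h, w)
      wt <- exp(-(gx^2 + gy^2) / (2 * sig_px^2)); wt <- wt / sum(wt)
      lum <- apply(bank$pixels, 3, function(img) sum(wt * img))
      con <- vapply(seq_len(n_images(bank)), function(i) {
        img <- bank$pixels[, , i]
        sqrt(sum(wt * (img - lum[i])^2))
      }, numeric(1))
      vs <- simple_reg_var(mm[u, ], lum)
      vc <- simple_reg_var(mm[u, ], con)
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = rownames(mm)[u] %||% u,
        pct_luminance = 100 * (vs[1] - vs[2]) / vs[1],
        pct_contrast = 100 * (vc[1] - vc[2]) / vc[1])
    }
    rf_windowed <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  # (c) identity variance within spectral groups
  grp <- spectral_groups(indices, n_groups)
  d <- dim(tensor)
  identity_by_group <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    imgs <- which(grp == g)
    sub <- tensor[, imgs, , drop = FALSE]
    flat <- matrix(sub, d[1], length(imgs) * d[3])   # trials = image x repeat
    labs <- rep(imgs, times = d[3])
    ok <- colSums(is.na(flat)) == 0
    vd <- variance_explained_categorical(flat[, ok, drop = FALSE], labs[ok],
                                         scope = "area")
    data.frame(group = g, n_images = length(imgs),
               pct_identity = vd$pct_explained)
  }))
  structure(list(per_index = per_index, rf_windowed = rf_windowed,
                 n_excluded_no_rf = n_excluded,
                 identity_by_group = identity_by_group),
            class = "lowlevel_controls")
}

#' @export
print.lowlevel_controls <- function(x, ...) {
  cat("Low-level controls: top indices by % variance explained\n")
  print(utils::head(x$per_index[order(-x$per_index$pct_explained), ], 5),
        row.names = FALSE)
  invisible(x)
}
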