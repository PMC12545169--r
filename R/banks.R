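#' Image bank container
#'
#' A light container for a set of grayscale images with category labels.
#'
#' @param pixels Numeric array `H x W x N`, values in `[0, 1]`.
#' @param category Character vector length `N` with values in
#'   `face`, `object`, `texture`, `noise`.
#' @param family Optional integer texture-family label per image (`NA`
#'   otherwise).
#' @param repeats Planned presentation count per image.
#' @param image_ids Integer ids; default `1:N`.
#' @return Object of class `image_bank`.
#' @export
image_bank <- function(pixels, category, family = NULL, repeats = 1L,
                       image_ids = NULL) {
  stopifnot(length(dim(pixels)) == 3)
  n <- dim(pixels)[3]
  stopifnot(length(category) == n)
  image_ids <- image_ids %||% seq_len(n)
  if (anyDuplicated(image_ids)) stop("image ids must be unique")
  structure(list(
    image_ids = as.integer(image_ids),
    pixels = pixels,
    category = as.character(category),
    family = if (is.null(family)) rep(NA_integer_, n) else as.integer(family),
    repeats = rep_len(as.integer(repeats), n)
  ), class = "image_bank")
}

#' @export
print.image_bank <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Image bank: %d images (%d x %d px)\n", d[3], d[1], d[2]))
  print(table(x$category))
  invisible(x)
}

n_images <- function(bank) dim(bank$pixels)[3]

check_image_shape <- function(image_shape) {
  if (length(image_shape) != 2 || image_shape[1] != image_shape[2])
    stop("image_shape must be square (H == W)")
  if (image_shape[1] < 16)
    stop("image_shape must be at least 16 x 16 pixels")
}

# Phase-scramble a real image: keep the Fourier amplitude spectrum, replace
# phases by those of a random real field (so Hermitian symmetry, hence a real
# result, is preserved exactly).  The DC phase of a positive-mean field is 0,
# so the mean is preserved too.
phase_scramble <- function(img) {
  f <- stats::fft(img)
  r <- matrix(stats::runif(length(img)), nrow(img), ncol(img))
  fr <- stats::fft(r)
  scr <- Mod(f) * exp(1i * Arg(fr))
  Re(stats::fft(scr, inverse = TRUE)) / length(img)
}

#' Generate a naturalistic-texture bank with spectrally matched noise
#'
#' Textures are organized as families of closely related samples (default 15
#' families x 5 samples).  Each family is defined by a shared Fourier-domain
#' recipe: an oriented band-pass amplitude mask spanning two radial
#' frequency bands with aligned phases across scales, plus a family phase
#' template; samples within a family share the recipe and differ only by a
#' moderate phase jitter, so within-family images are pixel-correlated.  For
#' every texture image a spectrally matched noise partner is produced by
#' Fourier phase scrambling (identical amplitude spectrum, randomized
#' phases), destroying the higher-order structure while preserving the
#' power spectrum.  Each texture/noise pair is mapped to `[0, 1]` by one
#' shared affine transform so the spectral match is exact.
#'
#' @param n_families Number of texture families (default 15).
#' @param samples_per_family Samples per family (default 5).
#' @param image_shape `(H, W)` in pixels; must be square and >= 16.
#' @param repeats Planned presentations per image (default 5).
#' @param seed Integer seed.
#' @return An [image_bank] with `2 * n_families * samples_per_family`
#'   images; texture image `i` and noise image `i + n_textures` are
#'   spectrally matched partners sharing the family label.
#' @export
make_texture_bank <- function(n_families = 15, samples_per_family = 5,
                              image_shape = c(64, 64), repeats = 5L,
                              seed = 1L) {
  stopifnot(n_families >= 1, samples_per_family >= 1)
  check_image_shape(image_shape)
  h <- image_shape[1]; w <- image_shape[2]
  # centred frequency coordinates
  fx <- (seq_len(w) - 1) / w; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  fy <- (seq_len(h) - 1) / h; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  FX <- matrix(fx, h, w, byrow = TRUE)
  FY <- matrix(fy, h, w)
  rad <- sqrt(FX^2 + FY^2)
  ang <- atan2(FY, FX)

  n_tex <- n_families * samples_per_family
  with_seed(seed, {
    tex <- array(0, c(h, w, n_tex))
    noi <- array(0, c(h, w, n_tex))
    fam_lab <- integer(n_tex)
    k <- 0L
    for (fam in seq_len(n_families)) {
      theta <- stats::runif(1, 0, pi)
      f0 <- stats::runif(1, 0.06, 0.18)          # base band, cycles/px
      sig_t <- stats::runif(1, 0.25, 0.5)        # orientation bandwidth, rad
      # two radial bands an octave apart, cross-scale phase alignment:
      # both bands share the same family phase template
      dtheta <- atan2(sin(2 * (ang - theta)), cos(2 * (ang - theta))) / 2
      mask <- exp(-dtheta^2 / (2 * sig_t^2)) *
        (exp(-(log(pmax(rad, 1e-6) / f0))^2 / 0.18) +
         exp(-(log(pmax(rad, 1e-6) / (2 * f0)))^2 / 0.18))
      phase_fam <- Arg(stats::fft(matrix(stats::runif(h * w), h, w)))
      for (s in seq_len(samples_per_family)) {
        k <- k + 1L
        jit <- Arg(stats::fft(matrix(stats::runif(h * w), h, w)))
        phase <- phase_fam + 0.45 * jit
        raw <- Re(stats::fft(mask * exp(1i * phase), inverse = TRUE)) / (h * w)
        raw <- raw - min(raw) + 0.5     # positive mean before scrambling
        part <- phase_scramble(raw)
        lo <- min(raw, part); hi <- max(raw, part)
        tex[, , k] <- (raw - lo) / (hi - lo)
        noi[, , k] <- (part - lo) / (hi - lo)
        fam_lab[k] <- fam
      }
    }
    pixels <- array(c(tex, noi), c(h, w, 2L * n_tex))
    image_bank(pixels,
               category = rep(c("texture", "noise"), each = n_tex),
               family = rep(fam_lab, 2L),
               repeats = repeats)
  })
}

# Rasterize a filled star-shaped region r(phi) = r0 * (1 + sum a_k cos(k phi
# + psi_k)) on a pixel grid in [-1, 1]^2; returns values in [0, 1].
blob_raster <- function(h, w, r0, a, psi, cx = 0, cy = 0, fill = 0.85) {
  x <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE) - cx
  y <- matrix(seq(-1, 1, length.out = h), h, w) - cy
  phi <- atan2(y, x)
  r <- sqrt(x^2 + y^2)
  rb <- r0 * (1 + Reduce(`+`, lapply(seq_along(a), function(k)
    a[k] * cos(k * phi + psi[k]))))
  img <- matrix(0.05, h, w)
  img[r <= pmax(rb, 0.02)] <- fill
  img
}

#' Generate a procedural object/face image bank
#'
#' Objects are random filled blob silhouettes (star-shaped polygons with
#' random radial harmonics, position, size and grey level).  Faces use a
#' distinct recipe — an oval outline with interior parts (two eyes, nose,
#' mouth) at roughly conserved positions — so that faces form a coherent
#' cluster in any reasonable feature space without the cluster being
#' injected into the features directly.  Defaults match the standard
#' stimulus set: 1,392 objects plus 201 faces = 1,593 images, 10 planned
#' repeats each.
#'
#' @param n_objects,n_faces Image counts (>= 0).
#' @param image_shape `(H, W)` pixels, square, >= 16.
#' @param repeats Planned presentations per image (default 10).
#' @param seed Integer seed.
#' @return An [image_bank] with categories `object` and `face`.
#' @export
make_object_bank <- function(n_objects = 1392, n_faces = 201,
                             image_shape = c(64, 64), repeats = 10L,
                             seed = 1L) {
  stopifnot(n_objects >= 0, n_faces >= 0, n_objects + n_faces > 0)
  check_image_shape(image_shape)
  h <- image_shape[1]; w <- image_shape[2]
  x01 <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
  y01 <- matrix(seq(0, 1, length.out = h), h, w)
  with_seed(seed, {
    n <- n_objects + n_faces
    pixels <- array(0, c(h, w, n))
    for (i in seq_len(n_objects)) {
      nh <- sample(2:5, 1)
      pixels[, , i] <- blob_raster(
        h, w,
        r0 = stats::runif(1, 0.25, 0.55),
        a = stats::runif(nh, 0.05, 0.35) / seq_len(nh),
        psi = stats::runif(nh, 0, 2 * pi),
        cx = stats::runif(1, -0.25, 0.25),
        cy = stats::runif(1, -0.25, 0.25),
        fill = stats::runif(1, 0.45, 0.95)
      )
    }
    for (j in seq_len(n_faces)) {
      i <- n_objects + j
      # oval head
      ecc <- stats::runif(1, 1.15, 1.45)
      rx <- stats::runif(1, 0.32, 0.42); ry <- rx * ecc
      cx <- stats::runif(1, -0.08, 0.08); cy <- stats::runif(1, -0.08, 0.08)
      xn <- (2 * x01 - 1 - cx) / rx; yn <- (2 * y01 - 1 - cy) / ry
      img <- matrix(0.05, h, w)
      img[xn^2 + yn^2 <= 1] <- stats::runif(1, 0.6, 0.8)
      # interior parts in head coordinates
      eye_y <- stats::runif(1, -0.42, -0.3); eye_dx <- stats::runif(1, 0.3, 0.45)
      eye_r <- stats::runif(1, 0.1, 0.16)
      img[((xn - eye_dx)^2 + (yn - eye_y)^2) <= eye_r^2] <- 0.1
      img[((xn + eye_dx)^2 + (yn - eye_y)^2) <= eye_r^2] <- 0.1
      img[(abs(xn) <= 0.08) & (yn > -0.05) & (yn < stats::runif(1, 0.15, 0.3))] <- 0.3
      mouth_y <- stats::runif(1, 0.45, 0.6)
      img[(abs(xn) <= stats::runif(1, 0.25, 0.4)) & (abs(yn - mouth_y) <= 0.07)] <- 0.15
      pixels[, , i] <- img
    }
    image_bank(pixels,
               category = c(rep("object", n_objects), rep("face", n_faces)),
               repeats = repeats)
  })
}
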