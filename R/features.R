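#' Feature bank container
#'
#' Features of a set of images in one "layer" of an extractor, together
#' with a principal-subspace summary: an orthonormal loading matrix
#' (`pc_basis`, `D x n_pcs`), the feature mean (`pc_mean`), and scores
#' `pc_scores = (features - pc_mean) %*% pc_basis`.
#'
#' @param layer_name Label of the layer.
#' @param features `N x D` matrix of image features.
#' @param n_pcs Number of principal components (default 50, reduced when
#'   rank-limited).
#' @param image_ids Optional ids matching the source bank.
#' @return Object of class `feature_bank`.
#' @export
feature_bank <- function(features, layer_name = "layer1", n_pcs = 50,
                         image_ids = NULL) {
  stopifnot(is.matrix(features))
  n <- nrow(features)
  n_pcs <- min(n_pcs, n - 1L, ncol(features))
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = n_pcs)
  structure(list(
    layer_name = layer_name,
    features = features,
    pc_basis = pc$rotation,
    pc_mean = pc$center,
    pc_scores = pc$x,
    sdev = pc$sdev,
    image_ids = image_ids %||% seq_len(n)
  ), class = "feature_bank")
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("Feature bank '%s': %d images x %d features, %d PCs\n",
              x$layer_name, nrow(x$features), ncol(x$features),
              ncol(x$pc_basis)))
  invisible(x)
}

# Gabor patch on an n x n grid: orientation theta, frequency f (cycles/px),
# phase ph, Gaussian envelope centred at (cx, cy) with sd sigma (px units).
gabor_patch <- function(n, theta, f, ph, cx, cy, sigma) {
  x <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  y <- matrix(seq_len(n), n, n) - cy
  u <- x * cos(theta) + y * sin(theta)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2)) * cos(2 * pi * f * u + ph)
  g - mean(g)
}

# Block-average pooling of an H x W x N stack by integer factor p.
pool_stack <- function(px, p) {
  if (p == 1L) return(px)
  d <- dim(px)
  h2 <- d[1] %/% p; w2 <- d[2] %/% p
  px <- px[seq_len(h2 * p), seq_len(w2 * p), , drop = FALSE]
  dim(px) <- c(p, h2, p, w2, d[3])
  out <- apply(px, c(2, 4, 5), mean)
  out
}

#' Extract image features with a pluggable extractor
#'
#' The built-in extractor (`"builtin-gabor-random"`) is a deterministic
#' stack: a fixed bank of Gabor filters (4 orientations x 2 spatial
#' frequencies x 2 phases on a grid of spatial envelopes) is applied to the
#' image, responses are rectified, and a seeded random linear readout maps
#' them to a `D`-dimensional feature vector per layer.  Deeper layers see
#' the image average-pooled over progressively larger windows, so effective
#' receptive fields grow monotonically across layers.  Each layer's
#' features are summarized by their leading principal components
#' (orthonormal loadings, default 50).
#'
#' An `"external-dnn"` extractor can be plugged in by passing a function
#' `function(pixels, layer) -> N x D matrix` via `extractor_fun`.
#'
#' @param bank An [image_bank].
#' @param extractor `"builtin-gabor-random"` (default) or `"external-dnn"`.
#' @param layers Integer vector of layer indices (pooling depth); default
#'   `1:3`.
#' @param n_pcs Principal components per layer (default 50).
#' @param out_dim Output feature dimension D (default 4096).
#' @param seed Seed for the random readout; fixed seed gives bit-identical
#'   features.
#' @param extractor_fun Required when `extractor = "external-dnn"`.
#' @return Named list of [feature_bank] objects, one per layer.
#' @export
extract_features <- function(bank, extractor = "builtin-gabor-random",
                             layers = 1:3, n_pcs = 50, out_dim = 4096,
                             seed = 1L, extractor_fun = NULL) {
  stopifnot(inherits(bank, "image_bank"))
  known <- c("builtin-gabor-random", "external-dnn")
  if (!extractor %in% known)
    stop(sprintf("unknown extractor '%s'; available: %s",
                 extractor, paste(known, collapse = ", ")))
  if (extractor == "external-dnn") {
    if (!is.function(extractor_fun))
      stop("extractor 'external-dnn' requires extractor_fun(pixels, layer)")
    out <- lapply(layers, function(l) {
      feature_bank(extractor_fun(bank$pixels, l),
                   layer_name = paste0("layer", l), n_pcs = n_pcs,
                   image_ids = bank$image_ids)
    })
    names(out) <- paste0("layer", layers)
    return(out)
  }

  out <- vector("list", length(layers))
  names(out) <- paste0("layer", layers)
  for (li in seq_along(layers)) {
    l <- layers[li]
    pooled <- pool_stack(bank$pixels, 2L^(l - 1L))
    d <- dim(pooled)
    n <- min(d[1], d[2])
    npix <- d[1] * d[2]
    # fixed Gabor bank: 3 x 3 envelope centres, 4 orientations, 2 freqs,
    # 2 phases -> 144 filters.  Filter size is fixed in *pooled* pixels, so
    # in image coordinates the effective receptive field doubles per layer.
    centres <- seq(0.25, 0.75, length.out = 3) * n
    filt <- list()
    for (cx in centres) for (cy in centres)
      for (th in (0:3) * pi / 4)
        for (f in c(0.15, 0.3))
          for (ph in c(0, pi / 2))
            filt[[length(filt) + 1L]] <-
              gabor_patch(n, th, f, ph, cx, cy, sigma = max(n / 10, 2.5))
    G <- vapply(filt, function(g) as.vector(g[seq_len(d[1]), seq_len(d[2])]),
                numeric(npix))
    imgs <- matrix(pooled, nrow = npix, ncol = d[3])
    resp <- pmax(crossprod(imgs, G), 0)          # N x n_filters, rectified
    W <- with_seed(seed + l, matrix(stats::rnorm(ncol(G) * out_dim,
                                                 sd = 1 / sqrt(ncol(G))),
                                    ncol(G), out_dim))
    feats <- resp %*% W
    out[[li]] <- feature_bank(feats, layer_name = paste0("layer", l),
                              n_pcs = n_pcs, image_ids = bank$image_ids)
  }
  out
}
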