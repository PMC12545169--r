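#' Split-half explainable variance (Spearman–Brown)
#'
#' Upper bound on the stimulus-driven fraction of response variance,
#' estimated as the split-half reliability of per-image mean responses:
#' repeats are split into two halves (odd/even repeat indices by default,
#' or a seeded random split), `rho` is the Pearson correlation across
#' images between the two half-means, and the explainable variance is the
#' Spearman–Brown corrected value `2 rho / (1 + rho)`, clamped to
#' `[0, 1]` (the raw value is retained for audit).
#'
#' @param tensor Response array units x images x repeats (>= 2 repeats).
#' @param split `"odd_even"` (default) or `"random"`.
#' @param seed Seed for the random split.
#' @return Data frame per unit: `unit_id`, `rho`, `explainable`,
#'   `explainable_raw`.
#' @export
explainable_variance <- function(tensor, split = c("odd_even", "random"),
                                 seed = 1L) {
  split <- match.arg(split)
  n_rep <- dim(tensor)[3]
  if (n_rep < 2) stop("need at least 2 repeats per image")
  idx <- seq_len(n_rep)
  half1 <- if (split == "odd_even") idx[idx %% 2 == 1L]
           else with_seed(seed, sample(idx, floor(n_rep / 2)))
  half2 <- setdiff(idx, half1)
  m1 <- apply(tensor[, , half1, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  m2 <- apply(tensor[, , half2, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  units <- dimnames(tensor)[[1]] %||% seq_len(dim(tensor)[1])
  res <- vapply(seq_len(nrow(m1)), function(u) {
    if (stats::sd(m1[u, ]) == 0 || stats::sd(m2[u, ]) == 0)
      return(c(NA_real_, NA_real_, NA_real_))
    rho <- stats::cor(m1[u, ], m2[u, ])
    sb <- 2 * rho / (1 + rho)
    c(rho, min(max(sb, 0), 1), sb)
  }, numeric(3))
  data.frame(unit_id = units, rho = res[1, ], explainable = res[2, ],
             explainable_raw = res[3, ])
}

#' Spearman–Brown correction
#'
#' @param rho Split-half Pearson correlation.
#' @param clamp Clamp the result to `[0, 1]` (default `TRUE`).
#' @return `2 rho / (1 + rho)`.
#' @export
spearman_brown <- function(rho, clamp = TRUE) {
  sb <- 2 * rho / (1 + rho)
  if (clamp) pmin(pmax(sb, 0), 1) else sb
}

ols_axis <- function(X, y) {
  Xc <- cbind(1, X)
  fit <- stats::lm.fit(Xc, y)
  beta <- fit$coefficients[-1]
  if (anyNA(beta)) {
    # rank-deficient design: ridge fallback with a small trace-scaled penalty
    XtX <- crossprod(X)
    lam <- 1e-6 * sum(diag(XtX))
    beta <- solve(XtX + lam * diag(ncol(X)),
                  crossprod(X, y - mean(y)))[, 1]
  }
  beta
}

#' Estimate a unit's preferred axis in feature space
#'
#' Finds the direction in the reduced feature space (default 50 principal
#' components) whose 1-D linear projection captures the largest fraction
#' of variance of the unit's per-image mean responses — operationalized as
#' the unit-normalized ordinary-least-squares coefficient vector of the
#' response on the PC scores.  Estimation is 10-fold cross-validated over
#' images: each fold's axis is fitted on the other 90% of images and the
#' held-out images' projections onto it are recorded, so every image gets
#' exactly one projection from a fold that excluded it.  Fold axes are
#' sign-aligned to the first fold's (ties resolved toward a positive
#' first coordinate) and averaged, then renormalized, giving the overall
#' preferred axis.  `ev_cv` is the squared Pearson correlation between
#' held-out projections and responses.
#'
#' @param responses Per-image mean responses (length N >= 100 by default).
#' @param pc_scores N x D matrix of feature PC scores (not whitened).
#' @param n_folds Number of CV folds; default 10.
#' @param seed Seed for the fold assignment.
#' @param min_images Minimum N; default 100.
#' @return Object of class `preferred_axis`: `axis` (unit D-vector),
#'   `fold_axes` (n_folds x D), `cv_projections` (length N),
#'   `ev_cv`.
#' @export
fit_preferred_axis <- function(responses, pc_scores, n_folds = 10, seed = 1L,
                               min_images = 100) {
  stopifnot(is.matrix(pc_scores), length(responses) == nrow(pc_scores))
  n <- length(responses)
  if (n < min_images)
    stop(sprintf("need at least %d images (got %d)", min_images, n))
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  D <- ncol(pc_scores)
  fold_axes <- matrix(NA_real_, n_folds, D)
  proj <- rep(NA_real_, n)
  for (k in seq_len(n_folds)) {
    test <- folds == k
    a <- ols_axis(pc_scores[!test, , drop = FALSE], responses[!test])
    a <- unit_vector(a)
    if (k > 1L) {
      d <- sum(a * fold_axes[1L, ])
      if (d < 0 || (d == 0 && a[1] < 0)) a <- -a
    }
    fold_axes[k, ] <- a
    proj[test] <- pc_scores[test, , drop = FALSE] %*% a
  }
  axis <- unit_vector(colMeans(fold_axes))
  ev_cv <- if (stats::sd(proj) > 0) stats::cor(proj, responses)^2 else 0
  structure(list(axis = axis, fold_axes = fold_axes,
                 cv_projections = proj, ev_cv = ev_cv),
            class = "preferred_axis")
}

#' @export
print.preferred_axis <- function(x, ...) {
  cat(sprintf("Preferred axis in %d-D feature space: cross-validated EV = %.3f\n",
              length(x$axis), x$ev_cv))
  invisible(x)
}

#' Principal orthogonal axis
#'
#' Control direction: the first principal component of the feature space
#' projected onto the hyperplane orthogonal to the cell's preferred axis,
#' renormalized.  In PC-score coordinates the first PC is the first
#' coordinate direction; if the preferred axis is (numerically) parallel
#' to it, the second PC is used instead.
#'
#' @param axis Unit vector (preferred axis, PC coordinates).
#' @return Unit vector orthogonal to `axis`.
#' @export
principal_orthogonal_axis <- function(axis) {
  D <- length(axis)
  e1 <- c(1, rep(0, D - 1))
  if (abs(sum(e1 * axis)) > 1 - 1e-10) {
    message("preferred axis parallel to PC1; falling back to PC2")
    e1 <- c(0, 1, rep(0, D - 2))
  }
  unit_vector(e1 - sum(e1 * axis) * axis)
}

#' Binned tuning curve along an axis projection
#'
#' Projections are rescaled so that the 1st and 99th nearest-rank
#' percentiles map to -1 and +1 (the range `[-1, 1]` then covers 98% of
#' the stimuli up to rank discreteness), divided into equal-width bins
#' over `[-1, 1]`, and the mean response per bin is computed.  Empty bins
#' are reported as missing, not zero.
#'
#' @param responses Per-image responses.
#' @param projections Per-image projections onto the axis.
#' @param n_bins Number of bins; default 16.
#' @param axis_kind Label (`"preferred"` or `"principal_orthogonal"`).
#' @return Object of class `axis_tuning_curve`: `bin_edges`,
#'   `bin_centers`, `mean_response`, `n`, `coverage` (fraction of stimuli
#'   inside `[-1, 1]`), `q1`, `q99`.
#' @export
tuning_curve <- function(responses, projections, n_bins = 16,
                         axis_kind = "preferred") {
  stopifnot(all(is.finite(projections)))
  q1 <- quantile1(projections, 0.01)
  q99 <- quantile1(projections, 0.99)
  if (q99 <= q1) stop("degenerate projections: cannot rescale")
  z <- 2 * (projections - q1) / (q99 - q1) - 1
  edges <- seq(-1, 1, length.out = n_bins + 1)
  bi <- findInterval(z, edges, rightmost.closed = TRUE)
  inside <- bi >= 1 & bi <= n_bins
  mr <- nn <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    sel <- inside & bi == b
    nn[b] <- sum(sel)
    if (nn[b] > 0) mr[b] <- mean(responses[sel])
  }
  structure(list(bin_edges = edges, bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 mean_response = mr, n = nn,
                 coverage = mean(z >= -1 & z <= 1),
                 q1 = q1, q99 = q99, axis_kind = axis_kind),
            class = "axis_tuning_curve")
}

#' @export
plot.axis_tuning_curve <- function(x, ...) {
  graphics::plot(x$bin_centers, x$mean_response, type = "b", pch = 16,
                 xlab = sprintf("projection on %s axis (rescaled)", x$axis_kind),
                 ylab = "mean response", ...)
  invisible(x)
}

#' Per-layer encoding profile of an area
#'
#' For every unit and every extractor layer, fits the 50-PC linear
#' encoding model with cross-validation and records the held-out EV
#' (squared correlation between held-out projections and responses).  The
#' per-cell best layer is the EV argmax; the area profile sums EV across
#' cells per layer and normalizes by the summed explainable variance of
#' the same cells, making layers comparable within an area.
#'
#' @param responses Units x images matrix of per-image mean responses.
#' @param feature_banks Named list of [feature_bank] objects (same image
#'   set in each).
#' @param explainable Per-unit explainable variance (from
#'   [explainable_variance]).
#' @param n_folds CV folds; default 10.
#' @param seed Fold seed.
#' @return Object of class `layer_encoding_profile`: `ev` (units x
#'   layers), `best_layer` (per unit), `profile` (per layer, normalized).
#' @export
layer_encoding_profile <- function(responses, feature_banks, explainable,
                                   n_folds = 10, seed = 1L) {
  stopifnot(is.matrix(responses), length(explainable) == nrow(responses))
  L <- length(feature_banks)
  ev <- matrix(NA_real_, nrow(responses), L,
               dimnames = list(rownames(responses), names(feature_banks)))
  for (l in seq_len(L)) {
    sc <- feature_banks[[l]]$pc_scores
    stopifnot(nrow(sc) == ncol(responses))
    for (u in seq_len(nrow(responses))) {
      fit <- fit_preferred_axis(responses[u, ], sc, n_folds = n_folds,
                                seed = seed, min_images = 2 * n_folds)
      ev[u, l] <- fit$ev_cv
    }
  }
  best <- apply(ev, 1, which.max)
  denom <- sum(explainable, na.rm = TRUE)
  profile <- colSums(ev) / denom
  structure(list(ev = ev, best_layer = best, profile = profile),
            class = "layer_encoding_profile")
}

#' @export
print.layer_encoding_profile <- function(x, ...) {
  cat("Layer encoding profile (sum EV / sum explainable):\n")
  print(round(x$profile, 3))
  cat("modal best layer:", names(which.max(table(x$best_layer))), "\n")
  invisible(x)
}
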