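#' Face selectivity score
#'
#' Welch two-sample t score between a unit's per-image mean responses to
#' faces and to the rest of the images, plus the face selectivity index
#' `FSI = (mu_face - mu_nonface) / (mu_face + mu_nonface)`.  Units with
#' `t > 5` are flagged face cells; `t >= 15` flags highly face-selective
#' cells.
#'
#' @param img_means Per-image mean responses of one unit (or a units x
#'   images matrix for many units).
#' @param is_face Logical per image.
#' @return Data frame per unit: `unit_id`, `t_score`, `fsi`,
#'   `face_cell`, `highly_selective`.
#' @export
face_selectivity <- function(img_means, is_face) {
  if (is.vector(img_means)) img_means <- matrix(img_means, nrow = 1)
  stopifnot(ncol(img_means) == length(is_face))
  if (sum(is_face) < 5 || sum(!is_face) < 5)
    stop("need at least 5 face and 5 non-face images")
  units <- rownames(img_means) %||% seq_len(nrow(img_means))
  res <- lapply(seq_len(nrow(img_means)), function(u) {
    x <- img_means[u, ]
    mf <- mean(x[is_face]); mn <- mean(x[!is_face])
    tt <- if (stats::sd(x[is_face]) == 0 && stats::sd(x[!is_face]) == 0) 0
          else unname(stats::t.test(x[is_face], x[!is_face])$statistic)
    fsi <- if (mf + mn == 0) NA_real_ else (mf - mn) / (mf + mn)
    data.frame(unit_id = units[u], t_score = tt, fsi = fsi,
               face_cell = tt > 5, highly_selective = tt >= 15)
  })
  do.call(rbind, res)
}

# Vectorized Gaussian naive Bayes: train on a units x images x repeats
# tensor minus one held-out repeat, classify the held-out repeat.
gnb_accuracy_one <- function(tensor, test_rep, var_floor = 1e-6) {
  d <- dim(tensor)
  train <- tensor[, , -test_rep, drop = FALSE]
  nr <- dim(train)[3]
  mu <- rowMeans(train, dims = 2)                    # units x images
  m2 <- rowMeans(train^2, dims = 2)
  vv <- pmax((m2 - mu^2) * nr / (nr - 1), var_floor)
  X <- tensor[, , test_rep]                          # units x images (test)
  if (is.null(dim(X))) X <- matrix(X, d[1], d[2])
  # log-likelihood of test image j under class c:
  # -0.5 * sum_u [ (x_uj - mu_uc)^2 / v_uc + log v_uc ]
  iv <- 1 / vv
  a <- crossprod(X^2, iv)                            # test x class
  b <- crossprod(X, mu * iv)
  cc <- matrix(colSums(mu^2 * iv + log(vv)), nrow(a), ncol(a), byrow = TRUE)
  ll <- -0.5 * (a - 2 * b + cc)
  pred <- max.col(ll, ties.method = "first")
  mean(pred == seq_len(d[2]))
}

#' Identity decoding with Gaussian naive Bayes
#'
#' Decodes image identity from trial-by-trial population spike counts
#' under a resampling protocol: per neuron resample, `n_cells` units are
#' drawn at random; per split resample, classifiers are trained on all
#' but one repeat per image (per-class independent Gaussians with a
#' variance floor) and tested on the held-out repeat, the train/test
#' assignment being randomized across split resamples.  Accuracy is the
#' fraction of correctly identified images, averaged over all resamples;
#' chance is `1 / n_images`.
#'
#' @param tensor Units x images x repeats response array.
#' @param n_cells Units per resample.
#' @param n_images Images per decoding problem (default 201; drawn at
#'   random from the available images).
#' @param n_neuron_resamples,n_split_resamples Resample counts; the
#'   reference protocol uses 500 and 200.
#' @param var_floor Absolute variance floor; default 1e-6.
#' @param units_subset Optional unit indices to restrict sampling to
#'   (e.g. face cells with `t > 5`).
#' @param seed Integer seed.
#' @return Object of class `identity_decoding`: `accuracy` (mean),
#'   `accuracy_sd`, `chance`, `n_cells`, `n_classes`.
#' @export
gnb_identity_decoding <- function(tensor, n_cells = 100, n_images = 201,
                                  n_neuron_resamples = 20,
                                  n_split_resamples = 20,
                                  var_floor = 1e-6,
                                  units_subset = NULL, seed = 1L) {
  d <- dim(tensor)
  pool <- units_subset %||% seq_len(d[1])
  if (n_cells > length(pool))
    stop(sprintf("n_cells = %d exceeds the %d available units", n_cells,
                 length(pool)))
  if (n_images > d[2])
    stop(sprintf("n_images = %d exceeds the %d available images", n_images, d[2]))
  n_rep <- d[3]
  with_seed(seed, {
    acc <- numeric(n_neuron_resamples * n_split_resamples)
    i <- 0L
    for (nr in seq_len(n_neuron_resamples)) {
      cells <- pool[sample.int(length(pool), n_cells)]
      imgs <- sample.int(d[2], n_images)
      sub <- tensor[cells, imgs, , drop = FALSE]
      for (sr in seq_len(n_split_resamples)) {
        i <- i + 1L
        acc[i] <- gnb_accuracy_one(sub, sample.int(n_rep, 1L), var_floor)
      }
    }
    structure(list(accuracy = mean(acc), accuracy_sd = stats::sd(acc),
                   chance = 1 / n_images, n_cells = n_cells,
                   n_classes = n_images, per_resample = acc),
              class = "identity_decoding")
  })
}

#' @export
print.identity_decoding <- function(x, ...) {
  cat(sprintf("GNB identity decoding: accuracy %.4f (chance %.4f, %d classes, %d cells)\n",
              x$accuracy, x$chance, x$n_classes, x$n_cells))
  invisible(x)
}

#' Decoding-accuracy curve over population size
#'
#' Runs [gnb_identity_decoding] over a grid of population sizes.
#'
#' @inheritParams gnb_identity_decoding
#' @param n_cells_grid Integer vector of population sizes.
#' @return Data frame `n_cells`, `accuracy`, `accuracy_sd`, `chance`.
#' @export
identity_decoding_curve <- function(tensor, n_cells_grid = c(10, 25, 50, 100),
                                    n_images = 201,
                                    n_neuron_resamples = 20,
                                    n_split_resamples = 20,
                                    units_subset = NULL, seed = 1L) {
  res <- lapply(seq_along(n_cells_grid), function(i) {
    r <- gnb_identity_decoding(tensor, n_cells = n_cells_grid[i],
                               n_images = n_images,
                               n_neuron_resamples = n_neuron_resamples,
                               n_split_resamples = n_split_resamples,
                               units_subset = units_subset, seed = seed + i)
    data.frame(n_cells = n_cells_grid[i], accuracy = r$accuracy,
               accuracy_sd = r$accuracy_sd, chance = r$chance)
  })
  do.call(rbind, res)
}

#' View-invariance index
#'
#' For each identity, the Pearson correlation between the population
#' response vector to the frontal view and to each non-frontal view;
#' correlations are averaged over views, then over identities.
#' Identities with a constant population vector are skipped with a
#' message.
#'
#' @param tensor Units x identities x views response array; view 1 is the
#'   frontal view unless `frontal` says otherwise.
#' @param frontal Index of the frontal view; default 1.
#' @return Object of class `invariance_index`: `index`, `per_identity`.
#' @export
invariance_index <- function(tensor, frontal = 1L) {
  d <- dim(tensor)
  stopifnot(length(d) == 3, d[3] >= 2)
  views <- setdiff(seq_len(d[3]), frontal)
  per_id <- rep(NA_real_, d[2])
  skipped <- 0L
  for (id in seq_len(d[2])) {
    f <- tensor[, id, frontal]
    if (stats::sd(f) == 0) { skipped <- skipped + 1L; next }
    cs <- vapply(views, function(v) {
      x <- tensor[, id, v]
      if (stats::sd(x) == 0) NA_real_ else stats::cor(f, x)
    }, numeric(1))
    per_id[id] <- mean(cs, na.rm = TRUE)
  }
  if (skipped > 0L)
    message(sprintf("invariance_index: %d identities skipped (constant response)",
                    skipped))
  structure(list(index = mean(per_id, na.rm = TRUE), per_identity = per_id),
            class = "invariance_index")
}

#' @export
print.invariance_index <- function(x, ...) {
  cat(sprintf("View-invariance index: %.3f (over %d identities)\n",
              x$index, sum(is.finite(x$per_identity))))
  invisible(x)
}
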