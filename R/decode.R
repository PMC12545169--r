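ols_predict_cv <- function(X, Y, folds) {
  # cross-validated multi-response OLS: predict each column of Y from X
  pred <- matrix(NA_real_, nrow(Y), ncol(Y))
  for (k in sort(unique(folds))) {
    test <- folds == k
    Xtr <- cbind(1, X[!test, , drop = FALSE])
    fit <- stats::lm.fit(Xtr, Y[!test, , drop = FALSE])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    pred[test, ] <- cbind(1, X[test, , drop = FALSE]) %*% cf
  }
  pred
}

#' Decode feature principal components from population activity
#'
#' Repeatedly samples `n_cells` cells at random (without replacement) from
#' the population, regresses each feature principal component on the
#' sampled response matrix with cross-validation over images, and reports
#' the fraction of each PC's variance explained by the neural data on
#' held-out images (R-squared; clipped at 1 by construction, negative
#' values reported raw), averaged across resamples.
#'
#' @param responses Images x cells matrix of per-image mean responses.
#' @param pc_scores Images x PCs matrix of feature PC scores.
#' @param n_cells Cells per resample; default 100.
#' @param n_resamples Number of cell resamples; default 10.
#' @param n_folds CV folds over images; default 10.
#' @param seed Integer seed.
#' @return Object of class `pc_decoding`: data frame `pc`,
#'   `frac_var_mean`, `frac_var_sd`, plus `n_cells`, `n_resamples`.
#' @export
decode_pcs <- function(responses, pc_scores, n_cells = 100, n_resamples = 10,
                       n_folds = 10, seed = 1L) {
  stopifnot(is.matrix(responses), is.matrix(pc_scores),
            nrow(responses) == nrow(pc_scores))
  n_avail <- ncol(responses); n_img <- nrow(responses)
  if (n_cells > n_avail)
    stop(sprintf("n_cells = %d exceeds the %d available cells; use n_cells <= %d",
                 n_cells, n_avail, n_avail))
  if (n_img < 2 * n_cells)
    warning(sprintf("only %d images for %d cells; held-out R^2 will be noisy",
                    n_img, n_cells))
  n_pc <- ncol(pc_scores)
  with_seed(seed, {
    fr <- matrix(NA_real_, n_resamples, n_pc)
    for (r in seq_len(n_resamples)) {
      cells <- sample.int(n_avail, n_cells)
      folds <- sample(rep_len(seq_len(n_folds), n_img))
      pred <- ols_predict_cv(responses[, cells, drop = FALSE], pc_scores, folds)
      sst <- colSums(sweep(pc_scores, 2, colMeans(pc_scores))^2)
      sse <- colSums((pc_scores - pred)^2)
      fr[r, ] <- 1 - sse / sst
    }
    out <- data.frame(pc = seq_len(n_pc),
                      frac_var_mean = colMeans(fr),
                      frac_var_sd = apply(fr, 2, stats::sd))
    structure(list(per_pc = out, n_cells = n_cells,
                   n_resamples = n_resamples),
              class = "pc_decoding")
  })
}

#' @export
print.pc_decoding <- function(x, ...) {
  cat(sprintf("PC decoding (%d cells, %d resamples): mean fraction of variance %.3f (PC1 %.3f)\n",
              x$n_cells, x$n_resamples, mean(x$per_pc$frac_var_mean),
              x$per_pc$frac_var_mean[1]))
  invisible(x)
}

#' Map decoded PC scores back to full feature space
#'
#' The reduction to principal components is an orthonormal projection, so
#' its Moore–Penrose pseudoinverse is the transpose of the loading
#' matrix: `v_recon = pc_mean + pc_basis %*% y_hat`.
#'
#' @param y_hat Decoded PC score vector (length `n_pcs`).
#' @param bank A [feature_bank] supplying `pc_basis` and `pc_mean`.
#' @return Feature-space vector (length D).
#' @export
reconstruct_feature_vector <- function(y_hat, bank) {
  stopifnot(inherits(bank, "feature_bank"))
  if (length(y_hat) != ncol(bank$pc_basis))
    stop(sprintf("y_hat has length %d but the bank holds %d PCs",
                 length(y_hat), ncol(bank$pc_basis)))
  as.vector(bank$pc_mean + bank$pc_basis %*% y_hat)
}

#' Nearest auxiliary image in feature space
#'
#' Returns the image of an auxiliary bank whose full feature vector has
#' the smallest Euclidean distance to the query vector; ties are broken
#' toward the lowest image id.
#'
#' @param v Query feature vector (length D).
#' @param aux A [feature_bank] of auxiliary images (disjoint from the
#'   presented set).
#' @return List: `image_id`, `index`, `v_best` (the winning feature
#'   vector), `distance`.
#' @export
nearest_auxiliary <- function(v, aux) {
  stopifnot(inherits(aux, "feature_bank"))
  F <- aux$features
  if (nrow(F) == 0) stop("auxiliary bank is empty")
  d2 <- rowSums(F^2) - 2 * as.vector(F %*% v) + sum(v^2)
  ord <- order(d2, aux$image_ids)       # ties -> lowest id
  i <- ord[1]
  list(image_id = aux$image_ids[i], index = i, v_best = F[i, ],
       distance = sqrt(max(d2[i], 0)))
}

#' Normalized decoding distance
#'
#' Reconstruction score for one image: the distance between the decoded
#' feature vector and the original's feature vector, divided by the
#' distance from the original to the best possible retrieval — by default
#' the auxiliary image nearest to the *original* vector (the alternative
#' convention, nearest to the decoded vector, is available via
#' `best_by`).  A value of 1 means the reconstruction found the best
#' solution the auxiliary bank allows; 0 means perfect decoding.
#'
#' @param v_recon Decoded feature vector.
#' @param v_original True feature vector of the presented image.
#' @param aux Auxiliary [feature_bank]; must not contain the original.
#' @param best_by `"original"` (default) or `"recon"`.
#' @return List of class `reconstruction_record`: `normalized_distance`,
#'   `chosen_auxiliary_id` (nearest to the decoded vector), `v_best`,
#'   `best_id`.
#' @export
normalized_decoding_distance <- function(v_recon, v_original, aux,
                                         best_by = c("original", "recon")) {
  best_by <- match.arg(best_by)
  chosen <- nearest_auxiliary(v_recon, aux)
  best <- if (best_by == "original") nearest_auxiliary(v_original, aux) else chosen
  denom <- sqrt(sum((best$v_best - v_original)^2))
  if (denom == 0)
    stop("original image present in the auxiliary bank; banks must be disjoint")
  structure(list(
    normalized_distance = sqrt(sum((v_recon - v_original)^2)) / denom,
    chosen_auxiliary_id = chosen$image_id,
    best_id = best$image_id,
    v_best = best$v_best
  ), class = "reconstruction_record")
}

#' Area-level reconstruction summary
#'
#' Runs the full decoding-reconstruction chain for one area: decodes the
#' PC scores of every presented image from a sampled population of
#' `n_cells` cells with cross-validation over images, maps the decoded
#' scores back to feature space through the pseudoinverse, and scores
#' every image with the normalized decoding distance against an auxiliary
#' bank.  Reports the mean and dispersion over images.
#'
#' @param responses Images x cells per-image mean responses.
#' @param bank [feature_bank] of the presented images.
#' @param aux Auxiliary [feature_bank] (disjoint image set).
#' @param n_cells Cells sampled; default 100 (capped at available).
#' @param n_folds CV folds; default 10.
#' @param seed Integer seed.
#' @param best_by Convention passed to [normalized_decoding_distance].
#' @return Object of class `reconstruction_summary`: `mean_distance`,
#'   `sd_distance`, `distances` (per image), `chosen_auxiliary_id`.
#' @export
area_reconstruction_summary <- function(responses, bank, aux, n_cells = 100,
                                        n_folds = 10, seed = 1L,
                                        best_by = "original") {
  stopifnot(inherits(bank, "feature_bank"))
  n_img <- nrow(responses)
  if (n_img < 50) stop("need at least 50 images")
  n_cells <- min(n_cells, ncol(responses))
  with_seed(seed, {
    cells <- sample.int(ncol(responses), n_cells)
    folds <- sample(rep_len(seq_len(n_folds), n_img))
    yhat <- ols_predict_cv(responses[, cells, drop = FALSE], bank$pc_scores, folds)
    dist <- numeric(n_img); chosen <- integer(n_img)
    for (i in seq_len(n_img)) {
      v_rec <- reconstruct_feature_vector(yhat[i, ], bank)
      rec <- normalized_decoding_distance(v_rec, bank$features[i, ], aux,
                                          best_by = best_by)
      dist[i] <- rec$normalized_distance
      chosen[i] <- rec$chosen_auxiliary_id
    }
    structure(list(mean_distance = mean(dist), sd_distance = stats::sd(dist),
                   distances = dist, chosen_auxiliary_id = chosen,
                   n_cells = n_cells),
              class = "reconstruction_summary")
  })
}

#' @export
print.reconstruction_summary <- function(x, ...) {
  cat(sprintf("Reconstruction: mean normalized distance %.3f (sd %.3f, %d cells, %d images)\n",
              x$mean_distance, x$sd_distance, x$n_cells, length(x$distances)))
  invisible(x)
}
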