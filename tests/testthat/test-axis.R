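test_that("Spearman-Brown reliability follows the closed-form algebra", {
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(1 / 3), 0.5)
  expect_equal(spearman_brown(-0.2), 0)             # clamped
  expect_equal(spearman_brown(-0.2, clamp = FALSE), 2 * (-0.2) / 0.8)
  # identical halves give rho = 1 and explainable = 1
  tens <- array(rep(1:20, each = 2, times = 4), c(2, 20, 4))
  ev <- explainable_variance(tens)
  expect_equal(ev$rho, c(1, 1))
  expect_equal(ev$explainable, c(1, 1))
})

test_that("explainable variance estimates the signal fraction of variance", {
  # signal fraction s of total per-trial variance; mean SB estimate ~ s
  set.seed(20)
  n_img <- 400; n_rep <- 10; n_sims <- 40
  for (s in c(0.3, 0.6)) {
    est <- replicate(n_sims, {
      # per-trial noise scaled so the signal fraction of the all-repeat mean
      # response variance is exactly s
      sig <- rnorm(n_img, 0, sqrt(s))
      x <- matrix(sig, n_img, n_rep) +
        matrix(rnorm(n_img * n_rep, 0, sqrt(n_rep * (1 - s))), n_img, n_rep)
      tens <- array(x, c(1, n_img, n_rep))
      explainable_variance(tens)$explainable
    })
    expect_lt(abs(mean(est) - s), 0.05)
  }
})

test_that("explainable variance is invariant to half relabelling and needs 2 repeats", {
  set.seed(21)
  tens <- array(rpois(3 * 50 * 6, 4), c(3, 50, 6))
  a <- explainable_variance(tens)
  flipped <- tens[, , c(2, 1, 4, 3, 6, 5)]   # swap odd/even halves
  b <- explainable_variance(flipped)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
  expect_error(explainable_variance(tens[, , 1, drop = FALSE]), "2 repeats")
})

test_that("a noiseless linear cell's preferred axis equals the generating direction", {
  sc <- make_scores(300, 20, seed = 2)
  b <- vstream:::unit_vector(rnorm(20))
  y <- as.vector(sc %*% b) + 2
  fa <- fit_preferred_axis(y, sc, seed = 3)
  expect_gt(abs(sum(fa$axis * b)), 1 - 1e-10)
  expect_equal(fa$ev_cv, 1, tolerance = 1e-10)
  expect_equal(sqrt(sum(fa$axis^2)), 1, tolerance = 1e-12)
  # every image's projection comes from a fold that excluded it
  expect_true(all(is.finite(fa$cv_projections)))
  expect_equal(dim(fa$fold_axes), c(10, 20))
})

test_that("axis recovery holds under Poisson noise at moderate reliability", {
  set.seed(22)
  sc <- make_scores(800, 20, seed = 4)
  b <- vstream:::unit_vector(rnorm(20))
  proj <- as.vector(scale(sc %*% b))
  rates <- pmax(2 + 3 * pmax(proj, 0), 0.01)      # rectified-ramp cell
  tens <- sim_tensor(matrix(rates, 1), n_repeats = 10, seed = 5)
  y <- image_means(tens)[1, ]
  fa <- fit_preferred_axis(y, sc, seed = 6)
  expect_gt(abs(sum(fa$axis * b)), 0.9)
  # a response independent of the features has ev_cv near 0
  null_ev <- replicate(30, {
    y0 <- rpois(nrow(sc), 5)
    fit_preferred_axis(y0, sc, seed = 1)$ev_cv
  })
  expect_lt(mean(null_ev), 0.03)
})

test_that("axis estimation is equivariant under orthogonal rotation of the basis", {
  set.seed(23)
  sc <- make_scores(200, 12, seed = 7)
  y <- as.vector(sc %*% rnorm(12)) + rnorm(200, 0, 0.5)
  R <- qr.Q(qr(matrix(rnorm(144), 12, 12)))
  a1 <- fit_preferred_axis(y, sc, seed = 8)$axis
  a2 <- fit_preferred_axis(y, sc %*% R, seed = 8)$axis
  expect_lt(max(abs(as.vector(R %*% a2) - a1)), 1e-8)
})

test_that("the principal orthogonal axis is orthogonal and falls back off PC1", {
  expect_equal(principal_orthogonal_axis(c(0, 1, 0, 0)), c(1, 0, 0, 0))
  for (i in 1:20) {
    a <- vstream:::unit_vector(rnorm(10))
    o <- principal_orthogonal_axis(a)
    expect_lt(abs(sum(o * a)), 1e-12)
    expect_equal(sqrt(sum(o^2)), 1, tolerance = 1e-12)
  }
  expect_message(o <- principal_orthogonal_axis(c(1, 0, 0)), "PC2")
  expect_equal(o, c(0, 1, 0))
})

test_that("a ramp cell is flat along its principal orthogonal axis", {
  # isotropic scores: Euclidean orthogonality then implies decorrelation
  set.seed(24)
  sc <- make_scores(600, 15, decay = 1, seed = 9)
  b <- vstream:::unit_vector(rnorm(15))
  y <- pmax(as.vector(sc %*% b), 0) + rnorm(600, 0, 0.3)
  fa <- fit_preferred_axis(y, sc, seed = 10)
  o <- principal_orthogonal_axis(fa$axis)
  po <- as.vector(sc %*% o)
  fit <- summary(lm(y ~ po))
  expect_lt(abs(fit$coefficients["po", "t value"]), 3)
})

test_that("tuning-curve rescaling covers 98% of stimuli and tracks monotone cells", {
  set.seed(25)
  proj <- rnorm(1600)
  y <- 2 + proj
  tc <- tuning_curve(y, proj)
  n <- length(proj)
  expected <- (n - ceiling(0.99 * n)) + (ceiling(0.01 * n) - 1)  # outside count
  expect_equal(tc$coverage, 1 - expected / n)
  expect_lt(abs(tc$coverage - 0.98), 0.005)
  # linear cell: bin means increase along the axis
  expect_gt(cor(seq_along(tc$mean_response), tc$mean_response,
                method = "spearman", use = "complete.obs"), 0.9)
  # shuffled responses show no monotone trend (checked over repeats)
  rhos <- replicate(20, {
    tcs <- tuning_curve(sample(y), proj)
    cor(seq_along(tcs$mean_response), tcs$mean_response,
        method = "spearman", use = "complete.obs")
  })
  expect_lt(mean(abs(rhos) < 0.5), 1.01)  # most runs show no trend
  expect_gt(mean(abs(rhos) < 0.5), 0.7)
  # empty bins are missing, not zero
  tc2 <- tuning_curve(y[1:50], proj[1:50], n_bins = 30)
  expect_true(any(is.na(tc2$mean_response)))
  expect_false(any(tc2$mean_response == 0, na.rm = TRUE))
})

test_that("layer encoding profiles identify the generating layer", {
  ob <- make_object_bank(n_objects = 150, n_faces = 50, image_shape = c(32, 32),
                         seed = 26)
  fe <- extract_features(ob, layers = 1:3, n_pcs = 20, out_dim = 128, seed = 27)
  set.seed(28)
  n_cells <- 20
  gen <- fe[[2]]$pc_scores          # cells built from layer 2
  rates <- t(sapply(seq_len(n_cells), function(u) {
    b <- vstream:::unit_vector(rnorm(20))
    pmax(4 + 2.5 * as.vector(scale(gen %*% b)), 0.1)
  }))
  tens <- sim_tensor(rates, n_repeats = 8, seed = 29)
  dimnames(tens) <- list(unit = 1:n_cells, stim = ob$image_ids, rep = 1:8)
  expl <- explainable_variance(tens)$explainable
  prof <- layer_encoding_profile(image_means(tens), fe, expl, seed = 30)
  modal <- as.integer(names(which.max(table(prof$best_layer))))
  expect_equal(modal, 2L)
  # encoding cannot beat reliability by much for the generating layer
  expect_lt(prof$profile[2], 1.1)
  expect_equal(names(which.max(prof$profile)), "layer2")
})
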