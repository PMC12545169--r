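test_that("face selectivity index and t score follow their definitions", {
  set.seed(40)
  is_face <- rep(c(TRUE, FALSE), c(20, 60))
  # mu_face = 3, mu_nonface = 1 -> FSI = 0.5
  x <- c(rnorm(20, 3, 1e-6), rnorm(60, 1, 1e-6))
  s <- face_selectivity(x, is_face)
  expect_equal(s$fsi, 0.5, tolerance = 1e-4)
  expect_true(s$face_cell)
  # equal means -> FSI ~ 0, t ~ 0
  y <- rnorm(80, 2, 0.5)
  s0 <- face_selectivity(y, is_face)
  expect_lt(abs(s0$fsi), 0.2)
  expect_lt(abs(s0$t_score), 3)
  expect_error(face_selectivity(y, rep(c(TRUE, FALSE), c(3, 77))),
               "at least 5")
})

test_that("FSI is invariant to multiplicative rescaling; t matches Welch's test", {
  set.seed(41)
  is_face <- rep(c(TRUE, FALSE), c(30, 70))
  x <- rgamma(100, 4, 1) + ifelse(is_face, 2, 0)
  s1 <- face_selectivity(x, is_face)
  s2 <- face_selectivity(5 * x, is_face)
  expect_equal(s1$fsi, s2$fsi, tolerance = 1e-12)
  expect_equal(s1$t_score, s2$t_score, tolerance = 1e-12)
  expect_equal(s1$t_score,
               unname(t.test(x[is_face], x[!is_face])$statistic),
               tolerance = 1e-12)
})

test_that("a deterministic unique-signature population decodes identity perfectly", {
  n_img <- 40; n_units <- 12
  rates <- matrix(seq_len(n_units * n_img), n_units, n_img)  # distinct patterns
  tens <- array(rates, c(n_units, n_img, 5))                 # noiseless repeats
  g <- gnb_identity_decoding(tens, n_cells = 8, n_images = 30,
                             n_neuron_resamples = 3, n_split_resamples = 3,
                             seed = 1)
  expect_equal(g$accuracy, 1)
  expect_equal(g$chance, 1 / 30)
  expect_error(gnb_identity_decoding(tens, n_cells = 50), "available units")
  expect_error(gnb_identity_decoding(tens, n_cells = 8, n_images = 100), "available images")
})

test_that("the GNB agrees with an independent naive Bayes implementation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  n_units <- 6; n_img <- 8; n_rep <- 6
  tens <- array(rpois(n_units * n_img * n_rep, 8) +
                  rep(seq_len(n_img) * 2, each = n_units),
                c(n_units, n_img, n_rep))
  test_rep <- 2
  acc <- vstream:::gnb_accuracy_one(tens, test_rep, var_floor = 1e-9)
  train <- tens[, , -test_rep]
  X <- t(matrix(train, n_units, n_img * (n_rep - 1)))
  yl <- factor(rep(seq_len(n_img), n_rep - 1))
  nb <- e1071::naiveBayes(X, yl)
  pred <- predict(nb, t(tens[, , test_rep]))
  expect_equal(acc, mean(pred == factor(seq_len(n_img))), tolerance = 1e-12)
})

test_that("decoding accuracy grows with population size for signal populations", {
  set.seed(43)
  n_units <- 60; n_img <- 30
  sig <- matrix(rnorm(n_units * n_img, 6, 2), n_units, n_img)
  tens <- sim_tensor(pmax(sig, 0.1), n_repeats = 6, seed = 44)
  curve <- identity_decoding_curve(tens, n_cells_grid = c(5, 20, 50),
                                   n_images = 30,
                                   n_neuron_resamples = 4,
                                   n_split_resamples = 4, seed = 45)
  expect_true(all(diff(curve$accuracy) > -0.05))   # monotone within error
  expect_gt(curve$accuracy[3], curve$accuracy[1])
  expect_gt(curve$accuracy[3], 3 * curve$chance[1])
})

test_that("restricting to face cells does not hurt face-identity decoding", {
  set.seed(46)
  n_face_cells <- 25; n_other <- 35; n_img <- 30
  sig <- matrix(pmax(rnorm(n_face_cells * n_img, 8, 3), 0.1), n_face_cells, n_img)
  noise <- matrix(8, n_other, n_img)
  tens <- sim_tensor(rbind(sig, noise), n_repeats = 6, seed = 47)
  face_cells <- seq_len(n_face_cells)
  g_face <- gnb_identity_decoding(tens, n_cells = 15, n_images = 30,
                                  n_neuron_resamples = 5, n_split_resamples = 5,
                                  units_subset = face_cells, seed = 48)
  g_rand <- gnb_identity_decoding(tens, n_cells = 15, n_images = 30,
                                  n_neuron_resamples = 5, n_split_resamples = 5,
                                  seed = 48)
  expect_gte(g_face$accuracy, g_rand$accuracy)
})

test_that("the invariance index hits its closed-form endpoints and null", {
  set.seed(49)
  base <- matrix(rnorm(20 * 6), 20, 6)
  # identical across views -> 1
  tens1 <- array(base, c(20, 6, 4))
  expect_equal(invariance_index(tens1)$index, 1)
  # sign-flipped non-frontal views -> -1
  tens2 <- tens1
  tens2[, , 2:4] <- -tens2[, , 2:4]
  expect_equal(invariance_index(tens2)$index, -1)
  # independent noise across views -> ~0
  tens3 <- array(rnorm(40 * 100 * 8), c(40, 100, 8))
  expect_lt(abs(invariance_index(tens3)$index), 0.05)
  # constant population vectors are skipped with a message
  tens4 <- tens1
  tens4[, 2, 1] <- 5
  expect_message(invariance_index(tens4), "skipped")
})

test_that("low-level index set is complete, finite and versioned", {
  ob <- make_object_bank(25, 10, c(32, 32), seed = 50)
  idx <- lowlevel_indices(ob)
  expect_equal(ncol(idx), 13)
  expect_equal(attr(idx, "version"), "v1")
  expect_true(all(is.finite(idx[, setdiff(colnames(idx), "compactness")])))
  # spectral groups partition the bank with sizes differing by <= 1
  g <- spectral_groups(idx, 7)
  expect_equal(sort(unique(g)), 1:7)
  expect_lte(diff(range(table(g))), 1)
})

test_that("low-level controls attribute variance to the generating index", {
  set.seed(51)
  ob <- make_object_bank(70, 30, c(32, 32), seed = 52)
  idx <- lowlevel_indices(ob)
  lum <- scale(idx[, "mean_luminance"])[, 1]
  # one luminance-coding cell and one identity-coding cell
  r_lum <- pmax(5 + 4 * lum, 0.1)
  r_id <- pmax(rnorm(100, 5, 3), 0.1)
  tens <- sim_tensor(rbind(r_lum, r_id), n_repeats = 8, seed = 53)
  ctl <- lowlevel_variance_controls(tens, ob, indices = idx)
  lum_row <- ctl$per_index[ctl$per_index$index == "mean_luminance", ]
  expect_gt(lum_row$pct_explained, 15)
  expect_equal(nrow(ctl$identity_by_group), 7)
  expect_true(all(ctl$identity_by_group$pct_identity > 0, na.rm = TRUE))
  # rf-windowed variant runs when fits are supplied and skips units without
  rf_fits <- list(list(has_rf = TRUE, sigma = 5), NULL)
  ctl2 <- lowlevel_variance_controls(tens, ob, indices = idx, rf_fits = rf_fits)
  expect_equal(ctl2$n_excluded_no_rf, 1)
  expect_equal(nrow(ctl2$rf_windowed), 1)
  expect_gt(ctl2$rf_windowed$pct_luminance, 15)
})
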