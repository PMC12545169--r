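test_that("sparse-noise schedules have one dot per grid cell and balanced polarities", {
  sn <- make_sparse_noise_schedule(grid_shape = c(4, 3), n_frames = 100, seed = 2)
  expect_equal(nrow(sn$dots), 100 * 12)
  expect_equal(as.vector(table(sn$frames$polarity)[c("white", "black")]),
               c(50L, 50L))
  # exactly one dot in each of the 12 scheduling cells, every frame
  cell_w <- 108 / 4; cell_h <- 76 / 3
  col <- 1L + floor((sn$dots$azimuth + 54) / cell_w)
  row <- 1L + floor((sn$dots$elevation + 38) / cell_h)
  per_frame <- table(sn$dots$frame_index, paste(col, row))
  expect_true(all(per_frame == 1))
  # defaults carry the standard design values
  expect_equal(sn$dot_size_deg, 5)
  expect_equal(sn$frames$duration_s[1], 0.1)
})

test_that("sparse-noise schedules are deterministic per seed and reject oversized dots", {
  a <- make_sparse_noise_schedule(n_frames = 40, seed = 9)
  b <- make_sparse_noise_schedule(n_frames = 40, seed = 9)
  expect_identical(a, b)
  c <- make_sparse_noise_schedule(n_frames = 40, seed = 10)
  expect_false(identical(a$dots, c$dots))
  expect_error(make_sparse_noise_schedule(grid_shape = c(20, 20)),
               "exceeds the grid cell")
  expect_error(make_sparse_noise_schedule(n_frames = 99), "even")
})

test_that("grating schedules are a shuffled full factorial", {
  gr <- make_grating_schedule()
  expect_equal(nrow(gr$conditions), 120)       # 6 x 5 x 4
  expect_equal(nrow(gr$events), 600)           # 5 repeats
  expect_true(all(range(gr$conditions$spatial_frequency) == c(0.1, 1.6)))
  expect_equal(sort(unique(gr$conditions$orientation)),
               seq(0, 150, by = 30))
  # shuffled order is a permutation of the unshuffled event multiset
  expect_equal(sort(table(gr$events$stim_id)),
               sort(table(rep(gr$conditions$condition_id, 5))))
  one <- make_grating_schedule(n_orientations = 1, sf_values = 0.4, n_phases = 1)
  expect_equal(nrow(one$conditions), 1)
  expect_error(make_grating_schedule(n_repeats = 0), "n_repeats")
})

test_that("same-seed grating schedules are identical; different seeds only reorder", {
  a <- make_grating_schedule(seed = 3)
  b <- make_grating_schedule(seed = 3)
  d <- make_grating_schedule(seed = 4)
  expect_identical(a, b)
  expect_identical(a$conditions, d$conditions)
  expect_equal(sort(a$events$stim_id), sort(d$events$stim_id))
  expect_false(identical(a$events$stim_id, d$events$stim_id))
})

test_that("texture bank matches the 15x5 design with spectrally matched noise", {
  tb <- make_texture_bank(image_shape = c(32, 32), seed = 5)
  expect_equal(vstream:::n_images(tb), 150)
  expect_equal(sum(tb$category == "texture"), 75)
  expect_equal(sum(tb$category == "noise"), 75)
  expect_equal(tb$repeats[1], 5L)
  # every texture has a spectrally matched partner (amplitude spectra equal)
  n_tex <- 75
  rel_err <- vapply(seq_len(10), function(i) {
    a <- Mod(fft(tb$pixels[, , i]))
    b <- Mod(fft(tb$pixels[, , i + n_tex]))
    max(abs(a - b)) / max(a)
  }, numeric(1))
  expect_true(all(rel_err <= 1e-6))
  expect_true(all(tb$pixels >= 0 & tb$pixels <= 1))
  expect_error(make_texture_bank(image_shape = c(8, 8)), "at least 16")
  expect_error(make_texture_bank(image_shape = c(32, 16)), "square")
})

test_that("within-family texture correlations exceed across-family correlations", {
  tb <- make_texture_bank(n_families = 6, samples_per_family = 4,
                          image_shape = c(32, 32), seed = 11)
  tex <- which(tb$category == "texture")
  M <- sapply(tex, function(i) as.vector(tb$pixels[, , i]))
  cc <- cor(M)
  fam <- tb$family[tex]
  same <- outer(fam, fam, "==") & upper.tri(cc)
  diff <- outer(fam, fam, "!=") & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff]))
})

test_that("object bank counts and composition follow the requested design", {
  ob <- make_object_bank(n_objects = 60, n_faces = 20, image_shape = c(32, 32))
  expect_equal(vstream:::n_images(ob), 80)
  expect_equal(sum(ob$category == "face"), 20)
  nf <- make_object_bank(n_objects = 10, n_faces = 0, image_shape = c(32, 32))
  expect_false("face" %in% nf$category)
  expect_identical(make_object_bank(20, 5, c(32, 32), seed = 2),
                   make_object_bank(20, 5, c(32, 32), seed = 2))
})

test_that("faces cluster in feature space relative to objects", {
  ob <- make_object_bank(n_objects = 60, n_faces = 25, image_shape = c(32, 32),
                         seed = 3)
  fb <- extract_features(ob, layers = 1, n_pcs = 20, out_dim = 128,
                         seed = 1)[[1]]
  X <- fb$pc_scores
  faces <- ob$category == "face"
  dmat <- as.matrix(dist(X))
  within_face <- mean(dmat[faces, faces][upper.tri(dmat[faces, faces])])
  face_obj <- mean(dmat[faces, !faces])
  expect_lt(within_face, face_obj)
})

test_that("presentation schedules cover each image n_repeats times, blocked or not", {
  ob <- make_object_bank(10, 5, c(32, 32))
  ev <- make_presentation_schedule(ob, n_repeats = 4, blocked = TRUE, seed = 1)
  expect_equal(nrow(ev), 60)
  expect_true(all(table(ev$stim_id) == 4))
  # in blocked mode each block holds every image exactly once
  expect_true(all(table(ev$block, ev$stim_id) == 1))
  ev2 <- make_presentation_schedule(ob, n_repeats = 2, blocked = FALSE, seed = 1)
  expect_true(all(table(ev2$stim_id) == 2))
})
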