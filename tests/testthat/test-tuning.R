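test_that("orientation recovery within 10 degrees (circular) in >= 90% of noisy runs", {
  oris <- rep(seq(0, 150, by = 30), each = 5)
  n_runs <- 100
  ok <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    th0 <- runif(1, 0, 180)
    mu <- 2 + 10 * exp(2 * (cos(2 * (oris - th0) * pi / 180) - 1))
    set.seed(4000 + i)
    r <- rpois(length(mu), mu)
    f <- fit_orientation(r, oris)
    ok[i] <- orientation_error(f$theta_pref, th0) < 10
  }
  expect_gte(mean(ok), 0.9)
})

test_that("orientation fits respect 180-degree periodicity and flag flat cells", {
  oris <- rep(seq(0, 150, by = 30), each = 8)
  mu <- 1 + 8 * exp(3 * (cos(2 * (oris - 170) * pi / 180) - 1))
  set.seed(11)
  f <- fit_orientation(rpois(length(mu), mu), oris)
  expect_lt(orientation_error(f$theta_pref, 170), 10)
  expect_true(f$theta_pref >= 0 && f$theta_pref < 180)
  # circular error can never exceed 90
  expect_lte(max(orientation_error(runif(50, 0, 180), runif(50, 0, 180))), 90)
  flat <- fit_orientation(rep(5, 48), oris)
  expect_false(flat$included)
  expect_equal(flat$A, 0)
  expect_error(fit_orientation(1:6, c(0, 0, 45, 45, 90, 90)), "4 distinct")
})

test_that("spatial-frequency fits recover the peak and scale linearly in amplitude", {
  sfs <- rep(c(0.1, 0.2, 0.4, 0.8, 1.6), each = 6)
  mu <- 2 + 9 * exp(-(log(sfs) - log(0.4))^2 / (2 * 0.6^2))
  set.seed(12)
  r <- rpois(length(mu), mu)
  f <- fit_spatial_frequency(r, sfs)
  expect_lt(abs(log2(f$f_pref) - log2(0.4)), 0.5)      # within half an octave
  # doubling all responses doubles A and B, leaves f_pref unchanged
  f2 <- fit_spatial_frequency(2 * r, sfs)
  expect_equal(f2$f_pref, f$f_pref, tolerance = 1e-6)
  expect_equal(f2$A, 2 * f$A, tolerance = 1e-6)
  flat <- fit_spatial_frequency(rep(3, 30), sfs)
  expect_false(flat$included)
  # monotone responses clamp to the range edge and are flagged
  mono <- fit_spatial_frequency(sfs * 10, sfs)
  expect_true(mono$unbounded)
})

test_that("categorical variance decomposition matches the hand-worked two-level table", {
  # {A: 1, 3; B: 5, 7}: V_total = 5, V_residual = 1 (population variances)
  v <- variance_explained_categorical(c(1, 3, 5, 7), c("A", "A", "B", "B"))
  expect_equal(v$V_total, 5)
  expect_equal(v$V_residual, 1)
  expect_equal(v$pct_explained, 80)
  # equal within level, different across -> 100%
  v2 <- variance_explained_categorical(c(2, 2, 9, 9), c("A", "A", "B", "B"))
  expect_equal(v2$pct_explained, 100)
  # zero total variance -> undefined
  v3 <- variance_explained_categorical(rep(4, 6), rep(c("A", "B"), 3))
  expect_true(is.na(v3$pct_explained))
})

test_that("decomposition agrees with one-way ANOVA sums of squares", {
  set.seed(13)
  y <- rnorm(60); g <- sample(letters[1:4], 60, replace = TRUE)
  v <- variance_explained_categorical(y, g)
  a <- anova(lm(y ~ g))
  expect_equal(v$pct_explained,
               100 * a$`Sum Sq`[1] / sum(a$`Sum Sq`), tolerance = 1e-10)
})

test_that("shuffled labels explain only the degrees-of-freedom floor", {
  set.seed(14)
  n <- 60; k <- 5
  y <- rnorm(n)
  pct <- replicate(500, {
    variance_explained_categorical(y, sample(rep(1:k, n / k)))$pct_explained
  })
  # E[R^2] under the null = (k - 1)/(n - 1)
  expect_equal(mean(pct), 100 * (k - 1) / (n - 1), tolerance = 0.25)
})

test_that("percentage explained is invariant to affine response transforms", {
  set.seed(15)
  y <- rnorm(40, 10, 3); g <- rep(1:4, 10)
  p0 <- variance_explained_categorical(y, g)$pct_explained
  for (ab in list(c(2, 0), c(-1.5, 7), c(0.1, -3))) {
    p <- variance_explained_categorical(ab[1] * y + ab[2], g)$pct_explained
    expect_equal(p, p0, tolerance = 1e-10)
  }
})

test_that("area-scope percentage pools variances across cells before normalizing", {
  set.seed(16)
  g <- rep(1:3, each = 6)
  m <- rbind(rnorm(18, g, 0.2), rnorm(18, 0, 1))   # one tuned, one untuned cell
  va <- variance_explained_categorical(m, g, scope = "area")
  v1 <- variance_explained_categorical(m[1, ], g)
  v2 <- variance_explained_categorical(m[2, ], g)
  expect_equal(va$V_total, v1$V_total + v2$V_total)
  expect_equal(va$V_residual, v1$V_residual + v2$V_residual)
  # pooled percentage lies between the per-cell percentages
  expect_gt(va$pct_explained, min(v1$pct_explained, v2$pct_explained))
  expect_lt(va$pct_explained, max(v1$pct_explained, v2$pct_explained))
})

test_that("texture divergence finds area-ordered latencies and is two-tailed", {
  tb <- make_texture_bank(n_families = 5, samples_per_family = 3,
                          image_shape = c(32, 32), seed = 6)
  te <- make_presentation_schedule(tb, n_repeats = 6, blocked = FALSE, seed = 7)
  mk_area <- function(lat, gain, seed) {
    nn <- make_ground_truth_neurons(n_per_area = 15, areas = "X",
                                    latency_s = lat, texture_gain_hz = gain,
                                    seed = seed)
    nn$units$latency <- lat
    nn$units$texture_gain <- gain
    nn$units$baseline_rate <- 5
    nn$family_weights[] <- 0
    simulate_session(nn, textures = list(bank = tb, events = te), seed = seed)
  }
  s_fast <- mk_area(0.045, 10, 41)   # V2-like: early texture modulation
  s_slow <- mk_area(0.090, 10, 42)   # V1-like: late
  # require 3 consecutive significant bins so single chance bins (per-bin
  # alpha with no multiplicity correction) cannot shadow the true onset
  d_fast <- texture_divergence(s_fast$spikes, s_fast$events, tb, consecutive = 3)
  d_slow <- texture_divergence(s_slow$spikes, s_slow$events, tb, consecutive = 3)
  expect_lt(d_fast$divergence_latency, d_slow$divergence_latency)
  expect_lte(abs(d_fast$divergence_latency - 0.045), 0.02)
  expect_lte(abs(d_slow$divergence_latency - 0.090), 0.02)
  # a sign flip (noise > texture) still triggers the two-tailed test
  s_neg <- mk_area(0.045, -10, 43)
  d_neg <- texture_divergence(s_neg$spikes, s_neg$events, tb)
  expect_false(is.na(d_neg$divergence_latency))
  expect_error(texture_divergence(s_fast$spikes, s_fast$events, tb,
                                  units = 1:5), "at least 10")
})

test_that("family-identity variance rises after response latency and needs k >= 2", {
  tb <- make_texture_bank(n_families = 6, samples_per_family = 3,
                          image_shape = c(32, 32), seed = 8)
  te <- make_presentation_schedule(tb, n_repeats = 8, blocked = FALSE, seed = 9)
  nn <- make_ground_truth_neurons(n_per_area = 12, areas = "X",
                                  latency_s = 0.05, family_gain_hz = 12,
                                  seed = 44)
  nn$units$latency <- 0.05
  nn$units$texture_gain <- 0
  sess <- simulate_session(nn, textures = list(bank = tb, events = te),
                           seed = 45)
  tc <- texture_family_variance_timecourse(sess$spikes, sess$events, tb,
                                           bin_s = 0.02)
  pre <- mean(tc$pct_explained[tc$time < 0.04])
  post <- mean(tc$pct_explained[tc$time >= 0.06 & tc$time <= 0.15])
  expect_gt(post, pre + 5)
  one_family <- tb
  one_family$family[] <- 1L
  expect_error(
    texture_family_variance_timecourse(sess$spikes, sess$events, one_family),
    "k >= 2")
})
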