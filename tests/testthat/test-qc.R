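test_that("responsiveness z-score follows the Poisson-null arithmetic", {
  # constructed unit: baseline counts average 1.0 per 50-ms window
  # (lambda-hat = 2.0 in the 100-ms response window), mean evoked 3.0,
  # N = 100 trials -> z = (3 - 2) / sqrt(2/100) = 7.071
  events <- sim_events(100)
  spikes <- do.call(rbind, lapply(seq_len(100), function(i) {
    on <- events$onset_s[i]
    data.frame(unit_id = 1, area = "A",
               time_s = c(on - 0.025, on + runif(3, 0.005, 0.095)),
               amplitude = 1)
  }))
  r <- test_responsive(spikes, events)
  expect_equal(r$lambda_baseline, 2.0)
  expect_equal(r$mean_evoked, 3.0)
  expect_equal(r$z, 1 / sqrt(2 / 100), tolerance = 1e-12)
  expect_true(r$responsive)
})

test_that("evoked activity equal to baseline gives z near zero and no flag", {
  set.seed(21)
  spikes <- sim_constant_spikes(5, rate_hz = 20, t_end = 80, seed = 3)
  events <- sim_events(200, t0 = 1)
  r <- test_responsive(spikes, events)
  expect_true(all(abs(r$z) < 4))
  expect_false(any(r$responsive))
  # silent units never divide by zero
  mute <- data.frame(unit_id = 9, area = "A", time_s = 0.001, amplitude = 1)
  r0 <- test_responsive(mute, events)
  expect_true(is.finite(r0$z))
  expect_error(test_responsive(spikes, events[1:5, ]), "at least 10")
})

test_that("raising the threshold never enlarges the responsive set", {
  set.seed(22)
  spikes <- sim_constant_spikes(20, rate_hz = 15, t_end = 40, seed = 5)
  events <- sim_events(100, t0 = 0.5)
  r5 <- test_responsive(spikes, events, threshold_sd = 5)
  for (thr in c(6, 8, 10)) {
    rt <- test_responsive(spikes, events, threshold_sd = thr)
    expect_true(all(rt$unit_id[rt$responsive] %in% r5$unit_id[r5$responsive]))
  }
  both <- responsive_any(r5, transform(r5, responsive = FALSE))
  expect_equal(both$responsive_any, r5$responsive)
})

test_that("block stability filter applies the 0.6 x third-largest amplitude rule", {
  # 10 blocks of 100 spikes each; block 4 has amplitudes at 10% of the rest
  blocks <- data.frame(block = 1:10, start = 0:9 * 10, end = 0:9 * 10 + 9.9)
  set.seed(1)
  spikes <- do.call(rbind, lapply(1:10, function(b) {
    amp <- if (b == 4) 10 else 100
    data.frame(unit_id = 1, area = "A",
               time_s = sort(runif(100, blocks$start[b], blocks$end[b])),
               amplitude = amp * exp(rnorm(100, 0, 0.02)))
  }))
  st <- filter_stable_blocks(spikes, blocks)
  expect_equal(nrow(st), 10)
  expect_false(st$kept[st$block == 4])
  expect_true(all(st$kept[st$block != 4]))
  # suprathreshold counts: block 4 has none, others all 100
  expect_equal(st$suprathreshold_count[st$block == 4], 0)
  expect_true(all(st$suprathreshold_count[st$block != 4] == 100))
})

test_that("stability threshold arithmetic and degenerate cases behave", {
  blocks <- data.frame(block = 1:10, start = 0:9 * 10, end = 0:9 * 10 + 9.9)
  # constant amplitudes and equal counts: all blocks kept
  spikes <- do.call(rbind, lapply(1:10, function(b)
    data.frame(unit_id = 1, area = "A",
               time_s = seq(blocks$start[b], blocks$end[b], length.out = 50),
               amplitude = 80)))
  st <- filter_stable_blocks(spikes, blocks)
  expect_true(all(st$kept))
  # amplitudes 10, 9, 8, ...: threshold = 0.6 * 8 = 4.8
  spikes2 <- do.call(rbind, lapply(1:10, function(b)
    data.frame(unit_id = 1, area = "A",
               time_s = seq(blocks$start[b], blocks$end[b], length.out = 20),
               amplitude = 11 - b)))
  st2 <- filter_stable_blocks(spikes2, blocks)
  expect_equal(unname(attr(st2, "amplitude_threshold")), 4.8)
  # fewer than 3 blocks: filter skipped with warning, everything kept
  expect_warning(st3 <- filter_stable_blocks(spikes, blocks[1:2, ]),
                 "fewer than 3")
  expect_true(all(st3$kept))
})

test_that("half-peak latency of a step response is the step time", {
  # rate steps from 2 Hz to 22 Hz at 40 ms after onset, 400 trials
  set.seed(7)
  events <- sim_events(400, duration_s = 0.2, isi_s = 0.2)
  spikes <- local({
    tt <- unlist(lapply(events$onset_s, function(on) {
      base <- runif(rpois(1, 2 * 0.4), -0.1, 0.3) + on
      ev <- runif(rpois(1, 20 * 0.16), 0.04, 0.2) + on
      c(base, ev)
    }))
    data.frame(unit_id = 1, area = "A", time_s = sort(tt), amplitude = 1)
  })
  lat <- half_peak_latency(spikes, events)
  expect_true(lat$passes_peak_test)
  expect_gte(lat$latency_s, 0.035)
  expect_lte(lat$latency_s, 0.045)
  # a flat PSTH is excluded
  flat <- sim_constant_spikes(1, rate_hz = 10, t_end = 170, seed = 8)
  lf <- half_peak_latency(flat, events)
  expect_false(lf$passes_peak_test)
  expect_true(is.na(lf$latency_s))
})

test_that("latency recovery: simulated 30/60/90 ms latencies come back within one bin", {
  gr <- make_grating_schedule(n_repeats = 21, seed = 2)  # ~2500 trials
  meds <- vapply(c(0.030, 0.060, 0.090), function(L) {
    nn <- make_ground_truth_neurons(n_per_area = 3, areas = "V1",
                                    latency_s = L, seed = 31)
    nn$units$latency <- L
    nn$units$baseline_rate <- 4
    nn$units$grating_gain <- 25
    nn$units$vm_kappa <- 0.5
    nn$units$sf_logsigma <- 3
    sess <- simulate_session(nn, gratings = gr, seed = 32)
    lat <- half_peak_latency(sess$spikes, sess$events)
    median(lat$latency_s, na.rm = TRUE)
  }, numeric(1))
  expect_lte(abs(meds[1] - 0.030), 0.005)
  expect_lte(abs(meds[2] - 0.060), 0.005)
  expect_lte(abs(meds[3] - 0.090), 0.005)
})
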