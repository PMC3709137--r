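test_that("ratio pulse train has the canonical structure", {
  spec <- ratio_train_spec()
  expect_equal(nrow(spec$amplitude_pairs), 10)
  ep <- make_ratio_pulse_train(spec, seed = 5)
  expect_equal(nrow(ep$segments), 10)
  expect_equal(ep$n_steps, 10 * 200)
  expect_setequal(
    ep$segments$label,
    c("0:0", "0.5:0.5", "1:0.5", "1.5:0.5", "0.5:1", "1:1", "1.5:1",
      "0.5:1.5", "1:1.5", "1.5:1.5"))
  # reproducible; different seeds differ
  expect_identical(ep$currents, make_ratio_pulse_train(spec, seed = 5)$currents)
  expect_false(identical(ep$currents,
                         make_ratio_pulse_train(spec, seed = 6)$currents))
  expect_error(ratio_train_spec(pulse_ms = 0), "positive")
})

test_that("noiseless pulses follow the first-order RC step response", {
  spec <- ratio_train_spec(noise_sigma = 0)
  ep <- make_ratio_pulse_train(spec, seed = 2, randomize = FALSE)
  # second segment in listed order follows the silent 0:0 pulse, so the
  # filter state is exactly zero at its onset
  seg <- ep$segments[2, ]
  expect_identical(seg$label, "0.5:0.5")
  ks <- (seg$start_step + 1):(seg$start_step + 100)
  expected <- 0.5 * spec$drive_gain * (1 - exp(-(seq_len(100)) * 1 / 10))
  expect_equal(ep$currents[ks, 1], expected, tolerance = 1e-10)

  # the 0:0 pulse is identically zero without noise (first segment in order)
  seg0 <- ep$segments[ep$segments$label == "0:0", ]
  expect_true(all(ep$currents[(seg0$start_step + 1):(seg0$end_step + 1), ]
                  == 0))
})

test_that("synthetic SAWR traces realize the ratio-class structure", {
  quiet <- sawr_spec(trials_per_class = 1, gain_jitter_sd = 0,
                     tau_jitter_sd = 0, drift_sd = 0, diff_drift_sd = 0,
                     noise_sigma = 0)
  tr <- make_synthetic_sawr(quiet, seed = 1)
  expect_equal(sort(unique(tr$class)), paste0("R", 1:5))

  # equal volumes (R3): equal steady-state differentials on both channels
  late <- tr[tr$class == "R3" & tr$time_s == 109, ]
  d <- late$f_uncoated - late$f_coated
  expect_equal(d[1], d[2], tolerance = 1e-2)

  # steady-state ordering across classes follows the volume table (channel 1)
  ss <- vapply(paste0("R", 1:5), function(cl) {
    row <- tr[tr$class == cl & tr$channel == 1 & tr$time_s == 109, ]
    row$f_uncoated - row$f_coated
  }, numeric(1))
  expect_true(all(diff(ss) > 0))
  # oracle: analytic steady state of the first-order model
  cls <- ratio_classes()
  expected <- 100 * (cls$vol1 + 0.1 * cls$vol2) *
    (1 - exp(-(109 - 10) / 15))
  expect_equal(unname(ss), expected, tolerance = 1e-6)

  # zero concentration, drift and noise: coated equals uncoated (flat)
  zero_cls <- ratio_classes()
  zero_cls$vol1 <- zero_cls$vol2 <- 0
  tr0 <- make_synthetic_sawr(sawr_spec(classes = zero_cls,
                                       trials_per_class = 1,
                                       gain_jitter_sd = 0, drift_sd = 0,
                                       diff_drift_sd = 0, noise_sigma = 0),
                             seed = 1)
  expect_true(all(tr0$f_coated == tr0$f_uncoated))
  expect_true(all(tr0$f_coated == 0))

  # reproducibility and label integrity
  tr2 <- make_synthetic_sawr(sawr_spec(trials_per_class = 3), seed = 9)
  expect_identical(tr2, make_synthetic_sawr(sawr_spec(trials_per_class = 3),
                                            seed = 9))
  expect_equal(as.vector(table(tr2$class)), rep(2L * 3L * 151L, 5))
})

test_that("differential current is linear, clamped and common-mode immune", {
  tr <- make_synthetic_sawr(tiny_sawr_spec(), seed = 4)
  flat <- tr
  flat$f_coated <- flat$f_uncoated
  expect_true(all(differential_current(flat, 1)$current == 0))

  c1 <- differential_current(tr, 2e-5)$current
  c2 <- differential_current(tr, 4e-5)$current
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  expect_true(all(c1 >= 0))

  shifted <- tr
  common <- 123.4 + 0.5 * tr$time_s
  shifted$f_coated <- shifted$f_coated + common
  shifted$f_uncoated <- shifted$f_uncoated + common
  expect_equal(differential_current(shifted, 3e-5)$current, 3e-5 *
                 pmax(0, tr$f_uncoated - tr$f_coated) / 1, # same as original
               tolerance = 1e-10)
})

test_that("beta calibration hits the target ORN rate", {
  tr <- make_synthetic_sawr(tiny_sawr_spec(), seed = 6)
  cal <- calibrate_beta(tr, target_rate = 50)
  sim_rate <- length(lif_run(rep(cal$current_max, 2000))$spike_steps) / 2
  expect_lt(abs(sim_rate - 50) / 50, 0.05)

  # linearity: doubling all traces halves beta
  tr2 <- tr
  tr2$f_coated <- 2 * tr2$f_coated
  tr2$f_uncoated <- 2 * tr2$f_uncoated
  expect_equal(calibrate_beta(tr2)$beta, cal$beta / 2, tolerance = 1e-10)

  flat <- tr
  flat$f_uncoated <- flat$f_coated
  expect_error(calibrate_beta(flat), "calibrate")

  # closed-form variant agrees with the continuous f-I inversion
  cf <- calibrate_beta(tr, method = "closed_form")
  expect_equal(lif_rate_closed_form(cf$current_max), 50, tolerance = 1e-9)
})

test_that("grid resampling preserves structure", {
  t_s <- 0:150
  x <- matrix(c(rep(2, 151), seq(0, 15, length.out = 151)), ncol = 2)
  m <- resample_to_grid(t_s, x, compression = 10, delta = 1)
  expect_equal(nrow(m), 1501)
  expect_true(all(m[, 1] == 2))         # piecewise-constant preserved
  expect_equal(m[, 2], seq(0, 15, length.out = 1501), tolerance = 1e-9)

  # identity when sampling already matches the grid
  ident <- resample_to_grid(0:10, cbind(sin(0:10)), compression = 1,
                            delta = 1)
  expect_equal(as.numeric(ident), sin(0:10), tolerance = 1e-12)

  expect_error(resample_to_grid(numeric(0), cbind(1)), "empty|alignment")
  expect_error(resample_to_grid(0:10, cbind(1:5)), "alignment")
  expect_error(resample_to_grid(0:10, cbind(1:11), compression = 0),
               "positive")
})

test_that("sensor episodes are labeled per trial and normalized per trial", {
  tr <- make_synthetic_sawr(tiny_sawr_spec(), seed = 2)
  cal <- calibrate_beta(tr)
  se <- sensor_episodes(tr, cal)
  expect_equal(length(se$episodes), 20)
  expect_equal(as.vector(table(se$labels)), rep(4L, 5))
  # per-trial normalization: every trial's peak reaches the ceiling current
  peaks <- vapply(se$episodes, function(e) max(e$currents), numeric(1))
  expect_equal(peaks, rep(cal$beta * cal$max_differential, 20),
               tolerance = 1e-6)
  # raw mode: peaks scale with trial amplitude, at most the ceiling
  raw <- sensor_episodes(tr, cal, normalize = "none")
  peaks_raw <- vapply(raw$episodes, function(e) max(e$currents), numeric(1))
  expect_true(all(peaks_raw <= cal$beta * cal$max_differential + 1e-12))
  expect_gt(stats::sd(peaks_raw), 0)
})
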