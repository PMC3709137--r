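test_that("time-constant correction reproduces the exact exponential", {
  expect_equal(correct_tau(10, 1), 10.508331944775, tolerance = 1e-12)
  expect_equal(correct_tau(10, 0.001), 10.0005000083332, tolerance = 1e-10)
  expect_error(correct_tau(-1, 1), "positive")
  expect_error(correct_tau(10, 0), "positive")

  # algebraic identity 1 - delta/tau_corrected = exp(-delta/tau), any grid
  for (tau in c(1, 5, 10, 20, 100)) {
    for (delta in c(0.01, 0.1, 1, 5)) {
      expect_equal(1 - delta / correct_tau(tau, delta), exp(-delta / tau),
                   tolerance = 8 * .Machine$double.eps)
    }
  }

  # corrected recursion matches v0 * exp(-n delta / tau) on the grid
  set.seed(42)
  for (i in 1:10) {
    tau <- runif(1, 1, 100)
    delta <- runif(1, 0.01, 5)
    n <- sample(10:1000, 1)
    a <- 1 - delta / correct_tau(tau, delta)
    v <- 1
    for (k in seq_len(n)) v <- v * a
    expect_equal(v, exp(-n * delta / tau),
                 tolerance = 10 * n * .Machine$double.eps)
  }
})

test_that("LIF soma decays exactly, saturates, and resets on threshold", {
  p <- lif_params(tau_m = 10, delta = 1)
  s <- lif_state(v = 1)
  for (k in 1:10) s <- lif_step(s, p, 0)
  expect_equal(s$v, exp(-1), tolerance = 1e-12)

  # subthreshold constant current converges to the brute-force fixed point
  i_const <- 0.05   # I * tau_corr / c_m < v_theta
  s <- lif_state()
  for (k in 1:5000) s <- lif_step(s, p, i_const)
  expect_lt(i_const * p$tau_m_corrected / p$c_m, p$v_theta)
  expect_equal(s$v, lif_fixed_point_brute(i_const, p), tolerance = 1e-10)
  expect_equal(s$v, i_const * p$tau_m_corrected / p$c_m, tolerance = 1e-10)

  # threshold crossing: spike flag and same-step reset to v_ahp = 0
  s <- lif_step(lif_state(v = 0.95), p, 0.2)
  expect_true(s$spiked)
  expect_identical(s$v, 0)

  expect_error(lif_params(tau_m = 0), "positive")
  expect_error(lif_params(v_theta = 0, v_ahp = 0), "exceed")
})

test_that("no spontaneous activity from rest with zero input", {
  p <- lif_params()
  s <- lif_state()
  for (k in 1:2000) {
    s <- lif_step(s, p, 0)
    expect_false(s$spiked)
  }
  expect_identical(s$v, 0)
})

test_that("synapse follows the exact-integration EPSC kernel", {
  p <- synapse_params(tau_syn = 5, b = 1, w = 2, delta = 1)
  n <- 40
  tr <- numeric(n)
  s <- synapse_state()
  for (k in seq_len(n)) {
    s <- synapse_step(s, p, presyn_spike = (k == 1))
    tr[k] <- s$i
  }
  expect_equal(tr, epsc_closed_form(2, 5, 1, n), tolerance = 1e-12)

  # zero fixed point without spikes
  s <- synapse_state()
  for (k in 1:50) s <- synapse_step(s, p, FALSE)
  expect_identical(s$i, 0)

  # superposition: spikes at steps 0 and 5 equal sum of shifted kernels
  s <- synapse_state()
  tr2 <- numeric(n)
  for (k in seq_len(n)) {
    s <- synapse_step(s, p, presyn_spike = k %in% c(1, 6))
    tr2[k] <- s$i
  }
  expect_equal(tr2, epsc_closed_form(2, 5, 1, n) +
                 epsc_closed_form(2, 5, 1, n, spike_step = 5),
               tolerance = 1e-12)
})

test_that("synapse response is linear over arbitrary spike trains", {
  p <- synapse_params(tau_syn = 7, b = 1.5, w = -3, delta = 0.5)
  set.seed(7)
  run <- function(spikes) {
    s <- synapse_state()
    vapply(spikes, function(sp) {
      s <<- synapse_step(s, p, sp)
      s$i
    }, numeric(1))
  }
  for (rep in 1:5) {
    tr_a <- runif(80) < 0.15
    tr_b <- runif(80) < 0.15
    merged <- run(tr_a) + run(tr_b)
    expect_equal(run(tr_a | tr_b) + run(tr_a & tr_b), merged,
                 tolerance = 1e-12)
  }
})

test_that("steady firing rate is monotone and matches the closed form", {
  p <- lif_params(delta = 0.02)
  currents <- c(0.106, 0.12, 0.2, 0.5)
  rates <- vapply(currents, function(i) {
    length(lif_run(rep(i, 15 / 0.02 * 1000), p)$spike_steps) / 15
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  cf <- lif_rate_closed_form(currents, p)
  expect_true(all(currents * p$tau_m / p$c_m > 1.05 * p$v_theta))
  expect_true(all(abs(rates - cf) / cf < 0.02))
  # below rheobase the closed form is zero
  expect_identical(lif_rate_closed_form(0.05, p), 0)
})

test_that("quantized exact-integration decay tracks the closed form", {
  expect_error(decay_error_lsb(horizon = 0), "positive")
  expect_error(fixed_point_spec(word_length = 24), "16 or 32")

  # guard-bit (residual-preserving) rounding: within half an LSB throughout
  e <- decay_error_lsb(lif_params(), fixed_point_spec(), horizon = 1000)
  expect_lte(e$max_error_lsb, 0.5)
  expect_identical(e$error_lsb[1], e$v_lsb[1] -
                     round((2^31 - 1) * exp(-0.1)))

  # uncorrected forward-Euler factor drifts off and keeps growing
  eu <- decay_error_lsb(lif_params(), fixed_point_spec(), horizon = 1000,
                        corrected = FALSE)
  expect_gt(eu$max_error_lsb, 0.5)
  expect_gt(abs(eu$error_lsb[10]), abs(eu$error_lsb[1]))  # drift accumulates

  # plain round-to-nearest stalls at a small-value plateau
  en <- decay_error_lsb(lif_params(),
                        fixed_point_spec(rounding = "nearest"),
                        horizon = 1000)
  expect_gt(en$max_error_lsb, 0.5)
  expect_identical(en$v_lsb[1000], en$v_lsb[500])  # stuck plateau
})
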