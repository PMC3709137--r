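test_that("STDP kernel follows the asymmetric exponential rule", {
  p <- stdp_params()
  expect_equal(stdp_delta(0, p), 75)                       # coincident pair
  expect_equal(stdp_delta(-20, p), 27.5909580878582, tolerance = 1e-12)
  expect_lt(stdp_delta(10, p), 0)                          # pre after post
  expect_equal(stdp_delta(10, p), -75 * exp(-0.5), tolerance = 1e-12)
  # magnitude decays with |dt| on both branches
  expect_true(all(diff(stdp_delta(seq(0, -100, by = -5), p)) < 0))
  expect_true(all(diff(abs(stdp_delta(seq(1, 100, by = 5), p))) < 0))
  expect_error(stdp_params(tau_plus = 0), "positive")
  expect_error(stdp_params(w_min = 5, w_max = 5), "below")
})

test_that("single-step STDP updates potentiate, depress and clip", {
  net <- build_mgc(mgc_config("lca"), seed = 1)
  p <- stdp_params()
  mem <- stdp_memory(net)

  # no spikes: nothing changes
  out <- apply_stdp_step(net, list(orn = integer(), ln = integer()), p,
                         mem, step = 10)
  expect_identical(out$connectome$W_ol, net$W_ol)
  expect_identical(out$connectome$W_ll, net$W_ll)

  # a pre spike 5 ms before the post spike increments that synapse
  mem5 <- mem
  mem5$last_orn[1] <- 5L
  out <- apply_stdp_step(net, list(orn = integer(), ln = 3L), p, mem5,
                         step = 10)
  expect_equal(out$connectome$W_ol[3, 1] - net$W_ol[3, 1],
               stdp_delta(-5, p))
  expect_equal(out$memory$last_ln[3], 10)

  # weight at w_max stays at w_max under potentiation
  capped <- net
  capped$W_ol[3, 1] <- p$w_max
  out <- apply_stdp_step(capped, list(orn = integer(), ln = 3L), p, mem5,
                         step = 10)
  expect_identical(out$connectome$W_ol[3, 1], p$w_max)

  # depression: ORN spike after an LN spike decrements, floored at zero
  memd <- mem
  memd$last_ln[] <- 8L
  out <- apply_stdp_step(net, list(orn = 1L, ln = integer()), p, memd,
                         step = 12)
  expect_true(all(out$connectome$W_ol[, 1] <= net$W_ol[, 1]))
  low <- net
  low$W_ol[, 1] <- 1
  out <- apply_stdp_step(low, list(orn = 1L, ln = integer()), p, memd,
                         step = 12)
  expect_true(all(out$connectome$W_ol[, 1] >= 0))
})

test_that("compiled engine matches the pure-R reference on a tiny network", {
  cfg <- mgc_config("lca", n_ln = 4, n_pn_per_glom = 2, noise_sigma = 0,
                    b = c(2e-3, 2e-3, 2e-3, 2e-3, 2e-3))
  net <- build_mgc(cfg, seed = 3)
  p <- stdp_params()
  n_steps <- 120
  set.seed(99)
  input <- matrix(runif(n_steps * 2, 0, 0.4), n_steps, 2)
  ep <- new_episode_for_test(input, cfg$delta)

  res <- ratiolobe:::mgc_sim_core(
    net$W_ol, net$W_op, net$W_ll, net$W_lp, net$W_pp, net$A_ll, input,
    cfg$delta, cfg$tau_m_orn, cfg$tau_m_ln, cfg$tau_m_pn, cfg$tau_e,
    cfg$tau_i, cfg$v_theta, cfg$v_ahp, cfg$c_m, cfg$b, 0,
    TRUE, p$dw_plus, p$dw_minus, p$tau_plus, p$tau_minus, p$w_min, p$w_max,
    FALSE)

  ref <- reference_sim_stdp(net, input, p)
  expect_equal(res$W_ol, ref$W_ol, tolerance = 1e-10)
  expect_equal(res$W_ll, ref$W_ll, tolerance = 1e-10)
  expect_identical(sort(res$step + res$neuron * 1000),
                   sort(ref$spikes$step + (ref$spikes$neuron - 1) * 1000))
})

test_that("training converges to a stable bounded weight configuration", {
  net <- build_mgc(mgc_config("lca"), seed = 4)
  h0 <- train_stdp(net, epochs = 0, seed = 1)
  expect_equal(nrow(h0$epoch), 0)
  expect_identical(h0$snapshots[["0"]]$W_ol, net$W_ol)
  expect_error(train_stdp(net, epochs = -1), "non-negative")

  h <- train_stdp(net, epochs = 60, seed = 5, snapshot_every = 20)
  # boundedness at every snapshot
  for (sn in h$snapshots) {
    expect_true(all(sn$W_ol >= 0 & sn$W_ol <= 32767))
    expect_true(all(-sn$W_ll >= 0 & -sn$W_ll <= 32767))
  }
  # strict stability: an epoch with zero weight change occurs and is recorded
  expect_false(is.na(h$stability_epoch))
  expect_identical(h$epoch$abs_change[h$stability_epoch], 0)

  # absorbing: re-running an epoch on the stable state with noise disabled
  # changes nothing
  stable <- h$connectome
  stable$config$noise_sigma <- 0
  h2 <- train_stdp(stable, epochs = 1, seed = 77)
  expect_identical(h2$epoch$abs_change, 0)
  expect_identical(h2$connectome$W_ol, stable$W_ol)
})

test_that("training spreads LN input tunings (symmetry breaking)", {
  expect_equal(ln_tuning_pair(2000, 2000), c(0.5, 0.5))
  expect_equal(ln_tuning_pair(3000, 1000), c(0.75, 0.25))

  net <- build_mgc(mgc_config("lca"), seed = 6)
  h <- train_stdp(net, epochs = 100, seed = 8)
  pre <- ln_tuning(net)
  post <- ln_tuning(h$connectome)
  cv <- function(tun) {
    a <- tun$angle_deg[!tun$untuned]
    stats::sd(a) / mean(a)
  }
  expect_gt(cv(post), cv(pre))
})
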