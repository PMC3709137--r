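toy_tset <- function() {
  # two channels, three classes, hand-constructed trajectories
  mk <- function(a, b) cbind(rep(a, 10), rep(b, 10))
  trajectory_set(
    list(mk(1, 2), mk(3, 4), mk(0, 0), mk(0, 2), mk(5, 5), mk(5, 6)),
    labels = c("x", "x", "y", "y", "z", "z"))
}

test_that("class templates are pointwise trial means", {
  tset <- toy_tset()
  tm <- mean_class_trajectory(tset, "x")
  expect_equal(tm$mean, cbind(rep(2, 10), rep(3, 10)))  # mean of (1,2),(3,4)
  expect_equal(tm$n_trials, 2)
  expect_error(mean_class_trajectory(tset, "nope"), "no trials")

  one <- trajectory_set(list(cbind(1:5)), "solo")
  expect_equal(mean_class_trajectory(one, "solo")$mean, cbind(1:5))

  two <- trajectory_set(list(cbind(1:5), cbind(1:5)), c("a", "a"))
  expect_equal(mean_class_trajectory(two, "a")$mean, cbind(1:5))

  expect_error(trajectory_set(list(cbind(1:5), cbind(1:6)), c("a", "a")),
               "dimensions")
})

test_that("trajectory distance is the step-averaged Euclidean norm", {
  a <- cbind(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50))
  expect_equal(trajectory_distance(a, a, T_ms = 50), 0)

  # constant offset c in one channel integrates to exactly c
  b <- a
  b[, 1] <- b[, 1] + 0.7
  expect_equal(trajectory_distance(a, b, T_ms = 50), 0.7, tolerance = 1e-12)
  expect_equal(trajectory_distance(a, b, T_ms = 20), 0.7, tolerance = 1e-12)

  # homogeneity under joint scaling
  expect_equal(trajectory_distance(3 * a, 3 * b, T_ms = 50),
               3 * trajectory_distance(a, b, T_ms = 50), tolerance = 1e-12)

  expect_error(trajectory_distance(a, b, T_ms = 0), "positive")
  expect_error(trajectory_distance(a, b, T_ms = 51), "exceeds")
})

test_that("the decision-time distance satisfies the metric axioms", {
  set.seed(13)
  for (rep in 1:20) {
    x <- matrix(rnorm(60), 20, 3)
    y <- matrix(rnorm(60), 20, 3)
    z <- matrix(rnorm(60), 20, 3)
    dxy <- trajectory_distance(x, y, T_ms = 20)
    dyx <- trajectory_distance(y, x, T_ms = 20)
    dxz <- trajectory_distance(x, z, T_ms = 20)
    dzy <- trajectory_distance(z, y, T_ms = 20)
    expect_gte(dxy, 0)
    expect_equal(dxy, dyx, tolerance = 1e-12)
    expect_lte(dxy, dxz + dzy + 1e-12)
  }
})

test_that("nearest-mean classification picks the argmin with a stable tie rule", {
  tset <- toy_tset()
  tm <- class_templates(tset)
  expect_named(tm, c("x", "y", "z"))

  # unseen equal to a template
  expect_identical(classify_nearest(tm$y$mean, tm, T_ms = 10), "y")

  # hand-computed 3-class distances
  unseen <- cbind(rep(4.5, 10), rep(5, 10))
  d <- vapply(tm, function(t) trajectory_distance(unseen, t, 10), numeric(1))
  expect_identical(classify_nearest(unseen, tm, T_ms = 10),
                   names(tm)[which.min(d)])

  # exact tie broken in favour of the lower class index
  tie <- list(a = list(mean = cbind(rep(0, 10)), label = "a"),
              b = list(mean = cbind(rep(2, 10)), label = "b"))
  class(tie$a) <- class(tie$b) <- "class_template"
  expect_identical(classify_nearest(cbind(rep(1, 10)), tie, T_ms = 10), "a")
  expect_error(classify_nearest(unseen, list(), T_ms = 10), "empty")
})

test_that("leave-one-out curve is perfect for separated classes and honest about errors", {
  set.seed(5)
  mk <- function(mu) matrix(mu + rnorm(40, sd = 0.01), 20, 2)
  tset <- trajectory_set(c(lapply(1:3, function(i) mk(0)),
                           lapply(1:3, function(i) mk(5)),
                           lapply(1:3, function(i) mk(10))),
                         labels = rep(c("a", "b", "c"), each = 3))
  cv <- classification_curve(tset, times = c(5, 10, 20))
  expect_true(all(cv$p_correct == 1))
  expect_equal(attr(cv, "chance"), 1 / 3)

  single <- trajectory_set(list(mk(0), mk(0), mk(5)), c("a", "a", "b"))
  expect_error(classification_curve(single, times = 10), "two trials")
})

test_that("classification is invariant to a consistent channel permutation", {
  net <- build_mgc(sensor_mgc_config(), seed = 2)
  tr <- make_synthetic_sawr(tiny_sawr_spec(), seed = 3)
  se <- sensor_episodes(tr, calibrate_beta(tr))
  tset <- model_trajectories(net, se$episodes, se$labels, seed = 4)
  perm <- sample(tset$n_channels)
  tset_p <- trajectory_set(lapply(tset$trials, function(m) m[, perm]),
                           tset$labels, tset$delta)
  t_grid <- c(200, 400, 600)
  expect_identical(classification_curve(tset, t_grid)$p_correct,
                   classification_curve(tset_p, t_grid)$p_correct)
})

test_that("greedy selection returns the score maximizer deterministically", {
  tr <- make_synthetic_sawr(tiny_sawr_spec(), seed = 7)
  se <- sensor_episodes(tr, calibrate_beta(tr))
  cands <- lapply(1:3, function(i) build_mgc(sensor_mgc_config(), seed = i))

  one <- greedy_select(cands[1], se$episodes, se$labels, times = c(300, 550))
  expect_identical(one$best_index, 1L)
  expect_identical(one$best, cands[[1]])

  sel <- greedy_select(cands, se$episodes, se$labels, times = c(300, 550),
                       seed = 11)
  expect_gte(sel$scores$score[sel$best_index], max(sel$scores$score))
  sel2 <- greedy_select(cands, se$episodes, se$labels, times = c(300, 550),
                        seed = 11)
  expect_identical(sel$best_index, sel2$best_index)
  expect_identical(sel$scores, sel2$scores)
  expect_error(greedy_select(list(), se$episodes, se$labels), "empty")
})
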