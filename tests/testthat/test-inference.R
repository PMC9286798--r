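null_participant <- function(seed, n_per_cond = 32) {
  tt <- quick_task(seed, n_per_cond = n_per_cond)
  sim <- simulate_eeg(tt, group_preset("HA", channels = ch16(),
                                       srate_hz = 128), seed = seed + 900)
  list(sim = sim,
       idx = which(tt$condition != "neutral"),
       labels = factor(sim$trials$condition[
         tt$condition != "neutral"], levels = c("loss", "gain")))
}

test_that("permutation machinery enforces its preconditions", {
  p <- null_participant(1, n_per_cond = 8)
  expect_error(
    permutation_threshold(p$sim$epochs, p$labels,
                          sliding_window_spec(center_grid_ms = 475),
                          n_perm = 10, subset = p$idx),
    "n_perm")
})

test_that("null draws centre at chance and the threshold follows its convention", {
  p <- null_participant(2)
  # a single-value shrinkage grid isolates the Az statistic itself: under
  # label exchange its null is centred at 1/2 (a grid search inside each
  # draw would instead centre the per-window maximum slightly above it)
  null_fix <- permutation_threshold(
    p$sim$epochs, p$labels,
    sliding_window_spec(center_grid_ms = c(100, 475, 900)),
    grid = 0.5, n_perm = 200, alpha = 0.1, seed = 41, subset = p$idx)
  expect_lt(abs(mean(null_fix$null_az) - 0.5), 0.02)
  null <- permutation_threshold(
    p$sim$epochs, p$labels,
    sliding_window_spec(center_grid_ms = c(100, 475, 900)),
    grid = seq(0, 1, by = 0.1), n_perm = 200, alpha = 0.1,
    seed = 42, subset = p$idx)
  expect_gte(mean(null$null_az), 0.5 - 0.02)   # selection can only inflate
  # documented convention: the floor(alpha * n_draws)-th largest pooled draw
  draws <- as.vector(null$null_az)
  expect_equal(null$threshold,
               sort(draws, decreasing = TRUE)[floor(0.1 * length(draws))])
  perw <- permutation_threshold(
    p$sim$epochs, p$labels, sliding_window_spec(center_grid_ms = c(100, 475)),
    grid = c(0, 0.5), n_perm = 100, alpha = 0.05, pooling = "per_window",
    seed = 43, subset = p$idx)
  expect_length(perw$threshold, 2)
  expect_equal(perw$threshold[1],
               sort(perw$null_az[, 1], decreasing = TRUE)[5])
})

test_that("sampled permutation null agrees with exhaustive relabelling on 6 trials", {
  set.seed(31)
  x <- matrix(rnorm(6 * 3), 6, 3)
  grid <- c(0.1, 0.6)
  # exhaustive: all choose(6, 3) = 20 assignments of three 'gain' labels
  combos <- utils::combn(6, 3)
  exhaustive <- apply(combos, 2, function(ix) {
    code <- integer(6); code[ix] <- 1L
    max(loo_az(x, code, grid)$az)
  })
  # three-sample epochs whose middle sample holds x: a narrow window at
  # the centre makes the window-averaged features equal x exactly
  arr <- array(0, dim = c(6, 3, 3))
  arr[, , 2] <- x
  ep <- epoch_set(arr, channels = c("a", "b", "c"),
                  times_ms = c(-500, 0, 500), srate_hz = 2,
                  lock_event = "cue")
  null <- permutation_threshold(ep, rep(0:1, each = 3),
                                sliding_window_spec(width_ms = 2,
                                                    center_grid_ms = 0),
                                grid = grid, n_perm = 400, alpha = 0.1,
                                seed = 7)
  draws <- as.vector(null$null_az)
  expect_true(all(vapply(draws, function(d)
    any(abs(d - exhaustive) < 1e-10), logical(1))))
  expect_lt(abs(mean(draws) - mean(exhaustive)), 0.03)
})

test_that("forward models recover planted patterns and scale correctly", {
  a_true <- c(1.5, -0.5, 2)
  y <- c(1, -2, 0.5, 3)
  x <- outer(y, a_true)                       # trials x channels, rank one
  colnames(x) <- c("c1", "c2", "c3")
  expect_equal(unname(forward_model(x, y)), a_true, tolerance = 1e-12)
  expect_equal(forward_model(x, 2 * y), forward_model(x, y) / 2,
               tolerance = 1e-12)
  expect_error(forward_model(x, rep(1, 4)), "variance")
  # hand-computed fixture: a = X y / (y'y), X = t(x)
  xf <- rbind(c(1, 0, 2, 1),
              c(0, 1, 1, -1),
              c(2, 2, 0, 0))
  yf <- c(1, 2, 0, 1)
  want <- as.numeric(xf %*% yf) / sum(yf^2)   # = c(2, 1, 6)/6
  got <- forward_model(t(xf), yf)
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_equal(want, c(2, 1, 6) / 6)
})

test_that("significant intervals are maximal supra-threshold runs", {
  az <- tibble::tibble(window_ms = seq(0, 100, by = 10),
                       az = c(.5, .6, .9, .95, .9, .6, .5, .9, .5, .5, .5))
  none <- significant_intervals(az, 0.99)
  expect_equal(nrow(none), 0)
  si <- significant_intervals(az, 0.8)
  expect_equal(si$start_ms, c(15, 65))
  expect_equal(si$end_ms, c(45, 75))
  expect_equal(si$peak_ms, c(30, 70))
  # a single supra-threshold window extends half a step each side
  one <- significant_intervals(
    tibble::tibble(window_ms = c(460, 470, 480), az = c(.5, .9, .5)), 0.8)
  expect_equal(c(one$start_ms, one$end_ms), c(465, 475))
})

test_that("per-window thresholds flag windows against their own null", {
  az <- tibble::tibble(window_ms = c(100, 200), az = c(0.8, 0.8))
  null <- structure(list(threshold = c(0.9, 0.7), pooling = "per_window",
                         window_ms = c(100, 200), alpha = 0.05,
                         n_perm = 100), class = "permutation_null")
  si <- significant_intervals(az, null)
  expect_equal(nrow(si), 1)
  expect_equal(si$peak_ms, 200)
})
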