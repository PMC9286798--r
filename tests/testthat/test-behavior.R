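# task tables with raw agent RTs (no STV re-generation) for matching tests
task_rts <- function(seed, speeding = 80) {
  agent <- agent_model(rt_mean_ms = c(gain = 360 - speeding,
                                      loss = 360 - speeding, neutral = 360))
  simulate_task(agent = agent, seed = seed)
}

test_that("matched sets are balanced under planted incentive speeding", {
  for (s in 1:10) {
    m <- match_rt_distributions(task_rts(s))
    expect_equal(length(m$incentive_idx), length(m$neutral_idx))
    expect_equal(anyDuplicated(c(m$incentive_idx, m$neutral_idx)), 0)
    d <- m$diagnostics
    expect_lt(abs(d$smd), 0.1)
    expect_gte(d$var_ratio, 0.8); expect_lte(d$var_ratio, 1.25)
    expect_lte(d$post_gap_ms, max(d$pre_gap_ms, 2))
  }
})

test_that("identical RT distributions match nearly everything, first try", {
  ok <- vapply(1:20, function(s) {
    m <- match_rt_distributions(task_rts(s + 100, speeding = 0))
    d <- m$diagnostics
    # incentive side has ~96 responded trials, neutral ~47: pairs bounded
    # by the neutral count, and nearly all neutral trials find a partner
    d$n_pairs >= 40 && abs(d$smd) < 0.1 && d$caliper == 0.25
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("matching fails loudly when distributions cannot be balanced", {
  tt <- task_rts(1)
  tt$rt_ms[tt$condition != "neutral"] <-
    tt$rt_ms[tt$condition != "neutral"] - 2000    # no overlap at all
  tt$rt_ms <- pmax(tt$rt_ms, 1)
  expect_error(match_rt_distributions(tt), "matching|plausible")
})

test_that("STV extraction averages component amplitudes over the window", {
  fake <- structure(list(
    az = tibble::tibble(window_ms = c(400, 450, 500),
                        az = c(0.9, 0.95, 0.9), lambda = 0, n1 = 2, n2 = 2),
    y = rbind(c(1, 4), c(2, 5), c(6, 6)),
    spec = sliding_window_spec(center_grid_ms = c(400, 450, 500)),
    channels = c("a", "b")), class = "sliding_decode")
  stv <- extract_stv(fake, c(400, 500))
  expect_equal(stv$stv, c(mean(c(1, 2, 6)), mean(c(4, 5, 6))))
  expect_equal(stv$stv[1], 3)
  one <- extract_stv(fake, c(440, 460))
  expect_equal(one$stv, c(2, 5))
  expect_error(extract_stv(fake, c(600, 700)), "window")
})

test_that("the RT regression is exact on noiseless data", {
  trials <- tibble::tibble(trial_index = 1:20,
                           condition = rep(c("gain", "loss"), 10),
                           rt_ms = NA_real_,
                           outcome = rep(c(1, -1), each = 10),
                           target_duration_ms = 300)
  stv <- sin(1:20)
  trials$rt_ms <- 500 - 12 * stv
  fit <- suppressWarnings(fit_rt_regression(trials, stv))
  expect_equal(fit$estimate[fit$term == "stv"], -12, tolerance = 1e-9)
  expect_equal(fit$estimate[fit$term == "trial_order"], 0, tolerance = 1e-9)
  expect_equal(fit$estimate[fit$term == "trial_outcome"], 0,
               tolerance = 1e-9)
  expect_equal(fit$estimate[fit$term == "intercept"], 500, tolerance = 1e-9)
})

test_that("regression coefficients match hand-solved normal equations", {
  set.seed(8)
  trials <- tibble::tibble(trial_index = 1:12,
                           condition = "gain",
                           rt_ms = round(rnorm(12, 300, 30), 1),
                           outcome = rep(c(1, -1), 6),
                           target_duration_ms = 300)
  stv <- round(rnorm(12), 2)
  fit <- fit_rt_regression(trials, stv)
  x <- cbind(1, stv, 1:12, trials$outcome)
  beta <- solve(t(x) %*% x, t(x) %*% trials$rt_ms)
  expect_equal(fit$estimate, as.numeric(beta), tolerance = 1e-9)
  # residuals orthogonal to every design column
  resid <- trials$rt_ms - x %*% beta
  expect_lt(max(abs(t(x) %*% resid)), 1e-8)
})

test_that("degenerate designs are rejected with the offending column named", {
  trials <- tibble::tibble(trial_index = 1:12, condition = "gain",
                           rt_ms = rnorm(12, 300, 10), outcome = 1,
                           target_duration_ms = 300)
  expect_error(fit_rt_regression(trials, rnorm(12)), "trial_outcome")
  trials$outcome <- rep(c(1, -1), 6)
  expect_error(fit_rt_regression(trials, rep(2, 12)), "stv")
})

test_that("group test has the right df, direction handling and degeneracy", {
  set.seed(10)
  betas <- rnorm(22, -1, 0.5)
  res <- group_beta_test(betas, "negative")
  expect_equal(res$df, 21)
  expect_equal(res$t, mean(betas) / (sd(betas) / sqrt(22)),
               tolerance = 1e-12)
  expect_lt(res$p, 0.05)
  # wrong direction flips to the complementary tail
  expect_equal(group_beta_test(betas, "positive")$p, 1 - res$p,
               tolerance = 1e-12)
  zero <- group_beta_test(rep(0, 10), "negative")
  expect_true(is.na(zero$t))
  expect_equal(zero$p, 1)
})

test_that("directional test power matches the noncentral-t prediction", {
  n <- 22; mu <- -0.5
  crit <- qt(0.05, n - 1)
  analytic <- pt(crit, n - 1, ncp = mu * sqrt(n))
  set.seed(11)
  rejected <- vapply(1:1000, function(i) {
    b <- rnorm(n, mu, 1)
    group_beta_test(b, "negative")$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejected) - analytic), 0.04)
})
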