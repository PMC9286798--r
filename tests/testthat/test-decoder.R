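test_that("window averaging obeys the closed-interval sample rule", {
  ep <- tiny_epochs(n_trials = 2, srate = 256, span = c(-500, 2000),
                    fill = function(tr, ch, t) tr * 1.5)
  xm <- window_average(ep, 470 - 30, 470 + 30)
  expect_equal(xm, matrix(c(1.5, 3), 2, 3,
                          dimnames = list(NULL, ep$channels)),
               ignore_attr = FALSE)
  # 60 ms at 256 Hz covers 15 or 16 sample centres depending on alignment
  # (for every window fully inside the epoch span)
  counts <- vapply(seq(-200, 1970, by = 10), function(tau) {
    sum(ep$times_ms >= tau - 30 & ep$times_ms <= tau + 30)
  }, numeric(1))
  expect_true(all(counts %in% c(15, 16)))
  # a linear ramp averages to its value at the window centre
  ramp <- tiny_epochs(n_trials = 1, srate = 250, span = c(0, 1000),
                      fill = function(tr, ch, t) 0.25 * t)
  expect_equal(as.numeric(window_average(ramp, 500 - 30, 500 + 30)[1, 1]),
               0.25 * 500, tolerance = 1e-9)
})

test_that("covariance shrinkage interpolates to nu*I and preserves trace", {
  s <- matrix(c(2, 0, 0, 4), 2, 2)
  expect_equal(regularize_covariance(s, 0), s)
  expect_equal(regularize_covariance(s, 1), 3 * diag(2))
  set.seed(4)
  for (i in 1:20) {
    d <- sample(2:8, 1)
    a <- matrix(rnorm(d * d), d)
    spd <- crossprod(a) + 0.1 * diag(d)
    lam <- runif(1)
    st <- regularize_covariance(spd, lam)
    expect_lt(abs(sum(diag(st)) - sum(diag(spd))), 1e-10)
    expect_lt(max(abs(st - t(st))), 1e-12)
  }
  expect_error(regularize_covariance(matrix(c(1, 2, 0, 1), 2), 0.5),
               "symmetric")
})

test_that("fisher weights solve the pooled system on hand-checked toys", {
  # class 1: sample covariance exactly diag(1, 4), mean (0, 0)
  a <- sqrt(1.5); b <- sqrt(6)
  x1 <- rbind(c(a, 0), c(-a, 0), c(0, b), c(0, -b))
  x2 <- sweep(x1, 2, c(1, 0), "+")
  fit <- fit_fisher(x1, x2, lambda = 0)
  expect_equal(unname(fit$w), c(1, 0), tolerance = 1e-12)
  expect_equal(unname(fit$m2 - fit$m1), c(1, 0))
  # whitened case: identity pooled covariance gives w = m2 - m1
  set.seed(9)
  z <- matrix(rnorm(40), 20, 2)
  fitw <- fit_fisher(z, sweep(z, 2, c(2, -1), "+"), lambda = 1)
  nu <- sum(diag(cov(z))) / 2
  expect_equal(unname(fitw$w), c(2, -1) / nu, tolerance = 1e-9)
})

test_that("no direction beats the fisher solution on the separability toy", {
  a <- sqrt(1.5); b <- sqrt(6)
  x1 <- rbind(c(a, 0), c(-a, 0), c(0, b), c(0, -b))
  x2 <- sweep(x1, 2, c(1, 0), "+")
  crit <- function(w) {
    y1 <- x1 %*% w; y2 <- x2 %*% w
    (mean(y2) - mean(y1))^2 / (var(as.numeric(y1)) + var(as.numeric(y2)))
  }
  best <- crit(c(1, 0))
  angles <- seq(0, pi, length.out = 3600)
  others <- vapply(angles, function(th) crit(c(cos(th), sin(th))),
                   numeric(1))
  expect_true(all(others <= best + 1e-9))
})

test_that("leave-one-out Az matches the brute-force oracle exactly", {
  set.seed(12)
  for (rep in 1:12) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1); d <- sample(2:6, 1)
    x <- matrix(rnorm((n1 + n2) * d), n1 + n2, d)
    code <- rep(c(0L, 1L), c(n1, n2))
    for (lam in c(0, 0.27, 1)) {
      got <- loo_az(x, code, lam)
      want <- oracle_loo(x, code, lam)
      expect_equal(got$az, want$az, tolerance = 1e-10)
      expect_equal(as.numeric(attr(got, "y_loo")), want$y,
                   tolerance = 1e-8)
    }
  }
  # more channels than trials: pseudo-inverse route, still oracle-exact
  x <- matrix(rnorm(6 * 10), 6, 10)
  code <- rep(0:1, each = 3)
  got <- loo_az(x, code, c(0, 0.4))
  expect_equal(got$az[1], oracle_loo(x, code, 0)$az, tolerance = 1e-8)
  expect_equal(got$az[2], oracle_loo(x, code, 0.4)$az, tolerance = 1e-8)
})

test_that("Az respects its symmetries", {
  set.seed(13)
  x <- matrix(rnorm(30 * 4), 30, 4)
  code <- rep(0:1, 15)
  lam <- c(0.1, 0.5)
  got <- loo_az(x, code, lam)
  az <- got$az
  expect_true(all(az >= 0 & az <= 1))
  # swapping the class labels retrains a sign-flipped discriminant, so the
  # held-out projections negate and performance is unchanged
  flip <- loo_az(x, 1L - code, lam)
  expect_equal(attr(flip, "y_loo"), -attr(got, "y_loo"), tolerance = 1e-9)
  expect_equal(flip$az, az, tolerance = 1e-12)
  # for FIXED scores, relabelling complements the ROC area
  y <- attr(got, "y_loo")[, 1]
  expect_equal(oracle_auc(y, 1L - code), 1 - oracle_auc(y, code),
               tolerance = 1e-12)
  # rank statistics ignore common positive rescaling of the data
  az_scaled <- loo_az(3.7 * x, code, lam)$az
  expect_equal(az_scaled, az, tolerance = 1e-12)
})

test_that("lambda optimization scans the full grid and prefers shrinkage when needed", {
  set.seed(14)
  x <- matrix(rnorm(20 * 3), 20, 3)
  code <- rep(0:1, 10)
  opt <- optimize_lambda(x, code)
  expect_equal(nrow(opt$path), 101)
  expect_true(opt$lambda >= 0 && opt$lambda <= 1)
  expect_equal(opt$az, max(opt$path$az))
  # high-dimensional, strongly collinear noise: shrinkage should win mostly
  wins <- vapply(1:10, function(s) {
    set.seed(100 + s)
    base <- matrix(rnorm(12 * 2), 12, 2)
    x <- base %*% matrix(rnorm(2 * 24), 2, 24) +
      0.2 * matrix(rnorm(12 * 24), 12, 24)
    x[7:12, 1:4] <- x[7:12, 1:4] + 1
    optimize_lambda(x, rep(0:1, each = 6),
                    grid = seq(0, 1, by = 0.05))$lambda > 0
  }, logical(1))
  expect_gte(mean(wins), 0.6)
})

test_that("identical class distributions leave Az near chance for every lambda", {
  set.seed(15)
  x <- matrix(rnorm(60 * 4), 60, 4)
  path <- loo_az(x, rep(0:1, 30), seq(0, 1, by = 0.1))
  expect_true(all(abs(path$az - 0.5) < 0.2))
})

test_that("sliding analysis covers the stated grid and skips impossible windows", {
  ep <- tiny_epochs(n_trials = 8, channels = c("Pz", "Cz"), srate = 64,
                    span = c(-500, 2000),
                    fill = function(tr, ch, t) rnorm(length(t)))
  set.seed(16)
  ep$data[] <- rnorm(length(ep$data))
  dec <- suppressMessages(
    sliding_analysis(ep, rep(0:1, 4),
                     sliding_window_spec(center_grid_ms = seq(-200, 2000,
                                                              by = 10)),
                     grid = c(0.2, 0.8)))
  expect_equal(nrow(dec$az), 221)              # (2000 - (-200))/10 + 1
  # centres past 1970 ms would reach beyond the 2000-ms epoch edge
  expect_true(all(!is.na(dec$az$az[dec$az$window_ms <= 1970])))
  expect_true(all(is.na(dec$az$az[dec$az$window_ms > 1970])))
  # a window reaching past the epoch edge yields a null record, not an error
  wide <- sliding_window_spec(center_grid_ms = c(-490, 0, 1990))
  dec2 <- suppressMessages(
    sliding_analysis(ep, rep(0:1, 4), wide, grid = 0.5))
  expect_true(is.na(dec2$az$az[1]) && is.na(dec2$az$az[3]))
  expect_false(is.na(dec2$az$az[2]))
})

test_that("sliding analysis output is internally consistent", {
  tt <- quick_task(101, n_per_cond = 12)
  sim <- simulate_eeg(tt, group_preset("LA", channels = ch16(),
                                       srate_hz = 128), seed = 7)
  idx <- which(tt$condition != "neutral")
  lab <- factor(sim$trials$condition[idx], levels = c("loss", "gain"))
  dec <- sliding_analysis(sim$epochs, lab,
                          sliding_window_spec(center_grid_ms = c(475, 500)),
                          grid = seq(0, 1, by = 0.1), subset = idx)
  expect_equal(dim(dec$y), c(2, length(idx)))
  expect_equal(dim(dec$weights), c(2, 16))
  # stored y match re-projection with the stored weights
  xm <- window_average(sim$epochs, 475 - 30, 475 + 30)[idx, ]
  expect_equal(dec$y[1, ], as.numeric(xm %*% dec$weights[1, ]),
               tolerance = 1e-9)
})
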