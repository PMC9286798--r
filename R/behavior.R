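#' Match incentive and neutral trials on reaction time
#'
#' For the salience contrast (incentive vs neutral) the two trial sets must
#' not differ systematically in RT, otherwise motor-preparation speed would
#' confound the discrimination. The neutral RT distribution is approximated
#' with a Gaussian; incentive trials implausible under that Gaussian
#' (further than `trim_sd` SDs from its mean) are discarded, and the
#' remaining incentive trials are 1-1 nearest-neighbour matched to neutral
#' trials within a caliper. If the matched sets fail the balance
#' diagnostics, the caliper is tightened stepwise; if no caliper achieves
#' balance the function fails with the diagnostics attached.
#'
#' Matched sets always have exactly equal counts (they are pairs), and the
#' matching never widens the RT mean gap beyond its pre-matching value
#' (up to a 2-ms numerical allowance for the case where the sets were
#' already essentially identical).
#'
#' @param trials Trial table (see [simulate_task()]); only responded trials
#'   (non-missing `rt_ms`) are considered. At least 10 per side required.
#' @param smd_tol Maximum absolute standardized mean difference
#'   (default 0.1).
#' @param var_ratio_bounds Acceptable incentive/neutral RT variance ratio
#'   (default `c(0.8, 1.25)`).
#' @param calipers Decreasing sequence of matching calipers, in units of the
#'   neutral RT standard deviation.
#' @param trim_sd Plausibility trim under the neutral Gaussian (default 2.5).
#' @param min_pairs Minimum acceptable number of matched pairs (default 10).
#' @param seed Unused by the deterministic matcher; kept so callers can
#'   treat all selection utilities uniformly.
#' @return An object of class `match_result`: list with `incentive_idx` and
#'   `neutral_idx` (values of `trial_index`, equal length) and a one-row
#'   `diagnostics` tibble (`n_pairs`, means, variances, `smd`, `var_ratio`,
#'   `ks_stat`, `pre_gap_ms`, `post_gap_ms`, `caliper`).
#' @export
match_rt_distributions <- function(trials, smd_tol = 0.1,
                                   var_ratio_bounds = c(0.8, 1.25),
                                   calipers = c(0.25, 0.15, 0.1, 0.05),
                                   trim_sd = 2.5, min_pairs = 10,
                                   seed = NULL) {
  ok <- !is.na(trials$rt_ms)
  inc <- trials[ok & trials$condition %in% c("gain", "loss"), ]
  neu <- trials[ok & trials$condition == "neutral", ]
  assert_that(nrow(inc) >= 10 && nrow(neu) >= 10,
              "need at least 10 responded trials per side")
  mu_n <- mean(neu$rt_ms); sd_n <- sd(neu$rt_ms)
  pre_gap <- abs(mean(inc$rt_ms) - mu_n)

  # plausible under the fitted neutral Gaussian
  inc <- inc[abs(inc$rt_ms - mu_n) <= trim_sd * sd_n, ]
  assert_that(nrow(inc) >= min_pairs,
              "too few incentive trials plausible under the neutral Gaussian")

  match_at <- function(caliper_ms) {
    # greedy globally-closest 1-1 pairing within the caliper
    d <- abs(outer(inc$rt_ms, neu$rt_ms, "-"))
    pairs_i <- integer(0); pairs_n <- integer(0)
    repeat {
      k <- arrayInd(which.min(d), dim(d))
      if (!is.finite(d[k]) || d[k] > caliper_ms) break
      pairs_i <- c(pairs_i, k[1]); pairs_n <- c(pairs_n, k[2])
      d[k[1], ] <- Inf; d[, k[2]] <- Inf
    }
    list(i = pairs_i, n = pairs_n)
  }

  diag_of <- function(p, caliper) {
    ri <- inc$rt_ms[p$i]; rn <- neu$rt_ms[p$n]
    pooled <- sqrt((var(ri) + var(rn)) / 2)
    tibble(n_pairs = length(p$i),
           mean_incentive_ms = mean(ri), mean_neutral_ms = mean(rn),
           var_incentive = var(ri), var_neutral = var(rn),
           smd = (mean(ri) - mean(rn)) / pooled,
           var_ratio = var(ri) / var(rn),
           ks_stat = suppressWarnings(stats::ks.test(ri, rn)$statistic),
           pre_gap_ms = pre_gap, post_gap_ms = abs(mean(ri) - mean(rn)),
           caliper = caliper)
  }

  last <- NULL
  for (cal in calipers) {
    p <- match_at(cal * sd_n)
    if (length(p$i) < min_pairs) next
    dg <- diag_of(p, cal)
    last <- dg
    balanced <- abs(dg$smd) < smd_tol &&
      dg$var_ratio >= var_ratio_bounds[1] &&
      dg$var_ratio <= var_ratio_bounds[2] &&
      (dg$post_gap_ms <= pre_gap + 1e-9 || dg$post_gap_ms < 2)
    if (balanced) {
      return(structure(list(incentive_idx = inc$trial_index[p$i],
                            neutral_idx = neu$trial_index[p$n],
                            diagnostics = dg), class = "match_result"))
    }
  }
  stop("RT matching failed to reach balance tolerance; last diagnostics: ",
       paste(names(last), format(unlist(last), digits = 3),
             sep = "=", collapse = ", "), call. = FALSE)
}

#' @export
print.match_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<match_result> %d matched pairs; SMD = %.3f, var ratio = %.2f\n",
    d$n_pairs, d$smd, d$var_ratio))
  invisible(x)
}

#' Extract single-trial variability over a time window
#'
#' Averages the per-trial discriminating-component amplitudes `y` of a
#' [sliding_analysis()] over every window centre inside `[start, end]`,
#' giving one STV value per trial — the per-trial amplitude of the
#' component at the analysis window (conventionally the window of maximum
#' significant discrimination, or the a-priori hypothesis window, e.g.
#' 400-550 ms for the valence component).
#'
#' @param decode A `sliding_decode` object.
#' @param window_ms Two-element window `c(start, end)` in ms.
#' @return A tibble with columns `trial` (index within the decoded trials)
#'   and `stv`; attributes `window_ms` and `n_windows`.
#' @export
extract_stv <- function(decode, window_ms = c(400, 550)) {
  stopifnot(inherits(decode, "sliding_decode"))
  sel <- which(decode$az$window_ms >= window_ms[1] &
               decode$az$window_ms <= window_ms[2] &
               !is.na(decode$az$az))
  assert_that(length(sel) > 0,
              "no evaluated window centres inside the STV window")
  stv <- colMeans(decode$y[sel, , drop = FALSE])
  out <- tibble(trial = seq_along(stv), stv = as.numeric(stv))
  attr(out, "window_ms") <- window_ms
  attr(out, "n_windows") <- length(sel)
  out
}

#' Regress reaction times on single-trial variability
#'
#' Per-participant ordinary least squares of RT on the component STV with
#' trial order and task outcome (+1 hit / -1 miss) as nuisance regressors:
#' `rt ~ 1 + stv + trial_order + trial_outcome`. Trials without a response
#' are excluded (their RT is undefined).
#'
#' @param trials Trial table rows corresponding (in order) to the decoded
#'   trials the STV was extracted from.
#' @param stv STV tibble from [extract_stv()] (or a numeric vector).
#' @return A tibble of coefficients: `term`, `estimate`, `se`, `t`; the
#'   number of trials used is in attribute `n_used`.
#' @export
fit_rt_regression <- function(trials, stv) {
  if (is.data.frame(stv)) stv <- stv$stv
  assert_that(nrow(trials) == length(stv),
              "one STV value per trial required")
  df <- tibble(rt = trials$rt_ms, stv = stv,
               trial_order = as.numeric(trials$trial_index),
               trial_outcome = as.numeric(trials$outcome))
  df <- df[stats::complete.cases(df), ]
  assert_that(nrow(df) >= 10, "need at least 10 responded trials")
  const <- vapply(df[c("stv", "trial_order", "trial_outcome")],
                  function(v) var(v) == 0, logical(1))
  if (any(const)) {
    stop("constant regressor(s): ", paste(names(const)[const], collapse = ", "),
         call. = FALSE)
  }
  fit <- lm(rt ~ stv + trial_order + trial_outcome, data = df)
  s <- summary(fit)$coefficients
  out <- tibble(term = c("intercept", "stv", "trial_order", "trial_outcome"),
                estimate = unname(s[, 1]), se = unname(s[, 2]),
                t = unname(s[, 3]))
  attr(out, "n_used") <- nrow(df)
  attr(out, "fit") <- fit
  out
}

#' Group-level directional test on per-participant coefficients
#'
#' One-sample, one-tailed t test of whether the per-participant regression
#' coefficients come from a distribution whose mean lies in the hypothesized
#' direction (`df = n - 1`). The tested direction is a configuration
#' parameter and is recorded in the result. A degenerate input (all
#' coefficients identical at zero) yields a "no evidence" record rather
#' than an error.
#'
#' @param betas Numeric vector, one coefficient per participant (>= 3).
#' @param direction `"negative"` (mean < 0) or `"positive"` (mean > 0).
#' @return One-row tibble: `n`, `mean_beta`, `t`, `df`, `p`, `direction`.
#' @export
group_beta_test <- function(betas, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  betas <- betas[!is.na(betas)]
  assert_that(length(betas) >= 3, "need at least 3 participants")
  n <- length(betas)
  if (sd(betas) == 0) {
    m <- mean(betas)
    t_stat <- if (m == 0) NA_real_ else sign(m) * Inf
    p <- if (m == 0) 1 else {
      hit <- (direction == "negative" && m < 0) ||
             (direction == "positive" && m > 0)
      if (hit) 0 else 1
    }
    return(tibble(n = n, mean_beta = m, t = t_stat, df = n - 1, p = p,
                  direction = direction))
  }
  alt <- if (direction == "negative") "less" else "greater"
  tt <- t.test(betas, alternative = alt)
  tibble(n = n, mean_beta = mean(betas), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, direction = direction)
}
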