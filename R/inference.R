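#' Label-permutation null for sliding-window Az
#'
#' Estimates the Az value corresponding to a significance level `alpha` by
#' rerunning the *complete* discriminant pipeline — including the shrinkage
#' grid search and the leave-one-out projections — on label-permuted data.
#' Because the shrinkage is selected inside every permutation draw, the
#' optimism of selecting `lambda` on the evaluated trials is reflected in
#' the null as well.
#'
#' Two pooling modes are available. `"pooled"` (default) aggregates the null
#' draws across all evaluated windows and returns a single threshold — the
#' single dotted significance line drawn across time in the usual Az-curve
#' figure. `"per_window"` thresholds each window by its own null draws.
#' The threshold is the `m`-th largest null value with
#' `m = floor(alpha * n_draws)` (the empirical `1 - alpha` quantile;
#' for 1000 draws at `alpha = 0.05`, the 50th largest draw).
#'
#' @param x An [epoch_set()].
#' @param labels Two-class labels, one per (subset) trial.
#' @param spec A [sliding_window_spec()] giving the evaluated windows.
#' @param grid Shrinkage grid (as in [optimize_lambda()]).
#' @param n_perm Number of permutation draws (default 1000; fewer than 20
#'   is refused).
#' @param alpha Significance level (default 0.05).
#' @param pooling `"pooled"` or `"per_window"`.
#' @param seed Optional integer seed for the permutations.
#' @param subset Optional logical/integer trial subset (as in
#'   [sliding_analysis()]).
#' @return An object of class `permutation_null`: list with `null_az`
#'   (`n_perm x windows` matrix), `threshold` (scalar for pooled mode, one
#'   per window otherwise), `alpha`, `pooling`, `window_ms`, `n_perm`.
#' @export
permutation_threshold <- function(x, labels, spec = sliding_window_spec(),
                                  grid = seq(0, 1, by = 0.01),
                                  n_perm = 1000, alpha = 0.05,
                                  pooling = c("pooled", "per_window"),
                                  seed = NULL, subset = NULL) {
  pooling <- match.arg(pooling)
  assert_that(n_perm >= 20, "n_perm < 20 gives a meaningless quantile")
  stopifnot(inherits(x, "epoch_set"))
  if (!is.null(subset)) x$data <- x$data[subset, , , drop = FALSE]
  enc <- encode_labels(labels)
  assert_that(length(enc$code) == n_trials(x),
              "labels must match the number of trials")
  assert_that(min(table(enc$code)) >= 2, "need at least 2 trials per class")

  span <- range(x$times_ms)
  keep <- vapply(spec$center_grid_ms, function(tau) {
    wb <- window_bounds(spec, tau)
    wb[1] >= span[1] - 1e-9 && wb[2] <= span[2] + 1e-9
  }, logical(1))
  centers <- spec$center_grid_ms[keep]
  assert_that(length(centers) > 0, "no evaluated window fits the epoch span")
  xms <- lapply(centers, function(tau) {
    wb <- window_bounds(spec, tau)
    t(window_average(x, wb[1], wb[2]))        # channels x trials
  })

  null_az <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, length(centers))
    for (p in seq_len(n_perm)) {
      lab_p <- sample(enc$code)
      for (k in seq_along(xms)) {
        res <- fisher_loo_grid_cpp(xms[[k]], lab_p, grid)
        out[p, k] <- max(res$az)              # lambda selected inside draw
      }
    }
    out
  })

  thr_of <- function(v) {
    m <- max(1L, floor(alpha * length(v)))
    sort(v, decreasing = TRUE)[m]
  }
  threshold <- if (pooling == "pooled") thr_of(as.vector(null_az))
               else apply(null_az, 2, thr_of)

  structure(list(null_az = null_az, threshold = threshold, alpha = alpha,
                 pooling = pooling, window_ms = centers, n_perm = n_perm),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> %d draws x %d windows, alpha = %g (%s)\n",
    x$n_perm, length(x$window_ms), x$alpha, x$pooling))
  cat("  threshold:", format(round(range(x$threshold), 3)), "\n")
  invisible(x)
}

#' Forward model (scalp topography) of a discriminating component
#'
#' Converts a backward decoding model into an interpretable channel-space
#' pattern: `a = X y / (y' y)`, where `X` is the `channels x trials` matrix
#' of window-averaged data and `y` the per-trial component amplitudes. For
#' noiseless rank-one data `X = a y'` this recovers `a` exactly.
#'
#' @param x Numeric matrix `trials x channels` of window-averaged data.
#' @param y Numeric vector of component amplitudes (one per trial), with
#'   non-zero variance.
#' @return Named numeric channel vector.
#' @export
forward_model <- function(x, y) {
  assert_that(nrow(x) == length(y), "one y value per trial required")
  assert_that(stats::var(y) > 0, "y has zero variance; forward model undefined")
  a <- as.numeric(crossprod(x, y) / sum(y^2))
  stats::setNames(a, colnames(x))
}

#' Forward map of a sliding analysis at a given window
#'
#' Recomputes the window average of the epochs at each requested window
#' centre and couples it with the stored full-fit component amplitudes of
#' the [sliding_analysis()] result. With a single centre this is the
#' per-window forward model; with several (e.g. every evaluated centre
#' inside a component's significant interval) the windows are pooled as
#' `a = (sum_tau X_tau y_tau) / (sum_tau y_tau' y_tau)` — the same coupling
#' estimator with the component's windows treated as repeated observations,
#' so high-amplitude windows dominate. This estimates the same scalp
#' pattern with less sampling noise and is the map one reports for a
#' component window.
#'
#' @param x The [epoch_set()] the analysis was run on (after the same
#'   subsetting).
#' @param decode A `sliding_decode` object.
#' @param at_ms Window centre(s); each must be on the evaluated grid.
#' @param subset Optional trial subset, as passed to [sliding_analysis()].
#' @return Named numeric channel vector.
#' @export
decode_forward_map <- function(x, decode, at_ms, subset = NULL) {
  stopifnot(inherits(decode, "sliding_decode"))
  if (!is.null(subset)) x$data <- x$data[subset, , , drop = FALSE]
  num <- numeric(length(decode$channels))
  den <- 0
  for (tau in at_ms) {
    k <- match(tau, decode$az$window_ms)
    assert_that(!is.na(k), "at_ms is not on the evaluated window grid")
    wb <- window_bounds(decode$spec, tau)
    y <- decode$y[k, ]
    assert_that(stats::var(y) > 0, "component amplitudes have zero variance")
    num <- num + as.numeric(crossprod(window_average(x, wb[1], wb[2]), y))
    den <- den + sum(y^2)
  }
  stats::setNames(num / den, decode$channels)
}

#' Intervals of significant discrimination
#'
#' Maximal runs of consecutive windows whose Az exceeds the permutation
#' threshold. Interval edges extend half a grid step beyond the first/last
#' supra-threshold window centre.
#'
#' @param az Az tibble from a [sliding_analysis()] (`$az`) or the
#'   `sliding_decode` object itself.
#' @param null A [permutation_threshold()] result, or a numeric threshold
#'   (scalar or one per window).
#' @return Tibble with columns `start_ms`, `end_ms`, `peak_az`,
#'   `peak_ms` (possibly zero rows).
#' @export
significant_intervals <- function(az, null) {
  if (inherits(az, "sliding_decode")) az <- az$az
  threshold <- if (inherits(null, "permutation_null")) null$threshold else null
  if (inherits(null, "permutation_null") && null$pooling == "per_window") {
    idx <- match(az$window_ms, null$window_ms)
    threshold <- null$threshold[idx]
  }
  sig <- !is.na(az$az) & az$az > threshold
  if (!any(sig)) {
    return(tibble(start_ms = numeric(), end_ms = numeric(),
                  peak_az = numeric(), peak_ms = numeric()))
  }
  step <- if (nrow(az) > 1) min(diff(az$window_ms)) else 0
  r <- rle(sig)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  purrr::map_dfr(runs, function(i) {
    sel <- starts[i]:ends[i]
    pk <- sel[which.max(az$az[sel])]
    tibble(start_ms = az$window_ms[starts[i]] - step / 2,
           end_ms = az$window_ms[ends[i]] + step / 2,
           peak_az = az$az[pk], peak_ms = az$window_ms[pk])
  })
}
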