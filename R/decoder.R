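#' Sliding-window specification
#'
#' Grid of training windows for the sliding discriminant: fixed width
#' (default 60 ms) and centre times from -200 to 2000 ms relative to the cue
#' in 10-ms increments. The window time parameter tau can be interpreted as
#' the window centre (default; the window spans `tau +/- width/2`) or as its
#' onset (`tau .. tau + width`).
#'
#' @param width_ms Window length in ms (default 60).
#' @param center_grid_ms Numeric vector of window times (default
#'   `seq(-200, 2000, by = 10)`).
#' @param align `"center"` (default) or `"onset"`.
#' @return A list of class `sliding_window_spec`.
#' @export
sliding_window_spec <- function(width_ms = 60,
                                center_grid_ms = seq(-200, 2000, by = 10),
                                align = c("center", "onset")) {
  align <- match.arg(align)
  assert_that(width_ms > 0, "width_ms must be positive")
  assert_that(!is.unsorted(center_grid_ms), "window grid must be sorted")
  structure(list(width_ms = width_ms,
                 center_grid_ms = as.numeric(center_grid_ms),
                 align = align), class = "sliding_window_spec")
}

window_bounds <- function(spec, tau) {
  if (spec$align == "center") tau + c(-0.5, 0.5) * spec$width_ms
  else c(tau, tau + spec$width_ms)
}

#' Average epochs within a time window
#'
#' Collapses the sample axis over all samples whose centres fall inside the
#' closed interval `[from_ms, to_ms]`, giving one channel vector per trial —
#' the per-trial features the Fisher discriminant is trained on.
#'
#' @param x An [epoch_set()].
#' @param from_ms,to_ms Window bounds in ms (inclusive on sample centres).
#' @return Numeric matrix `trials x channels` (dimnames carry channel
#'   labels).
#' @export
window_average <- function(x, from_ms, to_ms) {
  stopifnot(inherits(x, "epoch_set"))
  sel <- which(x$times_ms >= from_ms & x$times_ms <= to_ms)
  assert_that(length(sel) > 0, "window contains no samples")
  m <- apply(x$data[, , sel, drop = FALSE], c(1, 2), mean)
  colnames(m) <- x$channels
  m
}

#' Shrink a covariance matrix towards a scaled identity
#'
#' Computes `(1 - lambda) * S + lambda * nu * I` with
#' `nu = trace(S) / D`, the average eigenvalue of `S`. The shrinkage is
#' trace-preserving for every `lambda`: `lambda = 0` returns `S` unchanged
#' and `lambda = 1` the spherical matrix `nu * I`.
#'
#' @param s Symmetric `D x D` covariance matrix.
#' @param lambda Shrinkage intensity in `[0, 1]`.
#' @return The regularized matrix.
#' @export
regularize_covariance <- function(s, lambda) {
  assert_that(is.matrix(s) && nrow(s) == ncol(s), "s must be square")
  assert_that(max(abs(s - t(s))) < 1e-8 * max(1, max(abs(s))),
              "s must be symmetric")
  assert_that(lambda >= 0 && lambda <= 1, "lambda must be in [0, 1]")
  nu <- sum(diag(s)) / nrow(s)
  (1 - lambda) * s + lambda * nu * diag(nrow(s))
}

# class covariance with the package convention: fewer than 2 rows -> zero
class_cov <- function(m) {
  if (nrow(m) < 2) return(matrix(0, ncol(m), ncol(m)))
  cov(m)
}

#' Fit a regularized Fisher discriminant
#'
#' Given window-averaged channel vectors for two classes, shrinks each class
#' covariance ([regularize_covariance()]), pools them as
#' `Sc = (S1 + S2) / 2` and solves `Sc w = m2 - m1` for the spatial weight
#' vector `w` (classes are never explicitly inverted; a pseudo-inverse with
#' a warning is used if `Sc` is singular, e.g. at `lambda = 0` with more
#' channels than trials).
#'
#' @param x1,x2 Numeric matrices `trials x channels` for class 1 and 2.
#' @param lambda Shrinkage intensity in `[0, 1]`.
#' @param window_center_ms Optional bookkeeping tag.
#' @return A list of class `fisher_discriminant`: `w`, `lambda`, `m1`, `m2`,
#'   `s_pooled`, `window_center_ms`.
#' @export
fit_fisher <- function(x1, x2, lambda = 0, window_center_ms = NA_real_) {
  assert_that(nrow(x1) >= 2 && nrow(x2) >= 2,
              "need at least 2 trials per class")
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  s1 <- regularize_covariance(class_cov(x1), lambda)
  s2 <- regularize_covariance(class_cov(x2), lambda)
  sc <- (s1 + s2) / 2
  dm <- m2 - m1
  w <- tryCatch(solve(sc, dm), error = function(e) {
    warning("pooled covariance is singular; using a pseudo-inverse",
            call. = FALSE)
    as.vector(MASS::ginv(sc) %*% dm)
  })
  structure(list(w = stats::setNames(as.numeric(w), colnames(x1)),
                 lambda = lambda, m1 = m1, m2 = m2, s_pooled = sc,
                 window_center_ms = window_center_ms),
            class = "fisher_discriminant")
}

#' @export
print.fisher_discriminant <- function(x, ...) {
  cat(sprintf("<fisher_discriminant> D = %d channels, lambda = %g\n",
              length(x$w), x$lambda))
  invisible(x)
}

#' Project trials onto a fitted discriminant
#'
#' @param fit A [fit_fisher()] object.
#' @param x Numeric matrix `trials x channels`.
#' @return Numeric vector of discriminating-component amplitudes `y`.
#' @export
project_component <- function(fit, x) {
  as.numeric(x %*% fit$w)
}

encode_labels <- function(labels) {
  f <- factor(labels)
  assert_that(nlevels(f) == 2, "labels must have exactly two classes")
  list(code = as.integer(f) - 1L, levels = levels(f))
}

#' Leave-one-out Az of the regularized Fisher discriminant
#'
#' For every trial, refits the discriminant on the remaining trials at the
#' given shrinkage and projects the held-out trial; the leave-one-out Az is
#' the rank-based ROC area of the held-out projections against the labels
#' (ties counted 1/2). Multiple `lambda` values are evaluated in one pass.
#'
#' @param x Numeric matrix `trials x channels`.
#' @param labels Two-class factor/vector, one per trial. The second factor
#'   level is the "positive" class (`w` points from class 1 to class 2).
#' @param lambda Numeric vector of shrinkage values in `[0, 1]`.
#' @return A tibble with columns `lambda` and `az`; attribute `y_loo` holds
#'   the `trials x length(lambda)` matrix of held-out projections.
#' @export
loo_az <- function(x, labels, lambda = 0) {
  enc <- encode_labels(labels)
  assert_that(min(table(enc$code)) >= 2, "need at least 2 trials per class")
  assert_that(all(lambda >= 0 & lambda <= 1), "lambda must be in [0, 1]")
  res <- fisher_loo_grid_cpp(t(x), enc$code, lambda)
  out <- tibble(lambda = as.numeric(lambda), az = as.numeric(res$az))
  attr(out, "y_loo") <- res$y_loo
  out
}

#' Select the shrinkage by leave-one-out performance
#'
#' Grid search over `lambda`, maximizing the leave-one-out Az; ties are
#' broken towards the larger `lambda` (more regularization).
#'
#' @inheritParams loo_az
#' @param grid Candidate shrinkage values (default `seq(0, 1, by = 0.01)`,
#'   101 values).
#' @return A list: `lambda` (selected), `az` (its LOO Az), `path` (tibble of
#'   the full grid), `y_loo` (held-out projections at the selected value).
#' @export
optimize_lambda <- function(x, labels, grid = seq(0, 1, by = 0.01)) {
  assert_that(length(grid) > 0, "empty lambda grid")
  path <- loo_az(x, labels, grid)
  best <- max(path$az)
  pick <- max(which(path$az >= best - 1e-12))   # largest lambda among ties
  list(lambda = path$lambda[pick], az = path$az[pick], path = path,
       y_loo = attr(path, "y_loo")[, pick])
}

#' Sliding-window discriminant analysis
#'
#' Runs the regularized Fisher discriminant independently at every window of
#' a [sliding_window_spec()]: window-averages the epochs, grid-searches the
#' shrinkage by leave-one-out Az, refits on all trials at the selected
#' shrinkage, and stores the per-window weights, full-fit component
#' amplitudes `y`, and held-out projections. Windows that do not fit inside
#' the epoch span, or where either class has fewer than 2 trials, yield a
#' null record (`az = NA`) rather than an error.
#'
#' @param x An [epoch_set()].
#' @param labels Two-class labels, one per trial.
#' @param spec A [sliding_window_spec()].
#' @param grid Shrinkage grid passed to [optimize_lambda()].
#' @return An object of class `sliding_decode`: list with
#'   `az` (tibble: `window_ms`, `az`, `lambda`, `n1`, `n2`),
#'   `weights` (`windows x channels`), `y` (`windows x trials`, full-fit
#'   component amplitudes), `y_loo` (held-out projections at the selected
#'   shrinkage), `labels`, `spec`, `channels`.
#' @export
#' @examples
#' tt <- simulate_task(task_config(n_trials_per_condition = 16), seed = 1)
#' sim <- simulate_eeg(tt, eeg_gen_config(channels = c("Pz", "POz", "CPz")),
#'                     seed = 2)
#' gl <- sim$trials$condition != "neutral"
#' dec <- sliding_analysis(sim$epochs, sim$trials$condition[gl],
#'                         sliding_window_spec(center_grid_ms = c(450, 500)),
#'                         subset = gl)
#' dec$az
sliding_analysis <- function(x, labels, spec = sliding_window_spec(),
                             grid = seq(0, 1, by = 0.01), subset = NULL) {
  stopifnot(inherits(x, "epoch_set"), inherits(spec, "sliding_window_spec"))
  if (!is.null(subset)) {
    x$data <- x$data[subset, , , drop = FALSE]
  }
  assert_that(length(labels) == n_trials(x),
              "labels must match the number of (subset) trials")
  enc <- encode_labels(labels)
  n_win <- length(spec$center_grid_ms)
  n_tr <- n_trials(x)
  az <- rep(NA_real_, n_win); lam <- rep(NA_real_, n_win)
  weights <- matrix(NA_real_, n_win, length(x$channels),
                    dimnames = list(NULL, x$channels))
  y <- matrix(NA_real_, n_win, n_tr)
  y_loo <- matrix(NA_real_, n_win, n_tr)
  span <- range(x$times_ms)
  enough <- min(table(enc$code)) >= 2

  for (k in seq_len(n_win)) {
    wb <- window_bounds(spec, spec$center_grid_ms[k])
    if (wb[1] < span[1] - 1e-9 || wb[2] > span[2] + 1e-9 || !enough) next
    xm <- window_average(x, wb[1], wb[2])
    opt <- optimize_lambda(xm, enc$code, grid)
    az[k] <- opt$az; lam[k] <- opt$lambda
    fit <- fit_fisher(xm[enc$code == 0, , drop = FALSE],
                      xm[enc$code == 1, , drop = FALSE],
                      lambda = opt$lambda,
                      window_center_ms = spec$center_grid_ms[k])
    weights[k, ] <- fit$w
    y[k, ] <- project_component(fit, xm)
    y_loo[k, ] <- opt$y_loo
  }
  n_skipped <- sum(is.na(az))
  if (n_skipped > 0) {
    message(n_skipped, " window(s) outside the epoch span or degenerate; ",
            "null records returned")
  }

  structure(list(
    az = tibble(window_ms = spec$center_grid_ms, az = az, lambda = lam,
                n1 = sum(enc$code == 0), n2 = sum(enc$code == 1)),
    weights = weights, y = y, y_loo = y_loo,
    labels = enc$code, label_levels = enc$levels,
    spec = spec, channels = x$channels), class = "sliding_decode")
}

#' @export
print.sliding_decode <- function(x, ...) {
  ok <- !is.na(x$az$az)
  cat(sprintf("<sliding_decode> %d windows (%d evaluated), %d + %d trials\n",
              nrow(x$az), sum(ok), x$az$n1[1], x$az$n2[1]))
  if (any(ok)) {
    pk <- which.max(x$az$az)
    cat(sprintf("  peak Az = %.3f at %g ms (lambda = %.2f)\n",
                x$az$az[pk], x$az$window_ms[pk], x$az$lambda[pk]))
  }
  invisible(x)
}
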