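#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()` returns
#' the per-unit table (windows, draws, channels, clusters) and `glance()` a
#' one-row summary.
#'
#' @param x A `sliding_decode`, `permutation_null`, `az_comparison`,
#'   `fisher_discriminant` or `match_result` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.sliding_decode <- function(x, ...) x$az

#' @rdname tidiers
#' @export
glance.sliding_decode <- function(x, ...) {
  ok <- !is.na(x$az$az)
  pk <- which.max(x$az$az)
  tibble(n_windows = nrow(x$az), n_evaluated = sum(ok),
         n1 = x$az$n1[1], n2 = x$az$n2[1],
         peak_az = if (length(pk)) x$az$az[pk] else NA_real_,
         peak_ms = if (length(pk)) x$az$window_ms[pk] else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.permutation_null <- function(x, ...) {
  tibble(draw = rep(seq_len(nrow(x$null_az)), times = ncol(x$null_az)),
         window_ms = rep(x$window_ms, each = nrow(x$null_az)),
         az = as.vector(x$null_az))
}

#' @rdname tidiers
#' @export
glance.permutation_null <- function(x, ...) {
  tibble(n_perm = x$n_perm, n_windows = length(x$window_ms),
         alpha = x$alpha, pooling = x$pooling,
         mean_null_az = mean(x$null_az),
         threshold = if (x$pooling == "pooled") x$threshold
                     else mean(x$threshold))
}

#' @rdname tidiers
#' @export
tidy.az_comparison <- function(x, ...) x$clusters

#' @rdname tidiers
#' @export
glance.az_comparison <- function(x, ...) {
  tibble(n_timepoints = nrow(x$t), crit = x$crit, tail = x$tail,
         n_perm = x$n_perm, n_clusters = nrow(x$clusters),
         min_cluster_p = if (nrow(x$clusters)) min(x$clusters$p)
                         else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.fisher_discriminant <- function(x, ...) {
  tibble(channel = names(x$w) %||% paste0("ch", seq_along(x$w)),
         weight = as.numeric(x$w))
}

#' @rdname tidiers
#' @export
tidy.match_result <- function(x, ...) x$diagnostics
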