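#' Assemble per-participant Az curves into a matrix
#'
#' @param curves List of `sliding_decode` objects or of their `$az` tibbles,
#'   all sharing the same window grid.
#' @return Numeric matrix `participants x windows`; window centres in
#'   `colnames`/attribute `window_ms`.
#' @export
az_matrix <- function(curves) {
  rows <- lapply(curves, function(cv) {
    if (inherits(cv, "sliding_decode")) cv <- cv$az
    cv
  })
  grid <- rows[[1]]$window_ms
  for (r in rows) {
    assert_that(isTRUE(all.equal(r$window_ms, grid)),
                "all curves must share the same window grid")
  }
  m <- do.call(rbind, lapply(rows, function(r) r$az))
  colnames(m) <- grid
  attr(m, "window_ms") <- grid
  m
}

# pooled-variance two-sample t statistics per column (group a minus group b)
t_per_timepoint <- function(m, is_a) {
  na <- sum(is_a); nb <- sum(!is_a)
  ma <- colMeans(m[is_a, , drop = FALSE])
  mb <- colMeans(m[!is_a, , drop = FALSE])
  va <- apply(m[is_a, , drop = FALSE], 2, var)
  vb <- apply(m[!is_a, , drop = FALSE], 2, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

cluster_masses <- function(t_stat, crit) {
  supra <- t_stat > crit
  if (!any(supra)) return(list(mass = numeric(0), runs = NULL))
  r <- rle(supra)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  mass <- vapply(runs, function(i) sum(t_stat[starts[i]:ends[i]]), numeric(1))
  list(mass = mass, starts = starts[runs], ends = ends[runs])
}

#' Cluster-based permutation comparison of group Az curves
#'
#' Tests whether discriminator performance differs between two groups over a
#' time window, controlling for the multiplicity of timepoints at the
#' cluster level. Per timepoint an unpaired pooled-variance t statistic
#' (group 1 minus group 2) is computed; contiguous runs exceeding the
#' one-tailed critical value `qt(1 - alpha, df)` form clusters whose mass is
#' the sum of their t values. The null distribution of the maximum cluster
#' mass is obtained by permuting group membership, and each observed
#' cluster's p value is the fraction of null maxima at least as large
#' (with the usual +1 correction). `tail = "greater"` tests group 1 > group
#' 2; `tail = "less"` is evaluated by swapping the groups, so the two calls
#' are exactly symmetric.
#'
#' @param az1,az2 Matrices `participants x windows` ([az_matrix()]) for
#'   group 1 and group 2, sharing a window grid.
#' @param window_ms Optional `c(start, end)` restriction of the compared
#'   grid (e.g. `c(400, 550)` for an a-priori valence window).
#' @param tail `"greater"` or `"less"` (direction for group 1 vs group 2).
#' @param n_perm Number of group-label permutations (>= 100; default 1000).
#' @param alpha Cluster-forming significance level (default 0.05).
#' @param seed Optional integer seed.
#' @return An object of class `az_comparison`: list with `t` (tibble
#'   `window_ms`, `t`), `crit` (cluster-forming threshold), `clusters`
#'   (tibble `start_ms`, `end_ms`, `mass`, `p`), `tail`, `n_perm`.
#' @export
compare_az_curves <- function(az1, az2, window_ms = NULL,
                              tail = c("greater", "less"), n_perm = 1000,
                              alpha = 0.05, seed = NULL) {
  tail <- match.arg(tail)
  assert_that(n_perm >= 100, "n_perm < 100 is refused for cluster p values")
  assert_that(nrow(az1) >= 2 && nrow(az2) >= 2,
              "need at least 2 participants per group")
  assert_that(ncol(az1) == ncol(az2), "groups must share the window grid")
  grid <- attr(az1, "window_ms") %||% as.numeric(colnames(az1))
  if (tail == "less") { tmp <- az1; az1 <- az2; az2 <- tmp }

  keep <- if (is.null(window_ms)) seq_along(grid) else {
    which(grid >= window_ms[1] & grid <= window_ms[2])
  }
  assert_that(length(keep) > 0, "window_ms excludes every grid point")
  grid <- grid[keep]
  m <- rbind(az1[, keep, drop = FALSE], az2[, keep, drop = FALSE])
  ok <- colSums(is.na(m)) == 0
  assert_that(any(ok), "all compared windows contain missing Az values")
  m <- m[, ok, drop = FALSE]; grid <- grid[ok]
  is_a <- rep(c(TRUE, FALSE), c(nrow(az1), nrow(az2)))
  df <- nrow(m) - 2
  crit <- qt(1 - alpha, df)

  t_obs <- t_per_timepoint(m, is_a)
  obs <- cluster_masses(t_obs, crit)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- sample(is_a)
      cm <- cluster_masses(t_per_timepoint(m, perm), crit)$mass
      if (length(cm)) max(cm) else 0
    }, numeric(1))
  })

  step <- if (length(grid) > 1) min(diff(grid)) else 0
  clusters <- if (length(obs$mass)) {
    tibble(start_ms = grid[obs$starts] - step / 2,
           end_ms = grid[obs$ends] + step / 2,
           mass = obs$mass,
           p = vapply(obs$mass, function(ms)
             (1 + sum(null_max >= ms)) / (n_perm + 1), numeric(1)))
  } else {
    tibble(start_ms = numeric(), end_ms = numeric(), mass = numeric(),
           p = numeric())
  }

  structure(list(t = tibble(window_ms = grid, t = t_obs), crit = crit,
                 clusters = clusters, tail = tail, n_perm = n_perm,
                 alpha = alpha), class = "az_comparison")
}

#' @export
print.az_comparison <- function(x, ...) {
  cat(sprintf(
    "<az_comparison> %d timepoints, tail = %s, crit t = %.3f (%d perms)\n",
    nrow(x$t), x$tail, x$crit, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no clusters\n")
  invisible(x)
}
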