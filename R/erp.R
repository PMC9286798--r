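#' Canonical ERP components of cue-locked MID epochs
#'
#' The five anticipation-phase components with their electrode groups and
#' measurement windows: P2 (160-210 ms) and N2 (210-310 ms) over a frontal
#' group (FC1, FC2, FCz, Fz); cue-P3a (250-400 ms) and cue-P3b (400-550 ms)
#' over a parietal group (P1, P2, POz, Pz); and the CNV, measured over the
#' 200 ms preceding the earliest target onset (1800-2000 ms post cue) over
#' a central group (C1, C2, Cz, FCz).
#'
#' @return A tibble with columns `component`, `electrodes` (list-column),
#'   `start_ms`, `end_ms`.
#' @export
erp_components <- function() {
  tibble(
    component = c("P2", "N2", "cueP3a", "cueP3b", "CNV"),
    electrodes = list(c("FC1", "FC2", "FCz", "Fz"),
                      c("FC1", "FC2", "FCz", "Fz"),
                      c("P1", "P2", "POz", "Pz"),
                      c("P1", "P2", "POz", "Pz"),
                      c("C1", "C2", "Cz", "FCz")),
    start_ms = c(160, 210, 250, 400, 1800),
    end_ms = c(210, 310, 400, 550, 2000))
}

#' Mean ERP window amplitude per condition
#'
#' For each requested component, averages the epochs over its electrode
#' group and measurement window, then over the trials of each condition.
#'
#' @param x An [epoch_set()].
#' @param trials Matching trial table.
#' @param components Component table as returned by [erp_components()]
#'   (subset or modify to taste).
#' @return Tibble: `component`, `condition`, `n_trials`, `amplitude_uv`.
#' @export
erp_window_means <- function(x, trials, components = erp_components()) {
  stopifnot(inherits(x, "epoch_set"), nrow(trials) == n_trials(x))
  purrr::pmap_dfr(components, function(component, electrodes, start_ms,
                                       end_ms) {
    missing <- setdiff(electrodes, x$channels)
    if (length(missing)) {
      stop("electrode(s) not in the montage: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    ch <- match(electrodes, x$channels)
    sm <- which(x$times_ms >= start_ms & x$times_ms <= end_ms)
    assert_that(length(sm) > 0, "component window outside the epoch span")
    per_trial <- apply(x$data[, ch, sm, drop = FALSE], 1, mean)
    dplyr::summarise(
      dplyr::group_by(tibble(condition = trials$condition, amp = per_trial),
                      .data$condition),
      n_trials = dplyr::n(), amplitude_uv = mean(.data$amp),
      .groups = "drop") |>
      dplyr::mutate(component = component, .before = 1)
  })
}

#' Condition difference wave
#'
#' Trial-average of condition `cond_a` minus trial-average of `cond_b`,
#' per channel and sample (e.g. the gain-minus-loss wave that isolates
#' valence-sensitive activity by cancelling operations common to both cues).
#' `cond_a`/`cond_b` may be single conditions or vectors (e.g.
#' `c("gain", "loss")` vs `"neutral"` for an incentive-minus-neutral wave).
#'
#' @param x An [epoch_set()].
#' @param trials Matching trial table.
#' @param cond_a,cond_b Condition labels.
#' @return Tibble: `channel`, `time_ms`, `amplitude_uv`.
#' @export
difference_wave <- function(x, trials, cond_a = "gain", cond_b = "loss") {
  stopifnot(inherits(x, "epoch_set"), nrow(trials) == n_trials(x))
  sel_a <- trials$condition %in% cond_a
  sel_b <- trials$condition %in% cond_b
  assert_that(any(sel_a) && any(sel_b), "both conditions must have trials")
  m <- apply(x$data[sel_a, , , drop = FALSE], c(2, 3), mean) -
       apply(x$data[sel_b, , , drop = FALSE], c(2, 3), mean)
  tibble(channel = rep(x$channels, times = length(x$times_ms)),
         time_ms = rep(x$times_ms, each = length(x$channels)),
         amplitude_uv = as.vector(m))
}

#' Repeated-measures / mixed ANOVA on ERP window amplitudes
#'
#' Thin convenience wrappers over stock routines for the standard
#' group-level ERP statistics: a one-way repeated-measures ANOVA on mean
#' amplitude with condition as the within-subject factor (optionally
#' crossed with a between-subject group factor), via `aov()` with an
#' `Error(participant)` stratum, plus Tukey-adjusted pairwise condition
#' contrasts via \pkg{emmeans}.
#'
#' @param data Long tibble with columns `participant`, `condition`,
#'   `amplitude_uv` and optionally `group`.
#' @param between Include the `group` between-subject factor (default:
#'   automatically if a `group` column is present).
#' @return List with `anova` (the summary of the `aov` fit) and `tukey`
#'   (tibble of pairwise condition contrasts).
#' @export
erp_anova <- function(data, between = "group" %in% names(data)) {
  data <- dplyr::mutate(data,
                        participant = factor(.data$participant),
                        condition = factor(.data$condition))
  df <- as.data.frame(data)
  # build the call with the data embedded so downstream re-evaluation
  # (emmeans refits aov error strata) does not depend on this frame
  fml <- if (between) {
    data$group <- factor(data$group)
    df$group <- factor(df$group)
    amplitude_uv ~ condition * group + Error(participant)
  } else {
    amplitude_uv ~ condition + Error(participant)
  }
  fit <- do.call(stats::aov, list(fml, data = df))
  emm <- emmeans::emmeans(fit, "condition", data = df)
  tk <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))
  list(anova = summary(fit), tukey = as_tibble(tk))
}
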