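#' Run the single-trial contrast analysis for one participant
#'
#' Convenience wrapper tying the pieces together for one participant:
#' selects the trials of the requested contrast (for `"salience"`,
#' RT-matched incentive vs neutral sets via [match_rt_distributions()]),
#' runs the sliding discriminant, extracts the component STV over the
#' analysis window and fits the RT regression.
#'
#' @param epochs An [epoch_set()] (cue-locked, one epoch per trial row).
#' @param trials Matching trial table.
#' @param contrast `"valence"` (gain vs loss) or `"salience"` (RT-matched
#'   incentive vs neutral).
#' @param spec A [sliding_window_spec()].
#' @param grid Shrinkage grid.
#' @param stv_window Window for STV extraction (default the a-priori
#'   valence window `c(400, 550)` ms).
#' @return List with `decode` (a `sliding_decode`), `trials_used` (the
#'   analysed trial rows, in decode order), `match` (a `match_result` or
#'   `NULL`), `stv` (tibble), `rt_fit` (coefficient tibble, or `NULL` if
#'   the regression was not estimable).
#' @export
analyze_participant <- function(epochs, trials,
                                contrast = c("valence", "salience"),
                                spec = sliding_window_spec(),
                                grid = seq(0, 1, by = 0.01),
                                stv_window = c(400, 550)) {
  contrast <- match.arg(contrast)
  if (contrast == "valence") {
    idx <- which(trials$condition %in% c("gain", "loss"))
    labels <- factor(trials$condition[idx], levels = c("loss", "gain"))
    mres <- NULL
  } else {
    mres <- match_rt_distributions(trials)
    idx <- match(c(mres$incentive_idx, mres$neutral_idx),
                 trials$trial_index)
    labels <- factor(rep(c("incentive", "neutral"), each = length(idx) / 2),
                     levels = c("neutral", "incentive"))
  }
  decode <- sliding_analysis(epochs, labels, spec, grid, subset = idx)
  stv <- extract_stv(decode, stv_window)
  trials_used <- trials[idx, ]
  rt_fit <- tryCatch(fit_rt_regression(trials_used, stv),
                     error = function(e) NULL)
  list(decode = decode, trials_used = trials_used, match = mres,
       stv = stv, rt_fit = rt_fit)
}

#' Analyse a whole (simulated or loaded) cohort
#'
#' Applies [analyze_participant()] to every participant and collects
#' group-level summaries. When given a [cohort_spec()], participants are
#' simulated one at a time and their epochs discarded after analysis, so
#' memory stays flat in cohort size.
#'
#' @param x A cohort tibble (from [generate_cohort()] / [read_cohort()])
#'   or a [cohort_spec()].
#' @param contrast,spec,grid,stv_window Passed to [analyze_participant()].
#' @return Tibble with one row per participant: `participant_id`, `group`,
#'   `az` (list-column of Az tibbles), `peak_az`, `peak_ms`, `beta_stv`
#'   (the participant's STV coefficient from the RT regression, `NA` if not
#'   estimable).
#' @export
analyze_cohort <- function(x, contrast = "valence",
                           spec = sliding_window_spec(),
                           grid = seq(0, 1, by = 0.01),
                           stv_window = c(400, 550)) {
  one <- function(participant_id, group, epochs, trials) {
    res <- analyze_participant(epochs, trials, contrast, spec, grid,
                               stv_window)
    az_tbl <- res$decode$az
    pk <- which.max(az_tbl$az)
    peak_az <- if (length(pk)) az_tbl$az[pk] else NA_real_
    peak_ms <- if (length(pk)) az_tbl$window_ms[pk] else NA_real_
    beta <- if (is.null(res$rt_fit)) NA_real_ else {
      res$rt_fit$estimate[res$rt_fit$term == "stv"]
    }
    tibble(participant_id = participant_id, group = group,
           az = list(az_tbl), peak_az = peak_az, peak_ms = peak_ms,
           beta_stv = beta)
  }

  if (inherits(x, "cohort_spec")) {
    plan <- tidyr::expand_grid(group = x$groups, idx = seq_len(x$n_per_group))
    rows <- purrr::pmap(
      list(seq_len(nrow(plan)), plan$group), function(k, g) {
        sim <- simulate_participant(x, g, child_seed(x$seed, k))
        one(sprintf("P%02d", k), g, sim$epochs, sim$trials)
      })
  } else {
    rows <- purrr::pmap(
      list(x$participant_id, x$group, x$epochs, x$trials), one)
  }
  dplyr::bind_rows(rows)
}
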