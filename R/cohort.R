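#' Group presets for simulated cohorts
#'
#' Two presets mirror the effect structure the pipeline is designed to
#' detect. `"LA"` (low-risk-like) participants carry a clear parietal
#' valence component whose single-trial variability speeds reaction times
#' (negative RT link). `"HA"` (hazardous-drinking-like) participants have a
#' disrupted valence component (amplitude 0, no RT link) but an elevated
#' late fronto-central salience component. The presets differ only in these
#' parameters.
#'
#' @param group `"LA"` or `"HA"`.
#' @param ... Further overrides passed to [eeg_gen_config()] (e.g.
#'   `channels`, `noise`).
#' @return An [eeg_gen_config()].
#' @export
group_preset <- function(group = c("LA", "HA"), ...) {
  group <- match.arg(group)
  dots <- list(...)
  if (group == "LA") {
    over <- list()                       # the generator defaults ARE the
                                         # intact-valence working point
  } else {
    over <- list(valence = list(amplitude_uv = 0),
                 salience = list(amplitude_uv = 9),
                 rt_link = list(beta1_ms_per_unit = 0))
  }
  for (nm in intersect(names(dots), c("valence", "salience", "rt_link", "noise"))) {
    over[[nm]] <- utils::modifyList(over[[nm]] %||% list(), dots[[nm]])
    dots[[nm]] <- NULL
  }
  do.call(eeg_gen_config, c(over, dots))
}

#' Cohort specification
#'
#' Defines a simulated study cohort: `n_per_group` participants per group
#' preset, a base task configuration and agent, and per-participant
#' heterogeneity (agent RT means jittered across participants). Each
#' participant receives a deterministic child seed derived from `seed`.
#'
#' @param n_per_group Participants per group (default 22, i.e. 44 in total
#'   for the default two groups).
#' @param groups Character vector of group presets (subset of
#'   `c("LA", "HA")`).
#' @param task A [task_config()].
#' @param agent Base [agent_model()]; per-participant RT means are jittered
#'   by a zero-mean Gaussian with `rt_mean_jitter_sd` ms.
#' @param rt_mean_jitter_sd Across-participant SD of RT means (default 15).
#' @param config_args List of overrides applied to every participant's
#'   [eeg_gen_config()] (e.g. `list(channels = ...)`).
#' @param seed Integer master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 22, groups = c("LA", "HA"),
                        task = task_config(), agent = agent_model(),
                        rt_mean_jitter_sd = 15, config_args = list(),
                        seed = 1) {
  assert_that(n_per_group >= 1, "n_per_group must be >= 1")
  groups <- match.arg(groups, several.ok = TRUE)
  structure(list(n_per_group = n_per_group, groups = groups, task = task,
                 agent = agent, rt_mean_jitter_sd = rt_mean_jitter_sd,
                 config_args = config_args, seed = seed),
            class = "cohort_spec")
}

simulate_participant <- function(spec, group, seed) {
  agent <- spec$agent
  agent$rt_mean_ms <- with_seed(seed, {
    stats::setNames(pmax(50, agent$rt_mean_ms +
                           rnorm(3) * spec$rt_mean_jitter_sd),
                    names(agent$rt_mean_ms))
  })
  cfg <- do.call(group_preset, c(list(group = group), spec$config_args))
  tt <- simulate_task(spec$task, agent, seed = child_seed(seed, 1))
  simulate_eeg(tt, cfg, seed = child_seed(seed, 2))
}

#' Generate a simulated cohort
#'
#' Simulates every participant of a [cohort_spec()] (task + EEG). With
#' `out_dir = NULL` the cohort is returned in memory as a tibble with
#' list-columns; otherwise each participant's epochs (RDS) and trial table
#' (TSV) are written to `out_dir` along with a deterministic
#' `manifest.json` recording group labels and per-participant seeds.
#' Generation is fully deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional output directory.
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @return A tibble with one row per participant: `participant_id`, `group`,
#'   `seed`, and either list-columns `trials`/`epochs`/`truth` (in-memory)
#'   or file paths `trials_file`/`epochs_file`.
#' @export
generate_cohort <- function(spec, out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  plan <- tidyr::expand_grid(group = spec$groups,
                             idx = seq_len(spec$n_per_group))
  plan <- dplyr::mutate(
    plan,
    participant_id = sprintf("P%02d", dplyr::row_number()),
    seed = vapply(dplyr::row_number(), function(k)
      child_seed(spec$seed, k), numeric(1)))

  if (is.null(out_dir)) {
    sims <- purrr::map2(plan$group, plan$seed,
                        function(g, s) simulate_participant(spec, g, s))
    return(tibble(participant_id = plan$participant_id, group = plan$group,
                  seed = plan$seed,
                  trials = purrr::map(sims, "trials"),
                  epochs = purrr::map(sims, "epochs"),
                  truth = purrr::map(sims, "truth")))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists in '", out_dir,
         "'; use overwrite = TRUE to replace the cohort", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::pmap(plan, function(group, idx, participant_id, seed) {
    sim <- simulate_participant(spec, group, seed)
    tf <- file.path(out_dir, paste0(participant_id, "_trials.tsv"))
    ef <- file.path(out_dir, paste0(participant_id, "_epochs.rds"))
    write_trial_table(sim$trials, tf)
    write_epoch_set(sim$epochs, ef)
    tibble(participant_id = participant_id, group = group, seed = seed,
           trials_file = basename(tf), epochs_file = basename(ef))
  })
  out <- dplyr::bind_rows(rows)
  manifest <- list(
    n_per_group = spec$n_per_group, groups = spec$groups,
    master_seed = spec$seed,
    participants = lapply(seq_len(nrow(out)), function(i) as.list(out[i, ])))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), manifest_path)
  out
}

#' Load a cohort written by [generate_cohort()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return Tibble with `participant_id`, `group`, `seed` and list-columns
#'   `trials`, `epochs`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyDataFrame = TRUE)
  p <- as_tibble(manifest$participants)
  dplyr::mutate(
    p,
    trials = purrr::map(.data$trials_file,
                        ~ read_trial_table(file.path(dir, .x))),
    epochs = purrr::map(.data$epochs_file,
                        ~ read_epoch_set(file.path(dir, .x))))
}
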