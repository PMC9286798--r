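#' Task configuration for the simulated eMID experiment
#'
#' Describes the monetary incentive delay (MID) trial structure and the
#' adaptive staircase. On every trial a cue (gain / loss / neutral) is shown,
#' followed after a jittered anticipation delay by a speeded target whose
#' presentation duration ("response interval") is adapted per condition so
#' that the running hit rate tracks `target_hit_rate` (the design value is
#' 66%): the interval is shortened when the running success rate of that
#' condition exceeds the target and lengthened when it falls below it,
#' always clipped to `target_duration_bounds_ms`.
#'
#' The staircase step size and the initial response interval are not dictated
#' by the task design and are exposed as free parameters; the defaults
#' (20 ms step, 350 ms start) give a staircase that settles within the first
#' few trials for agents with typical simple-RT distributions.
#'
#' @param n_trials_per_condition Trials per cue condition (default 48, i.e.
#'   144 trials in total).
#' @param target_hit_rate Design hit rate the staircase tracks (default 0.66).
#' @param target_duration_bounds_ms Allowed response-interval range
#'   (default `c(100, 1250)`).
#' @param initial_target_duration_ms Starting response interval (default 350).
#' @param staircase_step_ms Duration change applied per staircase update
#'   (default 20).
#' @param n_practice_trials Practice trials run before the main block
#'   (default 30, balanced across conditions). The staircase adapts during
#'   practice exactly as in the main block and its state carries over, so
#'   the main block starts near each agent's threshold; practice trials are
#'   not part of the returned trial table.
#' @param cue_duration_ms,anticipation_delay_ms,post_target_blank_ms,feedback_ms,iti_ms
#'   Timing of the remaining trial phases; the anticipation delay is jittered
#'   uniformly over the given 2-element range.
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_trials_per_condition = 48,
                        target_hit_rate = 0.66,
                        target_duration_bounds_ms = c(100, 1250),
                        initial_target_duration_ms = 350,
                        staircase_step_ms = 20,
                        n_practice_trials = 30,
                        cue_duration_ms = 250,
                        anticipation_delay_ms = c(2000, 2500),
                        post_target_blank_ms = 1200,
                        feedback_ms = 1000,
                        iti_ms = 2000) {
  assert_that(n_trials_per_condition >= 1, "need at least one trial per condition")
  assert_that(target_hit_rate > 0 && target_hit_rate < 1,
              "target_hit_rate must be in (0, 1)")
  assert_that(length(target_duration_bounds_ms) == 2 &&
              all(target_duration_bounds_ms > 0) &&
              diff(target_duration_bounds_ms) > 0,
              "target_duration_bounds_ms must be an ordered positive interval")
  assert_that(initial_target_duration_ms > 0 && staircase_step_ms > 0,
              "durations must be positive")
  assert_that(initial_target_duration_ms >= target_duration_bounds_ms[1] &&
              initial_target_duration_ms <= target_duration_bounds_ms[2],
              "initial target duration must lie inside the bounds")
  assert_that(n_practice_trials >= 0, "n_practice_trials must be >= 0")
  structure(as.list(environment()), class = "task_config")
}

#' Response model of a simulated participant
#'
#' Gaussian simple-RT agent: on each trial the agent responds with an RT
#' drawn from a condition-specific normal distribution (truncated at 1 ms),
#' or fails to respond at all with probability `lapse_rate`. The defaults
#' encode incentive speeding (faster RTs on gain/loss than neutral trials),
#' the behavioural signature the task is built to elicit.
#'
#' @param rt_mean_ms Named numeric: mean RT per condition
#'   (`gain`, `loss`, `neutral`).
#' @param rt_sd_ms Named numeric: RT standard deviation per condition.
#' @param lapse_rate Probability of a non-response (default 0.02).
#' @return A list of class `agent_model`.
#' @export
agent_model <- function(rt_mean_ms = c(gain = 280, loss = 280, neutral = 360),
                        rt_sd_ms = c(gain = 60, loss = 60, neutral = 60),
                        lapse_rate = 0.02) {
  conds <- c("gain", "loss", "neutral")
  rt_mean_ms <- rt_mean_ms[conds]; rt_sd_ms <- rt_sd_ms[conds]
  assert_that(!anyNA(rt_mean_ms) && !anyNA(rt_sd_ms),
              "rt_mean_ms and rt_sd_ms must be named for gain, loss, neutral")
  assert_that(all(rt_sd_ms > 0), "rt_sd_ms must be positive")
  assert_that(lapse_rate >= 0 && lapse_rate <= 1, "lapse_rate must be in [0, 1]")
  structure(list(rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
                 lapse_rate = lapse_rate), class = "agent_model")
}

#' Simulate one participant performing the staircase-controlled MID task
#'
#' Generates a randomized trial sequence with equal counts per condition and
#' plays it against the agent. Each condition has its own staircase: after
#' every trial of a condition the running success rate of that condition is
#' compared with the target rate, and the response interval for the next
#' trial of that condition is shortened (rate above target), lengthened
#' (below target) or left unchanged (exactly on target), clipped to the
#' configured bounds. A trial is a hit (`outcome = +1`) iff the agent
#' responded and its RT did not exceed the response interval in force on that
#' trial; misses and lapses are coded `-1` with `rt_ms = NA` for lapses.
#'
#' @param config A [task_config()].
#' @param agent An [agent_model()].
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A tibble (the trial table) with columns `trial_index`, `condition`,
#'   `rt_ms`, `outcome`, `target_duration_ms`.
#' @export
#' @examples
#' tt <- simulate_task(task_config(), agent_model(), seed = 1)
#' mean(tt$outcome == 1)   # close to 0.66
simulate_task <- function(config = task_config(), agent = agent_model(),
                          seed = NULL) {
  stopifnot(inherits(config, "task_config"), inherits(agent, "agent_model"))
  with_seed(seed, {
    conds <- c("gain", "loss", "neutral")
    n_prac <- config$n_practice_trials
    practice <- sample(rep(conds, length.out = n_prac))
    sequence <- sample(rep(conds, each = config$n_trials_per_condition))
    full <- c(practice, sequence)
    n <- length(full)
    dur <- stats::setNames(rep(config$initial_target_duration_ms, 3), conds)
    hits <- stats::setNames(numeric(3), conds)
    cnt <- stats::setNames(numeric(3), conds)
    rt <- numeric(n); out <- numeric(n); tdur <- numeric(n)
    lo <- config$target_duration_bounds_ms[1]
    hi <- config$target_duration_bounds_ms[2]
    for (i in seq_len(n)) {
      cond <- full[i]
      tdur[i] <- dur[cond]
      if (runif(1) < agent$lapse_rate) {
        rt[i] <- NA_real_
      } else {
        rt[i] <- max(1, rnorm(1, agent$rt_mean_ms[cond], agent$rt_sd_ms[cond]))
      }
      hit <- !is.na(rt[i]) && rt[i] <= tdur[i]
      out[i] <- if (hit) 1 else -1
      cnt[cond] <- cnt[cond] + 1
      hits[cond] <- hits[cond] + hit
      rate <- hits[cond] / cnt[cond]
      if (rate > config$target_hit_rate) {
        dur[cond] <- max(lo, dur[cond] - config$staircase_step_ms)
      } else if (rate < config$target_hit_rate) {
        dur[cond] <- min(hi, dur[cond] + config$staircase_step_ms)
      }
    }
    main <- seq.int(n_prac + 1L, n)
    tibble(trial_index = seq_along(main), condition = full[main],
           rt_ms = rt[main], outcome = out[main],
           target_duration_ms = tdur[main])
  })
}

#' Read/write a trial table
#'
#' Plain tab-separated persistence of the per-trial behavioural table.
#'
#' @param trials Trial table tibble (see [simulate_task()]).
#' @param path File path.
#' @return `read_trial_table()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_trial_table <- function(trials, path) {
  write.table(trials, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
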