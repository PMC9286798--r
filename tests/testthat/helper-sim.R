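# Shared fixtures for the suite, built in code. Cohort-level checks run on
# a reduced montage (16 or 32 channels) and 128 Hz so the default test run
# stays fast; the generative model is unchanged.

ch16 <- function() {
  c("Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz", "AFz",
    "F3", "F4", "C3", "C4", "P3", "P4", "PO3", "PO4")
}

ch32 <- function() mid_montage()$label[seq(1, 64, by = 2)]

quick_task <- function(seed, n_per_cond = 48) {
  simulate_task(task_config(n_trials_per_condition = n_per_cond),
                agent_model(), seed = seed)
}

# one participant on the reduced montage; preset "LA" or "HA"
quick_participant <- function(seed, preset = "LA", channels = ch32(),
                              srate = 128) {
  tt <- quick_task(seed)
  cfg <- group_preset(preset, channels = channels, srate_hz = srate)
  sim <- simulate_eeg(tt, cfg, seed = seed + 5000)
  sim
}

# tiny epoch set with known content: value[t, c, s] filled from a function
tiny_epochs <- function(n_trials = 4, channels = c("Pz", "POz", "Cz"),
                        srate = 200, span = c(-100, 400),
                        fill = function(tr, ch, t_ms) 0) {
  times <- seq(span[1], span[2], by = 1000 / srate)
  data <- array(0, dim = c(n_trials, length(channels), length(times)))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_along(channels)) {
      data[tr, ch, ] <- fill(tr, ch, times)
    }
  }
  epoch_set(data, channels, times, srate, lock_event = "cue",
            reference_state = "raw")
}
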