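#' EEG generator configuration
#'
#' Describes how cue-locked epochs are synthesised for a simulated
#' participant. Two components are planted on top of structured noise:
#'
#' * a *valence* component — a smooth amplitude bump with a parietal
#'   topography whose trial amplitude is `+amplitude_uv` on gain trials,
#'   `-amplitude_uv` on loss trials and 0 on neutral trials, plus a
#'   zero-mean trial-level fluctuation with standard deviation `stv_sd`
#'   (the planted single-trial variability, STV);
#' * a *salience* component — a late ramp with a fronto-central topography,
#'   present with amplitude `amplitude_uv` on incentive (gain and loss)
#'   trials and absent on neutral trials.
#'
#' Noise is spatially correlated Gaussian (squared-exponential covariance
#' over the montage) whose temporal spectrum mixes white and 1/f ("pink")
#' power; this gives the channel covariance enough structure that covariance
#' shrinkage is genuinely useful downstream.
#'
#' When `rt_link$enabled`, reaction times are re-generated from the planted
#' valence STV as `rt = beta0[condition] + beta1 * stv + eps`,
#' `eps ~ N(0, residual_sd_ms)`, with a negative default `beta1`: larger
#' single-trial valence differentiation speeds the upcoming response.
#' Outcomes are then re-derived against the staircase target durations.
#'
#' @param channels Character vector of montage labels (default: the full
#'   64-channel 10-10 set).
#' @param srate_hz Sampling rate of the synthetic epochs (default 256).
#' @param epoch_span_ms Cue-locked epoch span (default `c(-500, 2000)`).
#' @param valence List: `center`, `width` (topography peak site and spatial
#'   width), `kernel_center_ms`, `kernel_halfwidth_ms` (raised-cosine bump,
#'   zero outside its support), `amplitude_uv`, `stv_sd`.
#' @param salience List: `center`, `width`, `ramp_ms` (linear 0-to-1 ramp
#'   over this interval, zero before), `amplitude_uv`.
#' @param noise List: `sd_uv` (per-channel noise SD), `spatial_length_scale`
#'   and `nugget` (squared-exponential spatial correlation with an
#'   uncorrelated sensor-noise fraction), `pink_weight` (fraction of
#'   temporal noise power that is 1/f).
#' @param rt_link List: `enabled`, `beta0_ms` (named per-condition
#'   intercepts), `beta1_ms_per_unit`, `residual_sd_ms`.
#' @return A list of class `eeg_gen_config` with precomputed topographies
#'   (`topo_valence`, `topo_salience`) and the noise Cholesky factor.
#' @export
eeg_gen_config <- function(channels = mid_montage()$label,
                           srate_hz = 256,
                           epoch_span_ms = c(-500, 2000),
                           valence = list(),
                           salience = list(),
                           noise = list(),
                           rt_link = list()) {
  valence <- utils::modifyList(list(
    center = "Pz", width = 0.45, kernel_center_ms = 475,
    kernel_halfwidth_ms = 125, amplitude_uv = 10, stv_sd = 3), valence)
  salience <- utils::modifyList(list(
    center = "FCz", width = 0.5, ramp_ms = c(1300, 2000),
    amplitude_uv = 6), salience)
  noise <- utils::modifyList(list(
    sd_uv = 8, spatial_length_scale = 0.9, nugget = 0.25,
    pink_weight = 0.15), noise)
  rt_link <- utils::modifyList(list(
    enabled = TRUE,
    beta0_ms = c(gain = 280, loss = 280, neutral = 360),
    beta1_ms_per_unit = -12, residual_sd_ms = 40), rt_link)

  montage <- mid_montage()
  assert_that(all(channels %in% montage$label),
              "all channels must be 10-10 montage labels")
  sub <- montage[match(channels, montage$label), ]
  assert_that(valence$stv_sd >= 0, "stv_sd must be non-negative")
  assert_that(noise$sd_uv >= 0, "noise sd must be non-negative")
  assert_that(noise$pink_weight >= 0 && noise$pink_weight <= 1,
              "pink_weight must be in [0, 1]")

  topo_v <- scalp_topography(valence$center, valence$width, montage)
  topo_s <- scalp_topography(salience$center, salience$width, montage)
  # restrict to the requested channels, re-normalised to unit norm
  topo_v <- topo_v[channels]; topo_v <- topo_v / sqrt(sum(topo_v^2))
  topo_s <- topo_s[channels]; topo_s <- topo_s / sqrt(sum(topo_s^2))

  k <- spatial_noise_cov(sub, noise$spatial_length_scale, noise$nugget)
  structure(list(
    channels = channels, srate_hz = srate_hz, epoch_span_ms = epoch_span_ms,
    valence = valence, salience = salience, noise = noise, rt_link = rt_link,
    topo_valence = topo_v, topo_salience = topo_s,
    noise_chol = t(chol(k))), class = "eeg_gen_config")
}

# raised-cosine bump, exactly zero outside [center - hw, center + hw]
bump_kernel <- function(t_ms, center, halfwidth) {
  k <- numeric(length(t_ms))
  inside <- abs(t_ms - center) <= halfwidth
  k[inside] <- 0.5 * (1 + cos(pi * (t_ms[inside] - center) / halfwidth))
  k
}

# linear ramp from 0 at ramp[1] to 1 at ramp[2], zero before, clamped after
ramp_kernel <- function(t_ms, ramp) {
  pmin(1, pmax(0, (t_ms - ramp[1]) / (ramp[2] - ramp[1])))
}

# temporal noise: mix of white and 1/f power, unit marginal variance
temporal_noise <- function(n_samples, n_series, pink_weight) {
  w <- matrix(rnorm(n_samples * n_series), n_samples, n_series)
  if (pink_weight <= 0) return(w)
  # shape a second white draw to a 1/f amplitude spectrum via FFT
  w2 <- matrix(rnorm(n_samples * n_series), n_samples, n_series)
  k <- seq_len(n_samples) - 1
  f <- pmin(k, n_samples - k)           # symmetric frequency index
  s <- ifelse(f > 0, 1 / sqrt(f), 0)
  s <- s / sqrt(mean(s^2))              # unit output variance
  pink <- Re(stats::mvfft(stats::mvfft(w2) * s, inverse = TRUE)) / n_samples
  sqrt(1 - pink_weight) * w + sqrt(pink_weight) * pink
}

#' Simulate cue-locked epochs for a trial table
#'
#' Generates one epoch per row of `trials` according to an
#' [eeg_gen_config()]: planted valence and salience components (see that
#' help page for the generative model) plus spatially and temporally
#' structured noise. Optionally re-generates RTs from the planted valence
#' STV through the configured linear link and re-derives outcomes against
#' the per-trial staircase target durations.
#'
#' @param trials Trial table (see [simulate_task()]).
#' @param config An [eeg_gen_config()].
#' @param seed Optional integer seed.
#' @param regenerate_rt Re-generate `rt_ms` from the planted STV
#'   (default: `config$rt_link$enabled`). Trials that were lapses keep
#'   `rt_ms = NA` and remain misses.
#' @return A list with elements
#'   `epochs` (an [epoch_set()]),
#'   `trials` (the, possibly updated, trial table), and
#'   `truth` (planted per-trial STV and component amplitudes and the two
#'   topographies — for validation studies).
#' @export
#' @examples
#' tt <- simulate_task(seed = 1)
#' sim <- simulate_eeg(tt, eeg_gen_config(channels = c("Pz", "POz", "Cz")),
#'                     seed = 2)
#' sim$epochs
simulate_eeg <- function(trials, config = eeg_gen_config(), seed = NULL,
                         regenerate_rt = config$rt_link$enabled) {
  stopifnot(inherits(config, "eeg_gen_config"))
  assert_that(nrow(trials) > 0, "trials must be non-empty")
  n <- nrow(trials)
  d <- length(config$channels)
  times <- seq(config$epoch_span_ms[1], config$epoch_span_ms[2],
               by = 1000 / config$srate_hz)
  s <- length(times)
  kv <- bump_kernel(times, config$valence$kernel_center_ms,
                    config$valence$kernel_halfwidth_ms)
  ks <- ramp_kernel(times, config$salience$ramp_ms)
  cond_sign <- c(gain = 1, loss = -1, neutral = 0)[trials$condition]
  incentive <- trials$condition %in% c("gain", "loss")

  with_seed(seed, {
    stv <- rnorm(n) * config$valence$stv_sd
    val_amp <- cond_sign * config$valence$amplitude_uv +
      ifelse(cond_sign != 0, stv, 0)
    sal_amp <- ifelse(incentive, config$salience$amplitude_uv, 0)

    data <- array(0, dim = c(n, d, s))
    sig_v <- outer(config$topo_valence, kv)       # d x s
    sig_s <- outer(config$topo_salience, ks)
    # all trials' temporal noise in one FFT batch, then spatial colouring
    noise_t <- temporal_noise(s, d * n, config$noise$pink_weight)  # s x (d n)
    for (i in seq_len(n)) {
      eps <- config$noise$sd_uv *
        (config$noise_chol %*% t(noise_t[, ((i - 1) * d + 1):(i * d)]))
      data[i, , ] <- val_amp[i] * sig_v + sal_amp[i] * sig_s + eps
    }

    if (regenerate_rt) {
      b <- config$rt_link
      rt_new <- b$beta0_ms[trials$condition] + b$beta1_ms_per_unit * stv +
        rnorm(n) * b$residual_sd_ms
      rt_new <- pmax(1, rt_new)
      rt_new[is.na(trials$rt_ms)] <- NA_real_     # lapses stay lapses
      trials$rt_ms <- as.numeric(rt_new)
      trials$outcome <- ifelse(!is.na(trials$rt_ms) &
                                 trials$rt_ms <= trials$target_duration_ms,
                               1, -1)
    }

    epochs <- epoch_set(data, config$channels, times, config$srate_hz,
                        lock_event = "cue", reference_state = "raw")
    list(epochs = epochs, trials = trials,
         truth = list(stv = stv, valence_amp = val_amp,
                      salience_amp = sal_amp,
                      topo_valence = config$topo_valence,
                      topo_salience = config$topo_salience))
  })
}
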