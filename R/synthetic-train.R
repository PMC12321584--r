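#' Configuration for synthetic depressing fEPSP trains
#'
#' Depletion-replenishment model of a 20-Hz, 100-pulse train: the pulse-`i`
#' amplitude is `p_release * pool_i` (times multiplicative noise), the pool
#' updates as `pool_{i+1} = pool_i * (1 - p_release) + replenish_rate`, and
#' `pool_1 = rrp_true`. Recovery stimuli after the train sample a
#' single-exponential pool refill toward `rrp_true` with time constant
#' `recovery_tau_ms`; defaults mirror recovery stimulation at 100 ms after
#' the train end with 200-ms increments out to 2,900 ms.
#'
#' @param n_pulses pulses in the train (default 100).
#' @param rate_hz stimulation rate (default 20 Hz).
#' @param p_release release fraction per pulse, in (0, 1\].
#' @param rrp_true planted readily-releasable pool size (normalized units).
#' @param replenish_rate pool replenishment per inter-pulse interval.
#' @param noise_sd multiplicative amplitude noise SD.
#' @param recovery_intervals_ms intervals between train end and recovery
#'   stimulus.
#' @param recovery_tau_ms pool refill time constant for recovery stimuli.
#' @return object of class `train_config`.
#' @export
train_config <- function(n_pulses = 100L,
                         rate_hz = 20,
                         p_release = 0.3,
                         rrp_true = 10,
                         replenish_rate = 0.3,
                         noise_sd = 0.02,
                         recovery_intervals_ms = seq(100, 2900, by = 200),
                         recovery_tau_ms = 800) {
  vz_check_number(n_pulses, "n_pulses", positive = TRUE)
  vz_check_number(rate_hz, "rate_hz", positive = TRUE)
  vz_check_number(p_release, "p_release")
  if (p_release <= 0 || p_release > 1) vz_stop("'p_release' must lie in (0, 1]")
  vz_check_number(rrp_true, "rrp_true", positive = TRUE)
  vz_check_number(replenish_rate, "replenish_rate", nonneg = TRUE)
  vz_check_number(noise_sd, "noise_sd", nonneg = TRUE)
  vz_check_number(recovery_tau_ms, "recovery_tau_ms", positive = TRUE)
  if (length(recovery_intervals_ms) && is.unsorted(recovery_intervals_ms, strictly = TRUE))
    vz_stop("'recovery_intervals_ms' must be strictly increasing")
  structure(list(n_pulses = as.integer(n_pulses), rate_hz = rate_hz,
                 p_release = p_release, rrp_true = rrp_true,
                 replenish_rate = replenish_rate, noise_sd = noise_sd,
                 recovery_intervals_ms = as.numeric(recovery_intervals_ms),
                 recovery_tau_ms = recovery_tau_ms),
            class = "train_config")
}

#' Generate a synthetic fEPSP train with planted ground truth
#'
#' @param config a [train_config()].
#' @param seed non-negative integer seed.
#' @return list with `record` (class `train_record`: `amplitudes`,
#'   `rate_hz`, `n_pulses`, `recovery` data frame) and `truth`.
#' @export
gen_train <- function(config, seed) {
  stopifnot(inherits(config, "train_config"))
  seed <- vz_check_seed(seed)
  p <- config$p_release
  pool <- config$rrp_true
  amp <- numeric(config$n_pulses)
  for (i in seq_len(config$n_pulses)) {
    amp[i] <- p * pool
    pool <- pool * (1 - p) + config$replenish_rate
  }
  set.seed(seed)
  if (config$noise_sd > 0)
    amp <- amp * (1 + stats::rnorm(length(amp), 0, config$noise_sd))
  pool_end <- pool
  rec_pool <- config$rrp_true -
    (config$rrp_true - pool_end) * exp(-config$recovery_intervals_ms / config$recovery_tau_ms)
  rec_amp <- p * rec_pool
  if (config$noise_sd > 0)
    rec_amp <- rec_amp * (1 + stats::rnorm(length(rec_amp), 0, config$noise_sd))
  record <- structure(list(amplitudes = amp, rate_hz = config$rate_hz,
                           n_pulses = config$n_pulses,
                           recovery = data.frame(interval_ms = config$recovery_intervals_ms,
                                                 amplitude = rec_amp)),
                      class = "train_record")
  truth <- structure(list(modality = "train", rrp_true = config$rrp_true,
                          p_release = p, replenish_rate = config$replenish_rate,
                          recovery_tau_ms = config$recovery_tau_ms,
                          first_amplitude = p * config$rrp_true,
                          pool_end = pool_end),
                     class = "synthetic_truth")
  list(record = record, truth = truth)
}
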