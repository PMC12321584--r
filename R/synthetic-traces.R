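#' Configuration for synthetic glutamate-sensor traces
#'
#' Emulates stimulus-locked dF/F transients recorded at 7.5 ms (~133 Hz)
#' exposure for 400 frames: a flat baseline plus, at each stimulus, an
#' instantaneous-rise, exponential-decay transient. The second-pulse true
#' amplitude is `amp1 * ppr_true`. Transient peaks are placed on the first
#' frame strictly after the stimulus time (the response window opens after
#' the stimulus frame) so a noiseless analysis recovers `amp1` exactly.
#'
#' @param frame_interval_ms sampling interval (default 7.5 ms).
#' @param n_frames number of frames (default 400).
#' @param stim_times_ms ordered stimulus times within the recording.
#' @param amp1 true first-pulse peak in dF/F units.
#' @param ppr_true true paired-pulse ratio (second amplitude = amp1 * ppr).
#' @param decay_tau_ms transient decay time constant.
#' @param noise_sd additive Gaussian noise SD in dF/F units.
#' @param f0 baseline fluorescence (arbitrary units).
#' @return object of class `trace_config`.
#' @export
trace_config <- function(frame_interval_ms = 7.5,
                         n_frames = 400L,
                         stim_times_ms = c(750, 800),
                         amp1 = 0.5,
                         ppr_true = 1.5,
                         decay_tau_ms = 30,
                         noise_sd = 0.02,
                         f0 = 100) {
  vz_check_number(frame_interval_ms, "frame_interval_ms", positive = TRUE)
  vz_check_number(n_frames, "n_frames", positive = TRUE)
  vz_check_number(amp1, "amp1", positive = TRUE)
  vz_check_number(ppr_true, "ppr_true", positive = TRUE)
  vz_check_number(decay_tau_ms, "decay_tau_ms", positive = TRUE)
  vz_check_number(noise_sd, "noise_sd", nonneg = TRUE)
  vz_check_number(f0, "f0", positive = TRUE)
  total <- n_frames * frame_interval_ms
  if (is.unsorted(stim_times_ms, strictly = TRUE))
    vz_stop("'stim_times_ms' must be strictly increasing")
  if (any(stim_times_ms <= 0) || any(stim_times_ms >= total))
    vz_stop("stimulus times must lie within the recording (0, %g) ms", total)
  structure(list(frame_interval_ms = frame_interval_ms,
                 n_frames = as.integer(n_frames),
                 stim_times_ms = as.numeric(stim_times_ms),
                 amp1 = amp1, ppr_true = ppr_true,
                 decay_tau_ms = decay_tau_ms, noise_sd = noise_sd, f0 = f0),
            class = "trace_config")
}

#' Generate a synthetic raw fluorescence trace with planted ground truth
#'
#' @param config a [trace_config()].
#' @param seed non-negative integer seed.
#' @return list with `trace` (class `raw_trace`: `time_ms`, `intensity`,
#'   `stim_times_ms`) and `truth` (`synthetic_truth` with planted amplitudes
#'   and PPR).
#' @export
gen_dff_trace <- function(config, seed) {
  stopifnot(inherits(config, "trace_config"))
  seed <- vz_check_seed(seed)
  t <- (seq_len(config$n_frames) - 1) * config$frame_interval_ms
  amps <- config$amp1 * c(1, rep(config$ppr_true, max(0, length(config$stim_times_ms) - 1)))
  dff <- numeric(length(t))
  for (k in seq_along(config$stim_times_ms)) {
    i_peak <- which(t > config$stim_times_ms[k])[1]
    idx <- i_peak:length(t)
    dff[idx] <- dff[idx] + amps[k] * exp(-(t[idx] - t[i_peak]) / config$decay_tau_ms)
  }
  set.seed(seed)
  f <- config$f0 * (1 + dff) + stats::rnorm(length(t), 0, config$noise_sd * config$f0)
  trace <- structure(list(time_ms = t, intensity = f,
                          stim_times_ms = config$stim_times_ms),
                     class = "raw_trace")
  truth <- structure(list(modality = "dff", amp1 = config$amp1,
                          ppr_true = config$ppr_true, amps = amps,
                          decay_tau_ms = config$decay_tau_ms, f0 = config$f0),
                     class = "synthetic_truth")
  list(trace = trace, truth = truth)
}

#' Configuration for synthetic FRAP recovery curves
#'
#' Internal-bleach FRAP: a prebleach plateau at 1, a bleach after
#' `prebleach_frames` frames, then fractional recovery following the
#' one-phase association `f(t) = mobile_fraction * (1 - exp(-t / tau_s))`
#' with additive Gaussian noise. Defaults mirror 0.6 s frames, 100 frames,
#' bleach after frame 3 and bleach-spot diameters of 800 or 1600 nm.
#'
#' @param tau_s true recovery time constant in seconds.
#' @param mobile_fraction true mobile fraction in \[0, 1\].
#' @param prebleach_frames frames acquired before the bleach (default 3).
#' @param frame_interval_s frame interval in seconds (default 0.6).
#' @param n_frames total frames (default 100).
#' @param noise_sd additive Gaussian noise SD (fractional-recovery units).
#' @param bleach_diameter_nm bleach-spot diameter (800 or 1600 nm typical).
#' @return object of class `frap_config`.
#' @export
frap_config <- function(tau_s = 2,
                        mobile_fraction = 0.8,
                        prebleach_frames = 3L,
                        frame_interval_s = 0.6,
                        n_frames = 100L,
                        noise_sd = 0.02,
                        bleach_diameter_nm = 800) {
  vz_check_number(tau_s, "tau_s", positive = TRUE)
  vz_check_number(mobile_fraction, "mobile_fraction")
  if (mobile_fraction < 0 || mobile_fraction > 1)
    vz_stop("'mobile_fraction' must lie in [0, 1]")
  vz_check_number(prebleach_frames, "prebleach_frames", positive = TRUE)
  vz_check_number(frame_interval_s, "frame_interval_s", positive = TRUE)
  vz_check_number(n_frames, "n_frames", positive = TRUE)
  if (n_frames <= prebleach_frames + 10)
    vz_stop("'n_frames' must exceed prebleach_frames + 10")
  vz_check_number(noise_sd, "noise_sd", nonneg = TRUE)
  vz_check_number(bleach_diameter_nm, "bleach_diameter_nm", positive = TRUE)
  structure(list(tau_s = tau_s, mobile_fraction = mobile_fraction,
                 prebleach_frames = as.integer(prebleach_frames),
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 bleach_diameter_nm = bleach_diameter_nm),
            class = "frap_config")
}

#' Generate a synthetic FRAP curve with planted ground truth
#'
#' @param config a [frap_config()].
#' @param seed non-negative integer seed.
#' @return list with `curve` (class `frap_curve`: data frame `time_s`,
#'   `value`, `phase` in prebleach/postbleach, plus attributes) and `truth`.
#' @export
gen_frap_curve <- function(config, seed) {
  stopifnot(inherits(config, "frap_config"))
  seed <- vz_check_seed(seed)
  n <- config$n_frames
  pb <- config$prebleach_frames
  t_all <- (seq_len(n) - 1) * config$frame_interval_s
  t_post <- t_all[(pb + 1):n] - t_all[pb + 1]  # time since bleach frame
  ideal <- c(rep(1, pb),
             config$mobile_fraction * (1 - exp(-t_post / config$tau_s)))
  set.seed(seed)
  val <- ideal + stats::rnorm(n, 0, config$noise_sd)
  val[seq_len(pb)] <- pmax(val[seq_len(pb)], 0)
  curve <- structure(
    data.frame(time_s = t_all, value = val,
               phase = rep(c("prebleach", "postbleach"), c(pb, n - pb))),
    class = c("frap_curve", "data.frame"),
    prebleach_frames = pb,
    frame_interval_s = config$frame_interval_s,
    bleach_diameter_nm = config$bleach_diameter_nm)
  truth <- structure(list(modality = "frap", tau_s = config$tau_s,
                          mobile_fraction = config$mobile_fraction),
                     class = "synthetic_truth")
  list(curve = curve, truth = truth)
}

#' Generate a synthetic axonal line profile with condensate bumps
#'
#' Emulates a 1-D intensity profile drawn along an axon: a positive baseline
#' plus Gaussian condensate bumps at random positions plus noise. The
#' `dispersed` variant redistributes each bump's integrated intensity
#' uniformly along the profile, conserving total intensity, as after
#' aliphatic-alcohol treatment.
#'
#' @param n_condensates number of bumps.
#' @param bump_amplitude bump peak amplitude above baseline.
#' @param baseline positive baseline intensity.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed non-negative integer seed.
#' @param n_px profile length in pixels (default 500).
#' @param bump_sigma_px bump Gaussian sigma in pixels (default 6).
#' @return list with `punctate` and `dispersed` numeric profiles and `truth`.
#' @export
gen_axon_profile <- function(n_condensates, bump_amplitude, baseline,
                             noise_sd, seed, n_px = 500L, bump_sigma_px = 6) {
  vz_check_number(baseline, "baseline", positive = TRUE)
  vz_check_number(bump_amplitude, "bump_amplitude", nonneg = TRUE)
  vz_check_number(noise_sd, "noise_sd", nonneg = TRUE)
  seed <- vz_check_seed(seed)
  set.seed(seed)
  x <- seq_len(n_px)
  bumps <- numeric(n_px)
  pos <- if (n_condensates > 0)
    stats::runif(n_condensates, 4 * bump_sigma_px, n_px - 4 * bump_sigma_px) else numeric(0)
  for (p in pos)
    bumps <- bumps + bump_amplitude * exp(-(x - p)^2 / (2 * bump_sigma_px^2))
  noise <- stats::rnorm(n_px, 0, noise_sd)
  punctate <- baseline + bumps + noise
  dispersed <- baseline + sum(bumps) / n_px + noise
  truth <- structure(list(modality = "axon", positions = pos,
                          bump_amplitude = bump_amplitude,
                          baseline = baseline,
                          bump_integral = sum(bumps)),
                     class = "synthetic_truth")
  list(punctate = punctate, dispersed = dispersed, truth = truth)
}
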