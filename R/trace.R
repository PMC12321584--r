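#' Rolling-ball background subtraction
#'
#' Grayscale rolling-ball background removal: the background is the
#' morphological opening (erosion then dilation) of the signal with a
#' non-flat half-ball structuring element of the given radius, and is
#' subtracted from the input. Works on 1-D traces (vectors) and 2-D images
#' (matrices). Output is clamped at 0.
#'
#' @param x numeric vector (trace) or matrix (image).
#' @param radius_px ball radius in samples/pixels (e.g. 7 for sensor movies,
#'   50 for condensate images).
#' @return same shape as `x`, background-subtracted, non-negative.
#' @export
background_subtract <- function(x, radius_px) {
  vz_check_number(radius_px, "radius_px", positive = TRUE)
  r <- as.integer(radius_px)
  if (r < 1) vz_stop("'radius_px' must be >= 1")
  if (is.matrix(x)) {
    if (2 * r + 1 > min(dim(x))) vz_stop("ball radius larger than image")
    off <- expand.grid(di = -r:r, dj = -r:r)
    off <- off[off$di^2 + off$dj^2 <= r^2, ]
    ball <- sqrt(r^2 - off$di^2 - off$dj^2)
    nr <- nrow(x); nc <- ncol(x)
    ero <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(off))) {
      sh <- vz_shift2(x, off$di[k], off$dj[k])
      ero <- pmin(ero, sh - ball[k])
    }
    bg <- matrix(-Inf, nr, nc)
    for (k in seq_len(nrow(off))) {
      sh <- vz_shift2(ero, -off$di[k], -off$dj[k])
      bg <- pmax(bg, sh + ball[k])
    }
  } else {
    if (2 * r + 1 > length(x)) vz_stop("ball radius larger than trace")
    off <- (-r):r
    ball <- sqrt(r^2 - off^2)
    n <- length(x)
    ero <- rep(Inf, n)
    for (k in seq_along(off)) ero <- pmin(ero, vz_shift1(x, off[k]) - ball[k])
    bg <- rep(-Inf, n)
    for (k in seq_along(off)) bg <- pmax(bg, vz_shift1(ero, -off[k]) + ball[k])
  }
  pmax(x - bg, 0)
}

# Shift with border replication dropped: out-of-range entries are +/- Inf so
# they never win the min/max; this keeps constants exactly constant.
vz_shift1 <- function(x, d) {
  n <- length(x)
  out <- rep(Inf, n)
  src <- seq_len(n) + d
  ok <- src >= 1 & src <= n
  out[ok] <- x[src[ok]]
  out
}

vz_shift2 <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(Inf, nr, nc)
  ri <- seq_len(nr) + di
  cj <- seq_len(nc) + dj
  rok <- ri >= 1 & ri <= nr
  cok <- cj >= 1 & cj <= nc
  out[rok, cok] <- m[ri[rok], cj[cok]]
  out
}

#' Compute dF/F from a raw fluorescence trace
#'
#' `dF/F0 = (F(t) - F0) / F0` with the baseline `F0` averaged over the
#' window (~300 ms by default, i.e. 40 frames at 7.5 ms sampling) ending at
#' the first stimulus; the window is truncated to the available frames and
#' rounded down to a whole frame count.
#'
#' @param trace a `raw_trace` (list with `time_ms`, `intensity`,
#'   `stim_times_ms`).
#' @param baseline_window_ms baseline window length (default 300 ms).
#' @return object of class `dff_trace`: data frame `time_ms`, `dff` with
#'   attributes `f0` and `stim_times_ms`.
#' @export
compute_dff <- function(trace, baseline_window_ms = 300) {
  vz_check_number(baseline_window_ms, "baseline_window_ms", positive = TRUE)
  t <- trace$time_ms; f <- trace$intensity
  if (length(t) != length(f) || is.unsorted(t, strictly = TRUE))
    vz_stop("invalid trace: time and intensity must align, time strictly increasing")
  t1 <- trace$stim_times_ms[1]
  pre <- which(t < t1)
  if (length(pre) == 0) vz_stop("no frames before the first stimulus")
  dt <- stats::median(diff(t))
  nwin <- max(1L, floor(baseline_window_ms / dt))
  base_idx <- utils::tail(pre, nwin)
  f0 <- mean(f[base_idx])
  if (f0 <= 0) vz_stop("baseline F0 <= 0: trace unusable")
  out <- data.frame(time_ms = t, dff = (f - f0) / f0)
  structure(out, class = c("dff_trace", "data.frame"), f0 = f0,
            stim_times_ms = trace$stim_times_ms,
            baseline_sd = stats::sd((f[base_idx] - f0) / f0))
}

#' Extract per-stimulus peak dF/F values
#'
#' For each stimulus the peak is the maximum dF/F in the window
#' `(stim, stim + response_window_ms]`, clipped at the next stimulus when
#' windows overlap. Peaks after the first are measured after subtracting the
#' extrapolated single-exponential decay of the preceding transient (fit to
#' the inter-pulse segment); set `decay_correct = FALSE` to disable. A peak
#' below the detection floor (3 x baseline SD of dF/F) is flagged as a
#' failure.
#'
#' @param dff a [compute_dff()] result.
#' @param response_window_ms window length after each stimulus (default 50).
#' @param decay_correct subtract the previous transient's extrapolated decay
#'   before measuring (default TRUE).
#' @param floor_sd failure floor in baseline SDs (default 3).
#' @return data frame of class `peak_set`: `stim`, `stim_time_ms`, `peak`,
#'   `failure`.
#' @export
extract_peaks <- function(dff, response_window_ms = 50, decay_correct = TRUE,
                          floor_sd = 3) {
  stopifnot(inherits(dff, "dff_trace"))
  stims <- attr(dff, "stim_times_ms")
  t <- dff$time_ms; y <- dff$dff
  floor_val <- floor_sd * max(attr(dff, "baseline_sd"), 0, na.rm = TRUE)
  res <- data.frame(stim = seq_along(stims), stim_time_ms = stims,
                    peak = NA_real_, failure = FALSE)
  prev_fit <- NULL
  for (k in seq_along(stims)) {
    hi <- stims[k] + response_window_ms
    if (k < length(stims)) hi <- min(hi, stims[k + 1])
    win <- which(t > stims[k] & t <= hi)
    if (length(win) == 0) { res$failure[k] <- TRUE; next }
    yw <- y[win]
    if (k > 1 && decay_correct && !is.null(prev_fit))
      yw <- yw - prev_fit$a * exp(-(t[win] - prev_fit$t0) / prev_fit$tau)
    pk <- max(yw)
    res$peak[k] <- pk
    res$failure[k] <- pk <= floor_val  # zero peak on a flat trace is a failure
    # fit the decay of this transient over the segment up to the next stim
    seg_hi <- if (k < length(stims)) stims[k + 1] else max(t)
    ipk <- win[which.max(y[win])]
    seg <- which(t > t[ipk] & t <= seg_hi & y > 0)
    prev_fit <- NULL
    if (length(seg) >= 3) {
      co <- stats::coef(stats::lm(log(y[seg]) ~ t[seg]))
      if (is.finite(co[2]) && co[2] < 0) {
        tau <- -1 / co[2]
        prev_fit <- list(t0 = t[ipk], tau = tau,
                         a = exp(co[1] + co[2] * t[ipk]))
      }
    }
  }
  class(res) <- c("peak_set", "data.frame")
  res
}

#' Paired-pulse ratio with range-based omission
#'
#' `PPR = P2 / P1`. A PPR outside \[0, 30\] is omitted; for 1,000-ms interval
#' experiments the admissible range tightens to \[0, 5\] (the expected
#' return to baseline). A zero or failed first peak is omitted with reason.
#'
#' @param peaks a [extract_peaks()] result (uses the first two peaks).
#' @param interval_ms inter-pulse interval in ms.
#' @return data frame of class `ppr_result`: `interval_ms`, `ppr` (NA when
#'   omitted), `omission_reason` (`"none"`, `"out_of_range"`, `"p1_zero"`,
#'   `"p1_failure"`).
#' @export
compute_ppr <- function(peaks, interval_ms) {
  vz_check_number(interval_ms, "interval_ms", positive = TRUE)
  if (nrow(peaks) < 2) vz_stop("need at least two stimuli for a PPR")
  p1 <- peaks$peak[1]; p2 <- peaks$peak[2]
  reason <- "none"; ppr <- NA_real_
  if (isTRUE(peaks$failure[1])) {
    reason <- "p1_failure"
  } else if (!is.finite(p1) || p1 == 0) {
    reason <- "p1_zero"
  } else {
    ppr <- p2 / p1
    lim <- if (interval_ms >= 1000) 5 else 30
    if (ppr > lim || ppr < 0) { reason <- "out_of_range"; ppr <- NA_real_ }
  }
  out <- data.frame(interval_ms = interval_ms, ppr = ppr,
                    omission_reason = reason)
  class(out) <- c("ppr_result", "data.frame")
  out
}

#' Fit a one-phase association to a FRAP recovery curve
#'
#' Least-squares fit of `f(t) = M * (1 - exp(-t / tau))` to the post-bleach
#' fractional-recovery values, `t` measured from the bleach frame. The fit
#' is initialized from the time to half of the final recovery
#' (`tau0 = t_half / ln 2`) and the last value (`M0`). A flat curve (final
#' recovery below `flat_tol`) is returned with `mobile_fraction = 0` and
#' `tau_s = NA`, flagged unidentifiable.
#'
#' @param curve a `frap_curve` (from [gen_frap_curve()]) or data frame with
#'   `time_s`, `value`, `phase`.
#' @param flat_tol recovery level below which tau is unidentifiable
#'   (default 1e-3).
#' @return object of class `frap_fit`: list with `tau_s`,
#'   `mobile_fraction`, `bleach_diameter_nm`, `identifiable`, `rss`.
#' @export
fit_frap <- function(curve, flat_tol = 1e-3) {
  post <- curve[curve$phase == "postbleach", , drop = FALSE]
  if (nrow(post) < 10) vz_stop("need at least 10 post-bleach frames")
  tt <- post$time_s - post$time_s[1]
  yy <- post$value
  M0 <- yy[length(yy)]
  if (!is.finite(M0) || M0 < flat_tol) {
    return(structure(list(tau_s = NA_real_, mobile_fraction = 0,
                          bleach_diameter_nm = attr(curve, "bleach_diameter_nm"),
                          identifiable = FALSE, rss = sum(yy^2)),
                     class = "frap_fit"))
  }
  ihalf <- which(yy >= M0 / 2)[1]
  tau0 <- max(tt[ihalf], tt[2]) / log(2)
  rss <- function(p) sum((yy - p[1] * (1 - exp(-tt / exp(p[2]))))^2)
  # bounded quasi-Newton on (M, log tau): robust on zero-residual
  # (noiseless) curves where Gauss-Newton nls stalls
  best <- NULL
  for (fac in c(1, 0.5, 2, 0.1, 10)) {
    fit <- tryCatch(
      stats::optim(c(M0, log(tau0 * fac)), rss, method = "L-BFGS-B",
                   lower = c(0, log(1e-6)), upper = c(1.5, log(1e6)),
                   control = list(factr = 10, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    vz_stop("FRAP fit did not converge after bounded restarts (M0=%g, tau0=%g)", M0, tau0)
  M <- best$par[1]; tau <- exp(best$par[2])
  if (M > 1.05)
    warning(sprintf("fitted mobile fraction %.3f outside [0, 1.05]", M))
  structure(list(tau_s = tau, mobile_fraction = M,
                 bleach_diameter_nm = attr(curve, "bleach_diameter_nm"),
                 identifiable = TRUE, rss = best$value),
            class = "frap_fit")
}

#' Coefficient of variation of a line profile (variance / mean)
#'
#' The dispersion CV used here is the population variance of the intensity
#' profile divided by its mean (this unconventional variance-to-mean form is
#' the field's stated definition for condensate dispersion; the conventional
#' SD/mean is available via `conventional = TRUE` but is never the default).
#'
#' @param profile numeric intensity profile (mean must be > 0).
#' @param conventional use SD/mean instead of variance/mean (default FALSE).
#' @return scalar raw CV.
#' @export
compute_cv <- function(profile, conventional = FALSE) {
  m <- mean(profile)
  if (!is.finite(m) || m <= 0) vz_stop("profile mean must be > 0")
  v <- vz_pop_var(profile)
  if (conventional) sqrt(v) / m else v / m
}

#' Normalize raw CVs by the condition average
#'
#' @param raw_cv numeric vector of raw CVs measured within one condition.
#' @return data frame `raw_cv`, `normalized_cv` (raw divided by the
#'   condition mean raw CV).
#' @export
normalize_cv <- function(raw_cv) {
  if (length(raw_cv) == 0) vz_stop("no CV values")
  data.frame(raw_cv = raw_cv, normalized_cv = raw_cv / mean(raw_cv))
}

#' Activity-driven dispersion time course
#'
#' Normalizes each ROI intensity trace to its pre-stimulus baseline mean,
#' averages across ROIs and reports the dispersion depth (minimum of the
#' mean trace) and the recovery time: the first post-minimum time at which
#' the mean trace returns to 90% of baseline.
#'
#' @param traces matrix (frames x ROIs) or vector of intensities.
#' @param time_s frame times.
#' @param stim_onset_s stimulation onset; frames before it define baseline.
#' @return list with `time_s`, `mean`, `sem`, `depth`,
#'   `recovery_time_s` (NA if the trace never returns to 90%).
#' @export
dispersion_timecourse <- function(traces, time_s, stim_onset_s) {
  if (is.vector(traces)) traces <- matrix(traces, ncol = 1)
  if (nrow(traces) != length(time_s)) vz_stop("traces and time must align")
  base <- which(time_s < stim_onset_s)
  if (length(base) == 0) vz_stop("no baseline frames precede stimulation")
  norm <- sweep(traces, 2, colMeans(traces[base, , drop = FALSE]), "/")
  m <- rowMeans(norm)
  s <- apply(norm, 1, vz_sem)
  post <- which(time_s >= stim_onset_s)
  imin <- post[which.min(m[post])]
  depth <- m[imin]
  rec <- which(seq_along(m) > imin & m >= 0.9)
  list(time_s = time_s, mean = m, sem = s, depth = depth,
       recovery_time_s = if (length(rec)) time_s[rec[1]] else NA_real_)
}
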