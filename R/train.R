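#' Normalize a train record to its first response
#'
#' Divides all amplitudes by the first and attaches cumulative sums.
#'
#' @param record a `train_record` (list with `amplitudes`, `rate_hz`,
#'   `n_pulses`, optional `recovery`).
#' @return object of class `normalized_train`: list with `norm_amplitudes`,
#'   `cum`, `rate_hz`, `n_pulses`.
#' @export
normalize_train <- function(record) {
  a <- record$amplitudes
  if (length(a) == 0 || !is.finite(a[1]) || a[1] <= 0)
    vz_stop("first amplitude must be > 0")
  norm <- a / a[1]
  structure(list(norm_amplitudes = norm, cum = cumsum(norm),
                 rate_hz = record$rate_hz %||% NA_real_,
                 n_pulses = length(a)),
            class = "normalized_train")
}

#' Average normalized amplitude over the first or last ten stimulations
#'
#' @param train a [normalize_train()] result.
#' @param window `"first_ten"` or `"last_ten"`.
#' @return scalar mean of the indicated ten normalized amplitudes.
#' @export
window_average <- function(train, window = c("first_ten", "last_ten")) {
  window <- match.arg(window)
  n <- train$n_pulses
  if (n < 10) vz_stop("train has fewer than 10 pulses")
  idx <- if (window == "first_ten") 1:10 else (n - 9):n
  mean(train$norm_amplitudes[idx])
}

#' Readily-releasable-pool estimate by linear back-extrapolation
#'
#' Ordinary least squares of cumulative normalized amplitude on pulse index
#' over the final `tail_points` pulses (the steady-state phase). The
#' intercept at pulse index 0 estimates the RRP in units of the first
#' response (the "nq" estimate); the slope is the per-pulse steady-state
#' replenishment. A tail with R-squared below 0.95 triggers a linearity
#' warning.
#'
#' @param train a [normalize_train()] result.
#' @param tail_points number of final pulses used for the regression
#'   (default 20).
#' @return object of class `rrp_estimate`: list with `intercept`, `slope`,
#'   `tail_range` (index interval), `r_squared`.
#' @export
backextrapolate_rrp <- function(train, tail_points = 20L) {
  n <- train$n_pulses
  if (anyNA(train$cum)) vz_stop("NaN amplitudes in train")
  if (tail_points < 2 || tail_points > n)
    vz_stop("'tail_points' must be in [2, n_pulses]")
  idx <- (n - tail_points + 1):n
  y <- train$cum[idx]
  fit <- stats::lm(y ~ idx)
  co <- stats::coef(fit)
  ssr <- sum(stats::resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= .Machine$double.eps * max(abs(y))^2) 1 else 1 - ssr / sst
  if (is.finite(r2) && r2 < 0.95)
    warning(sprintf("tail not linear: R-squared %.3f < 0.95", r2))
  structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                 tail_range = c(idx[1], idx[length(idx)]),
                 r_squared = max(min(r2, 1), 0)),
            class = "rrp_estimate")
}

#' Post-train recovery curve and optional refill time constant
#'
#' Divides each recovery amplitude by the baseline (pre-train first-pulse)
#' amplitude and optionally fits a single-exponential refill
#' `f(dt) = 1 - (1 - c0) * exp(-dt / tau)`.
#'
#' @param record a `train_record` with a `recovery` data frame
#'   (`interval_ms`, `amplitude`).
#' @param baseline_amplitude baseline amplitude (> 0).
#' @param fit_tau also fit the recovery time constant (default TRUE).
#' @return data frame `interval_ms`, `fraction_recovered` with attribute
#'   `tau_rec_ms` (NA when not fitted or not converged).
#' @export
recovery_curve <- function(record, baseline_amplitude, fit_tau = TRUE) {
  vz_check_number(baseline_amplitude, "baseline_amplitude", positive = TRUE)
  rec <- record$recovery
  if (is.null(rec) || nrow(rec) == 0) vz_stop("record has no recovery stimuli")
  frac <- rec$amplitude / baseline_amplitude
  out <- data.frame(interval_ms = rec$interval_ms, fraction_recovered = frac)
  tau <- NA_real_
  if (fit_tau && nrow(rec) >= 3) {
    dt <- rec$interval_ms
    rss <- function(p) sum((frac - (1 - (1 - p[1]) * exp(-dt / exp(p[2]))))^2)
    best <- NULL
    for (tau0 in c(stats::median(dt), max(dt), min(dt))) {
      fit <- tryCatch(
        stats::optim(c(max(min(frac[1], 0.99), 0), log(max(tau0, 1))), rss,
                     method = "L-BFGS-B",
                     lower = c(0, log(1)), upper = c(1, log(1e6)),
                     control = list(factr = 10, maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (!is.null(best)) tau <- exp(best$par[2])
  }
  attr(out, "tau_rec_ms") <- tau
  out
}
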