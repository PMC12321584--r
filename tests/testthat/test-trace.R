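# Fluorescence time-series analysis: rolling ball, dF/F, peaks/PPR, FRAP,
# CV, dispersion time courses.

test_that("rolling-ball background subtraction contracts", {
  expect_equal(background_subtract(matrix(7, 20, 20), 5), matrix(0, 20, 20))
  expect_equal(background_subtract(rep(3, 50), 7), rep(0, 50))
  expect_error(background_subtract(matrix(1, 5, 5), 10), "larger")
  # flat background + narrow tall blob: blob preserved within 2%
  x <- seq_len(64)
  blob <- 200 * exp(-(outer(x, x, function(a, b) (a - 32)^2 + (b - 32)^2)) / 2)
  img <- 100 + blob
  out <- background_subtract(img, 7)
  expect_lt(abs(max(out) - 200) / 200, 0.02)
  expect_lt(mean(out[blob < 1e-3]), 1)
  expect_true(all(out >= 0))
})

test_that("dF/F: baseline window, gain invariance, exact transients", {
  tr <- structure(list(time_ms = seq(0, 999, by = 7.5),
                       intensity = rep(10, 134), stim_times_ms = 500),
                  class = "raw_trace")
  d <- compute_dff(tr)
  expect_true(all(d$dff == 0))
  expect_equal(attr(d, "f0"), 10)
  # gain invariance
  tr2 <- tr; tr2$intensity <- tr$intensity * 7.3
  expect_equal(compute_dff(tr2)$dff, d$dff)
  # f0 window is ~300 ms -> 40 frames at 7.5 ms
  tr3 <- tr
  tr3$intensity[1:20] <- 1000  # frames well before the window: ignored
  expect_equal(attr(compute_dff(tr3), "f0"), 10)
  expect_error(compute_dff(structure(list(time_ms = 0:10, intensity = rep(0, 11),
                                          stim_times_ms = 5), class = "raw_trace")),
               "F0")
  g <- gen_dff_trace(trace_config(noise_sd = 0, amp1 = 0.5,
                                  stim_times_ms = 750), 1)
  expect_equal(max(compute_dff(g$trace)$dff), 0.5, tolerance = 1e-12)
})

test_that("peak extraction and PPR: exact recovery and omission rules", {
  # noiseless two-pulse trace, overlapping at 50 ms: decay correction
  # recovers ppr_true exactly
  for (ppr_true in c(0.5, 1, 2)) {
    g <- gen_dff_trace(trace_config(noise_sd = 0, ppr_true = ppr_true), 3)
    pk <- extract_peaks(compute_dff(g$trace))
    expect_false(any(pk$failure))
    expect_equal(compute_ppr(pk, 50)$ppr, ppr_true, tolerance = 1e-6)
  }
  # long interval: no overlap, p2/p1 = ppr within 1%
  g <- gen_dff_trace(trace_config(noise_sd = 0, ppr_true = 1,
                                  stim_times_ms = c(750, 1250)), 3)
  pk <- extract_peaks(compute_dff(g$trace))
  expect_equal(pk$peak[2] / pk$peak[1], 1, tolerance = 0.01)
  # flat trace: all failures flagged
  flat <- structure(list(time_ms = seq(0, 2999, 7.5),
                         intensity = rep(50, 400), stim_times_ms = c(750, 800)),
                    class = "raw_trace")
  pkf <- extract_peaks(compute_dff(flat))
  expect_true(all(pkf$failure))

  # omission rules
  mkpk <- function(p1, p2) structure(data.frame(stim = 1:2, stim_time_ms = c(0, 50),
                                                peak = c(p1, p2), failure = FALSE),
                                     class = c("peak_set", "data.frame"))
  expect_equal(compute_ppr(mkpk(0.2, 0.4), 50)$ppr, 2)
  r35 <- compute_ppr(mkpk(0.01, 0.35), 50)
  expect_true(is.na(r35$ppr) && r35$omission_reason == "out_of_range")
  r6 <- compute_ppr(mkpk(0.1, 0.6), 1000)
  expect_true(is.na(r6$ppr) && r6$omission_reason == "out_of_range")
  expect_equal(compute_ppr(mkpk(0.1, 0.6), 500)$ppr, 6)  # limit 30 below 1 s
  rz <- compute_ppr(mkpk(0, 0.1), 50)
  expect_equal(rz$omission_reason, "p1_zero")
})

test_that("FRAP fit: closed-form recovery, flat flag, scale equivariance", {
  g <- gen_frap_curve(frap_config(tau_s = 2, mobile_fraction = 0.8,
                                  noise_sd = 0), 1)
  f <- fit_frap(g$curve)
  expect_equal(f$tau_s, 2, tolerance = 1e-3)
  expect_equal(f$mobile_fraction, 0.8, tolerance = 1e-3)
  # flat curve: mobile fraction 0, tau flagged unidentifiable
  flat <- gen_frap_curve(frap_config(mobile_fraction = 0, noise_sd = 0), 1)
  ff <- fit_frap(flat$curve)
  expect_false(ff$identifiable)
  expect_equal(ff$mobile_fraction, 0)
  # doubling all times doubles fitted tau
  cu <- g$curve; cu$time_s <- cu$time_s * 2
  expect_equal(fit_frap(cu)$tau_s, 4, tolerance = 1e-3)
  expect_error(fit_frap(g$curve[1:8, ]), "10 post-bleach")
})

test_that("CV: definition, normalization, rank preservation", {
  expect_equal(compute_cv(rep(4, 100)), 0)
  expect_equal(compute_cv(c(1, 3)), 0.5)  # population variance 1 / mean 2
  expect_equal(compute_cv(c(1, 3), conventional = TRUE), 0.5)
  expect_error(compute_cv(c(-2, 0)), "mean")
  set.seed(8)
  raw <- sapply(1:6, function(s) compute_cv(gen_axon_profile(5, 4, 10, 0.2, s)$punctate))
  nc <- normalize_cv(raw)
  expect_equal(mean(nc$normalized_cv), 1)
  expect_equal(order(nc$normalized_cv), order(raw))
})

test_that("dispersion time course: depth, recovery, invariances", {
  t <- seq(0, 100, by = 1)
  flat <- rep(5, length(t))
  r <- dispersion_timecourse(flat, t, 20)
  expect_true(all(r$mean == 1))
  # planted 20% dip recovering to baseline
  dip <- 1 - 0.2 * exp(-abs(t - 40) / 10) * (t >= 20)
  traces <- sapply(1:5, function(k) 50 * dip)
  r2 <- dispersion_timecourse(traces, t, 20)
  expect_equal(r2$depth, 0.8, tolerance = 0.01)
  expect_true(r2$recovery_time_s > 40)
  # scale invariance
  r3 <- dispersion_timecourse(traces * 3.7, t, 20)
  expect_equal(r3$mean, r2$mean)
  expect_error(dispersion_timecourse(flat, t, -5), "baseline")
})
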