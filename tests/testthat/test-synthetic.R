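# Generators: determinism, planted-truth structure, stated-world geometry.

test_that("generators are pure functions of (config, seed)", {
  cfgs <- list(
    sted = function(s) gen_sted_scene(sted_scene_config(), s)$scene$channels$puncta,
    em = function(s) gen_em_cohort(em_cohort_config(n_profiles = 3L), s)$truth$counts,
    dff = function(s) gen_dff_trace(trace_config(), s)$trace$intensity,
    frap = function(s) gen_frap_curve(frap_config(), s)$curve$value,
    train = function(s) gen_train(train_config(), s)$record$amplitudes,
    axon = function(s) gen_axon_profile(5, 3, 10, 0.2, s)$punctate)
  for (nm in names(cfgs)) {
    a <- cfgs[[nm]](11); b <- cfgs[[nm]](11); c <- cfgs[[nm]](12)
    expect_identical(a, b, info = nm)
    expect_false(identical(a, c), info = nm)
  }
})

test_that("noiseless STED scene plants puncta exactly; noise leaves truth fixed", {
  cfg <- sted_scene_config(puncta_offsets_nm = 0, photon_scale = Inf)
  g <- gen_sted_scene(cfg, 1)
  # punctum at offset 0 sits on the true midline
  expect_equal(unname(g$truth$puncta_nm[1, "y"]), g$truth$midline$midpoint[2])
  # brightest pixel of the punctum channel is at the planted position
  ch <- g$scene$channels$puncta
  pk <- which(ch == max(ch), arr.ind = TRUE)[1, ]
  px <- g$scene$pixel_size_nm
  expect_lt(abs((pk[2] - 0.5) * px - g$truth$puncta_nm[1, "x"]), px)
  expect_lt(abs((pk[1] - 0.5) * px - g$truth$puncta_nm[1, "y"]), px)
  # different seeds: different noise realizations, identical truth
  g1 <- gen_sted_scene(sted_scene_config(), 5)
  g2 <- gen_sted_scene(sted_scene_config(), 6)
  expect_false(identical(g1$scene$channels$puncta, g2$scene$channels$puncta))
  expect_identical(g1$truth, g2$truth)
})

test_that("centroid of noiseless blob recovers a +50 nm offset within 10 nm", {
  cfg <- sted_scene_config(puncta_offsets_nm = 50, pixel_size_nm = 20,
                           psf_fwhm_nm = 50, photon_scale = Inf)
  g <- gen_sted_scene(cfg, 1)
  ch <- g$scene$channels$puncta - cfg$background_level
  # independent centroid oracle on the noiseless render
  idx <- which(ch >= max(ch) / 2, arr.ind = TRUE)
  w <- ch[idx]
  cy <- sum((idx[, 1] - 0.5) * 20 * w) / sum(w)
  cx <- sum((idx[, 2] - 0.5) * 20 * w) / sum(w)
  expect_lt(sqrt((cx - g$truth$puncta_nm[1, "x"])^2 +
                 (cy - g$truth$puncta_nm[1, "y"])^2), 10)
})

test_that("STED config rejects puncta outside the image, naming the offset", {
  expect_error(gen_sted_scene(sted_scene_config(puncta_offsets_nm = 1e4), 1),
               "1e\\+04|10000")
})

test_that("EM generator: docked tangency, empty cohort, distance law", {
  g <- gen_em_cohort(em_cohort_config(n_profiles = 3L, docked_mean = 0,
                                      replacement_mean = 0, reserve_mean = 0), 1)
  expect_true(all(vapply(g$profiles, function(p) nrow(p$vesicles) == 0, TRUE)))
  expect_true(all(vapply(g$profiles, function(p) nrow(p$membrane) > 10, TRUE)))

  g <- gen_em_cohort(em_cohort_config(n_profiles = 20L, docked_mean = 3,
                                      replacement_mean = 2, reserve_mean = 5), 2)
  for (i in seq_along(g$profiles)) {
    p <- g$profiles[[i]]
    vm <- classify_vesicles(p)
    docked_truth <- g$truth$counts$docked[i]
    # docked vesicles have edge distance 0 within numeric tolerance
    expect_equal(sum(vm$edge_distance_nm < 1e-6), docked_truth)
    # no vesicle pair overlaps
    if (nrow(p$vesicles) > 1) {
      dd <- as.matrix(dist(cbind(p$vesicles$x, p$vesicles$y)))
      diag(dd) <- Inf
      expect_gte(min(dd), 2 * p$vesicles$r[1] - 1e-9)
    }
  }

  # law of large numbers on uniform(0, 20] replacement distances
  cfg <- em_cohort_config(n_profiles = 250L, docked_mean = 0, reserve_mean = 0,
                          replacement_mean = 4,
                          replacement_distance_law = list(law = "uniform", min = 0, max = 20))
  g <- gen_em_cohort(cfg, 3)
  d <- unlist(g$truth$distances_nm)
  expect_gt(length(d), 800)
  expect_lt(abs(mean(d) - 10), 0.5)
})

test_that("EM packing beyond AZ slot capacity errors", {
  expect_error(gen_em_cohort(em_cohort_config(n_profiles = 50L, docked_mean = 30,
                                              az_length_nm = 200), 1),
               "infeasible")
})

test_that("noiseless dF/F transients carry exact amplitudes and PPR", {
  g <- gen_dff_trace(trace_config(noise_sd = 0, ppr_true = 1), 1)
  dff <- (g$trace$intensity - g$truth$f0) / g$truth$f0
  t <- g$trace$time_ms
  p <- sapply(g$trace$stim_times_ms, function(s) max(dff[t > s & t <= s + 7.5]))
  # ppr_true = 1: both transients the same height after removing the first
  # transient's tail under the second (closed-form overlap)
  tail1 <- g$truth$amp1 * exp(-(t - t[which(t > 750)[1]]) / 30)
  p2_corr <- max((dff - tail1)[t > 800 & t <= 850])
  expect_equal(p[1], g$truth$amp1)
  expect_equal(p2_corr, g$truth$amp1, tolerance = 1e-9)
})

test_that("FRAP curve follows the one-phase association closed form", {
  cfg <- frap_config(tau_s = 2, mobile_fraction = 0.8, noise_sd = 0)
  g <- gen_frap_curve(cfg, 1)
  post <- g$curve[g$curve$phase == "postbleach", ]
  tt <- post$time_s - post$time_s[1]
  i <- which.min(abs(tt - 2))
  expect_equal(post$value[i], 0.8 * (1 - exp(-tt[i] / 2)), tolerance = 1e-12)
  # immobile condensate: flat post-bleach curve
  flat <- gen_frap_curve(frap_config(mobile_fraction = 0, noise_sd = 0), 1)
  expect_true(all(flat$curve$value[flat$curve$phase == "postbleach"] == 0))
})

test_that("train generator matches the depletion model closed forms", {
  g <- gen_train(train_config(p_release = 0.4, replenish_rate = 0, noise_sd = 0,
                              rrp_true = 8), 1)
  a <- g$record$amplitudes
  expect_equal(a[-1] / a[-length(a)], rep(0.6, length(a) - 1), tolerance = 1e-12)
  expect_equal(sum(a), 8, tolerance = 1e-9)  # full pool released
  g1 <- gen_train(train_config(p_release = 1, replenish_rate = 0, noise_sd = 0,
                               rrp_true = 5), 1)
  expect_equal(g1$record$amplitudes[1], 5)
  expect_true(all(g1$record$amplitudes[-1] == 0))
})

test_that("axon profile: CV ordering and intensity conservation", {
  g0 <- gen_axon_profile(0, 0, 10, 0, 1)
  expect_equal(compute_cv(g0$punctate), 0)
  for (s in 1:5) {
    g <- gen_axon_profile(6, 5, 10, 0.1, s)
    expect_equal(sum(g$punctate), sum(g$dispersed), tolerance = 1e-9)
    expect_gt(compute_cv(g$punctate), compute_cv(g$dispersed))
  }
})
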