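# EM morphometry: edge distances, docked/replacement classification,
# 2-nm histograms, pits, cohort summaries, annotation JSON round trip.

test_that("edge_distance: flat-membrane cases and the dense-sampling oracle", {
  flat <- cbind(seq(-200, 200, by = 10), 0)
  expect_equal(edge_distance(c(0, 40), 20, flat), 20)
  expect_equal(edge_distance(c(0, 20), 20, flat), 0)
  expect_equal(edge_distance(c(0, 10), 20, flat), 0)  # overlap clamps to 0
  expect_error(edge_distance(c(0, 10), 20, flat[0, , drop = FALSE]), "empty")
  expect_error(edge_distance(c(0, 10), -1, flat), "radius")

  set.seed(5)
  for (rep in 1:10) {
    poly <- random_polyline(n_seg = 8)
    for (k in 1:10) {
      p <- c(runif(1, min(poly[, 1]) - 50, max(poly[, 1]) + 50),
             runif(1, min(poly[, 2]) - 50, max(poly[, 2]) + 50))
      r <- runif(1, 5, 25)
      got <- edge_distance(p, r, poly)
      want <- max(oracle_polyline_dist(p[1], p[2], poly) - r, 0)
      expect_lt(abs(got - want), 0.05)
    }
  }
})

test_that("classification: boundary conventions and partition invariants", {
  # hand-built profile with a flat AZ membrane and planted edge distances
  memb <- cbind(x = seq(-300, 300, by = 10), y = 0)
  r <- 20
  dists <- c(0, 5, 19, 20, 21)
  prof <- structure(list(
    membrane = memb, az_range = c(0L, nrow(memb)),
    vesicles = data.frame(x = seq(-200, 200, length.out = 5),
                          y = r + dists, r = r),
    pits = data.frame(x = numeric(0), y = numeric(0), kind = character(0)),
    meta = list(condition = "a", timepoint = "t")), class = "em_profile")
  vm <- classify_vesicles(prof)
  expect_equal(sum(vm$status == "docked"), 1)
  expect_equal(sum(vm$in_replacement_zone), 3)  # 5, 19 and exactly 20 (closed bound)
  expect_true(vm$in_replacement_zone[4])
  expect_false(vm$in_replacement_zone[5])
  # partition: docked + undocked = total
  expect_equal(sum(vm$status == "docked") + sum(vm$status == "undocked"), nrow(vm))
  # monotonicity: enlarging the docking tolerance never loses docked vesicles
  n_prev <- 0
  for (tol in c(0, 0.5, 5, 19, 25)) {
    n <- sum(classify_vesicles(prof, docking_tol_nm = tol)$status == "docked")
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("distance histogram: bins, normalization, uniform law", {
  h <- distance_histogram(c(3, 3, 19, 49))
  expect_equal(length(h$rel_freq), 24)
  expect_equal(h$rel_freq[1], 0.5)    # [2,4)
  expect_equal(h$rel_freq[9], 0.25)   # [18,20)
  expect_equal(h$rel_freq[24], 0.25)  # [48,50)
  expect_equal(sum(h$rel_freq), 1)
  expect_equal(h$n_total, 4)
  # sub-2-nm and >= 50 nm distances are excluded from the histogram
  h2 <- distance_histogram(c(1, 3, 50, 60))
  expect_equal(h2$n_total, 1)
  expect_warning(distance_histogram(numeric(0)), "all-zero")
  set.seed(6)
  h3 <- distance_histogram(runif(1e5, 2, 50))
  expect_true(all(abs(h3$rel_freq - 1 / 24) < 0.005))
})

test_that("pit counting by nearest-membrane-vertex membership", {
  memb <- cbind(x = seq(-300, 300, by = 10), y = 0)
  az <- c(20L, 41L)  # 0-based half-open
  prof <- structure(list(
    membrane = memb, az_range = az,
    vesicles = data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
    pits = data.frame(x = c(-95, -290, 145), y = c(2, 1, -1),
                      kind = c("exocytic", "exocytic", "clathrin")),
    meta = list(condition = "a", timepoint = "t")), class = "em_profile")
  pc <- count_pits(prof)
  expect_equal(pc$in_az[pc$kind == "exocytic"], 1)      # -95 projects into AZ
  expect_equal(pc$outside_az[pc$kind == "exocytic"], 1) # -290 outside
  expect_equal(pc$total[pc$kind == "clathrin"], 1)
  prof0 <- prof
  prof0$pits <- data.frame(x = numeric(0), y = numeric(0), kind = character(0))
  expect_equal(sum(count_pits(prof0)$total), 0)
})

test_that("cohort summary: SEM conventions and truth recovery", {
  g <- gen_em_cohort(em_cohort_config(n_profiles = 30L), 11)
  cs <- summarize_cohort(g$profiles)
  expect_identical(cs$per_profile$docked, g$truth$counts$docked)
  expect_identical(cs$per_profile$replacement, g$truth$counts$replacement)
  expect_identical(cs$per_profile$total, g$truth$counts$total)
  srow <- cs$summary[cs$summary$metric == "docked", ]
  expect_equal(srow$mean, mean(g$truth$counts$docked))
  expect_equal(srow$sem, sd(g$truth$counts$docked) / sqrt(30))
  # single profile: SEM reported as 0 with n = 1
  cs1 <- summarize_cohort(g$profiles[1])
  expect_true(all(cs1$summary$sem == 0))
  expect_true(all(cs1$summary$n == 1))
  # two profiles {2, 4} docked -> mean 3, SEM 1 (direct convention check)
  expect_equal(vesiclezone:::vz_sem(c(2, 4)), 1)
})

test_that("annotation JSON round trip preserves the quantification", {
  g <- gen_em_cohort(em_cohort_config(n_profiles = 3L), 13)
  dir <- withr::local_tempdir()
  for (i in 1:3) {
    path <- file.path(dir, sprintf("p%d.json", i))
    write_em_annotation(g$profiles[[i]], path)
    back <- read_em_annotation(path)
    expect_equal(back$az_range, g$profiles[[i]]$az_range)
    vm0 <- classify_vesicles(g$profiles[[i]])
    vm1 <- classify_vesicles(back)
    expect_equal(vm1$edge_distance_nm, vm0$edge_distance_nm, tolerance = 1e-9)
  }
  expect_error(read_em_annotation(
    local({ p <- file.path(dir, "bad.json")
            jsonlite::write_json(list(membrane = list(c(0, 0))), p); p })),
    "missing field")
  # shipped synthetic example annotation parses and classifies
  ex <- read_em_annotation(system.file("extdata", "synthetic_em_profile.json",
                                       package = "vesiclezone"))
  vm <- classify_vesicles(ex)
  expect_true(nrow(vm) >= 1)
  expect_true(all(vm$edge_distance_nm >= 0))
})
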