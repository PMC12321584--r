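# STED morphometry chain: smoothing, blind deconvolution, punctum
# detection, half-max boundaries, midline fitting, distances.

test_that("preblur conserves flux and leaves constants unchanged", {
  const <- matrix(5, 16, 16)
  expect_equal(preblur(const), const, tolerance = 1e-12)
  set.seed(1)
  img <- matrix(rpois(32 * 32, 50), 32, 32)
  expect_lt(abs(sum(preblur(img)) - sum(img)) / sum(img), 0.001)
  # delta impulse becomes a Gaussian blob with the stated sigma
  d <- matrix(0, 33, 33); d[17, 17] <- 1
  b <- preblur(d, radius_px = 2)
  expect_equal(b[17, 19] / b[17, 17], exp(-4 / (2 * 4)), tolerance = 1e-6)
  expect_error(preblur(matrix(numeric(0), 0, 0)), "empty")
})

test_that("blind deconvolution: identity, sharpening, contracts", {
  set.seed(2)
  img <- matrix(rpois(32 * 32, 20), 32, 32) + 1
  delta <- matrix(0, 5, 5); delta[3, 3] <- 1
  out <- blind_deconvolve(img, delta, iterations = 3, passes = 1)
  expect_equal(out$image, img, tolerance = 1e-8)

  # blurred point source: deconvolution raises the peak
  src <- matrix(0, 32, 32); src[16, 16] <- 100
  blurred <- preblur(src, 2) + 0.01
  dec <- blind_deconvolve(blurred, vesiclezone:::vz_gaussian_kernel(1.5))
  expect_gt(max(dec$image), max(blurred))
  # non-negativity and flux conservation on random inputs
  for (s in 1:3) {
    set.seed(s)
    im <- matrix(rpois(24 * 24, 10), 24, 24)
    r <- blind_deconvolve(im, vesiclezone:::vz_gaussian_kernel(1))
    expect_true(all(r$image >= 0))
    expect_lt(abs(sum(r$image) - sum(im)) / sum(im), 0.01)
    expect_equal(sum(r$psf), 1, tolerance = 1e-9)
  }
  expect_error(blind_deconvolve(img, delta * 2), "normalized")
})

test_that("punctum detection: single blob, edge exclusion, separation", {
  px <- 20
  mk <- function(centers_px) {
    img <- matrix(0, 40, 40)
    for (c0 in centers_px) {
      src <- matrix(0, 40, 40); src[c0[1], c0[2]] <- 1000
      img <- img + preblur(src, 2)
    }
    img
  }
  one <- mk(list(c(20, 20)))
  p <- detect_puncta(one, px)
  expect_equal(nrow(p), 1)
  expect_equal(c(p$peak_row, p$peak_col), c(20, 20))

  # blob centered on the ROI edge is continuous with the border: excluded
  edge <- mk(list(c(1, 20)))
  expect_equal(nrow(detect_puncta(edge, px)), 0)

  # flat ROI gives an empty list, not an error
  expect_equal(nrow(detect_puncta(matrix(3, 20, 20), px)), 0)

  # two blobs 200 nm apart at high SNR: both found within 1 px of truth
  two <- mk(list(c(15, 15), c(25, 15)))
  p2 <- detect_puncta(two, px, min_separation_nm = 100)
  expect_equal(nrow(p2), 2)
  got <- sort(p2$y_nm)
  expect_lt(max(abs(got - c(14.5, 24.5) * px)), px)

  # two distinct maxima 80 nm apart (< min separation): brighter kept
  close2 <- mk(list(c(15, 20))) + 0.6 * mk(list(c(19, 20)))
  p3 <- detect_puncta(close2, px, min_separation_nm = 100)
  expect_equal(nrow(p3), 1)
  expect_lte(abs(p3$peak_row - 15), 1)
})

test_that("half-max contour of an ideal Gaussian has radius sigma*sqrt(2 ln 2)", {
  px <- 20; n <- 64; sig <- 50; c0 <- (n / 2) * px
  xc <- (seq_len(n) - 0.5) * px
  img <- outer(exp(-(xc - c0)^2 / (2 * sig^2)),
               exp(-(xc - c0)^2 / (2 * sig^2)))
  bc <- extract_boundary(img, c(n / 2, n / 2), px)
  r <- sqrt((bc$polygon_nm[, 1] - c0)^2 + (bc$polygon_nm[, 2] - c0)^2)
  expect_lt(abs(mean(r) - sig * sqrt(2 * log(2))) / (sig * sqrt(2 * log(2))), 0.05)
  expect_equal(bc$level, max(img) / 2)
  # peak on a constant image: no contour
  expect_error(extract_boundary(matrix(1, 16, 16), c(8, 8), px), "contour")
  # two separate blobs: each contour contains only its own peak
  img2 <- img + outer(exp(-(xc - 200)^2 / (2 * 40^2)),
                      exp(-(xc - 200)^2 / (2 * 40^2)))
  b1 <- extract_boundary(img2, c(n / 2, n / 2), px)
  expect_false(vesiclezone:::vz_point_in_polygon(200, 200, b1$polygon_nm))
})

test_that("midline fitting: orientation, rotation oracle, width recovery", {
  px <- 10
  # horizontal rectangle: horizontal midline through its centroid
  img <- matrix(0, 60, 60)
  img[28:33, 10:50] <- 1
  ml <- fit_midline(img, px)
  expect_equal(abs(ml$direction), c(1, 0), tolerance = 1e-9)
  expect_equal(ml$midpoint_nm[2], mean(c(27, 33)) * px, tolerance = px)

  # rotated rectangle: angle within 1 degree of the moment-of-inertia oracle
  th <- 30 * pi / 180
  rot <- matrix(0, 80, 80)
  for (i in 1:80) for (j in 1:80) {
    x <- (j - 0.5) * px - 400; y <- (i - 0.5) * px - 400
    u <- x * cos(th) + y * sin(th); v <- -x * sin(th) + y * cos(th)
    if (abs(u) <= 150 && abs(v) <= 40) rot[i, j] <- 1
  }
  ml2 <- fit_midline(rot, px)
  ang <- atan2(ml2$direction[2], ml2$direction[1]) * 180 / pi
  expect_lt(abs(ang - 30), 1)

  # planted 100-nm bar at high SNR: width within 10 nm
  g <- gen_sted_scene(sted_scene_config(), 42)
  ml3 <- fit_midline(g$scene$channels$bar, g$scene$pixel_size_nm)
  expect_lt(abs(ml3$width_estimate_nm - 100), 10)

  # isotropic blob: warning plus deterministic tie-break
  iso <- matrix(0, 40, 40); iso[18:22, 18:22] <- 1
  expect_warning(fit_midline(iso, px), "isotropic")
})

test_that("distance records: basic geometry and rigid-motion invariance", {
  ml <- structure(list(endpoints_nm = rbind(c(0, 0), c(200, 0)),
                       midpoint_nm = c(100, 0), direction = c(1, 0),
                       width_estimate_nm = 100, length_nm = 200),
                  class = "midline")
  pts <- data.frame(id = 1:3, channel = "p",
                    x_nm = c(100, 100, 350), y_nm = c(0, 50, 120))
  r <- measure_distances(pts, ml)
  expect_equal(r$d_midline_nm, c(0, 50, 120))
  expect_equal(r$d_midpoint_nm[2], 50, tolerance = 1e-9)
  expect_true(all(r$d_midpoint_nm >= r$d_midline_nm - 1e-12))

  # invariance under global rotation + translation
  th <- runif(1, 0, 2 * pi); tr <- runif(2, -500, 500)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- function(xy) sweep(xy %*% t(R), 2, -tr)
  ep <- rot(ml$endpoints_nm)
  ml2 <- structure(list(endpoints_nm = ep, midpoint_nm = colMeans(ep),
                        direction = as.numeric(R %*% c(1, 0)),
                        width_estimate_nm = 100, length_nm = 200),
                   class = "midline")
  p2 <- rot(cbind(pts$x_nm, pts$y_nm))
  pts2 <- data.frame(id = 1:3, channel = "p", x_nm = p2[, 1], y_nm = p2[, 2])
  r2 <- measure_distances(pts2, ml2)
  expect_equal(r2$d_midline_nm, r$d_midline_nm, tolerance = 1e-6)
  expect_equal(r2$d_midpoint_nm, r$d_midpoint_nm, tolerance = 1e-6)
})

test_that("signed boundary distances match the brute-force oracle", {
  set.seed(4)
  th <- seq(0, 2 * pi, length.out = 41)
  rad <- 80 + 25 * sin(3 * th[-41])
  poly <- cbind(300 + c(rad, rad[1]) * cos(th), 300 + c(rad, rad[1]) * sin(th))
  contour <- structure(list(polygon_nm = poly, level = 1,
                            parent_peak_nm = c(300, 300)),
                       class = "boundary_contour")
  ml <- structure(list(endpoints_nm = rbind(c(0, 300), c(600, 300)),
                       midpoint_nm = c(300, 300), direction = c(1, 0),
                       width_estimate_nm = 1, length_nm = 600),
                  class = "midline")
  pts <- data.frame(id = 1:40, channel = "p",
                    x_nm = runif(40, 100, 500), y_nm = runif(40, 100, 500))
  r <- measure_distances(pts, ml, contour)
  for (k in 1:40) {
    o <- oracle_polyline_dist(pts$x_nm[k], pts$y_nm[k], poly)
    if (oracle_in_polygon(pts$x_nm[k], pts$y_nm[k], poly)) o <- -o
    expect_equal(r$d_boundary_nm[k], o, tolerance = 0.1)
  }
})

test_that("fraction_within_window matches counts and the probability integral", {
  rec <- data.frame(d_midline_nm = c(10, 40, 60))
  expect_equal(fraction_within_window(rec, 50), 2 / 3)
  expect_equal(fraction_within_window(data.frame(d_midline_nm = rep(0, 5))), 1)
  expect_error(fraction_within_window(data.frame(d_midline_nm = numeric(0))),
               "non-empty")
  set.seed(9)
  rec2 <- data.frame(d_midline_nm = runif(10000, 0, 100))
  expect_lt(abs(fraction_within_window(rec2, 50) - 0.5), 0.02)
})
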