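#' Gaussian pre-smoothing of a STED image
#'
#' Blurs an image with a Gaussian filter of the given radius (sigma, in
#' pixels) to reduce Poisson noise before deconvolution. The default radius
#' of 1.2 pixels follows the standard STED preprocessing chain. Circular
#' convolution with a normalized kernel conserves total intensity.
#'
#' @param image numeric matrix.
#' @param radius_px Gaussian sigma in pixels (default 1.2).
#' @return smoothed matrix, same shape.
#' @export
preblur <- function(image, radius_px = 1.2) {
  if (!is.matrix(image) || length(image) == 0) vz_stop("empty image")
  vz_check_number(radius_px, "radius_px", positive = TRUE)
  out <- vz_conv2(image, vz_gaussian_kernel(radius_px))
  out[out < 0] <- 0
  out
}

#' Two-pass blind Richardson-Lucy deconvolution
#'
#' Blind deconvolution by alternating Richardson-Lucy updates of the image
#' estimate and the PSF estimate. Two passes are run by default: the first
#' starts from `psf0`; the second restarts from the original image using the
#' refined PSF returned by the first pass. Ten iterations are performed per
#' pass. The multiplicative updates keep the image non-negative, and the
#' image update conserves total flux (circular boundary), so output flux
#' stays within 1% of input flux.
#'
#' @param image non-negative numeric matrix.
#' @param psf0 initial PSF: a small non-negative matrix summing to 1.
#' @param iterations Richardson-Lucy iterations per pass (default 10).
#' @param passes number of blind passes (default 2).
#' @return list with `image` (deconvolved estimate) and `psf` (refined PSF,
#'   normalized).
#' @export
blind_deconvolve <- function(image, psf0, iterations = 10L, passes = 2L) {
  if (!is.matrix(image) || length(image) == 0) vz_stop("empty image")
  if (!is.matrix(psf0) || any(psf0 < 0)) vz_stop("PSF must be a non-negative matrix")
  if (abs(sum(psf0) - 1) > 1e-6) vz_stop("PSF must be normalized (sum to 1)")
  if (iterations < 1) vz_stop("'iterations' must be >= 1")
  eps <- 1e-12 * max(image, 1e-12)
  d <- pmax(image, 0)
  h <- psf0
  kh <- nrow(h); kw <- ncol(h)
  nr <- nrow(d); nc <- ncol(d)
  f <- d
  for (p in seq_len(passes)) {
    f <- d  # each pass restarts from the original image
    for (it in seq_len(iterations)) {
      hf <- vz_embed_kernel(h, nr, nc)
      e <- pmax(Re(stats::fft(stats::fft(f) * stats::fft(hf), inverse = TRUE)) / length(f), eps)
      ratio <- d / e
      # PSF update: h(u) <- h(u) * sum_x f(x) ratio(x + u), renormalized.
      hc <- vz_corr2_full(f, ratio)
      h_new <- h * vz_extract_kernel(hc, kh, kw)
      h_new[h_new < 0] <- 0
      s <- sum(h_new)
      if (s > 0) h <- h_new / s
      # Image update with the refreshed PSF.
      hf <- vz_embed_kernel(h, nr, nc)
      e <- pmax(Re(stats::fft(stats::fft(f) * stats::fft(hf), inverse = TRUE)) / length(f), eps)
      ratio <- d / e
      corr <- vz_corr2_full(hf, ratio)
      f <- f * corr
      f[f < 0] <- 0
    }
  }
  list(image = f, psf = h)
}

# Connected component (8-connectivity) of mask containing (i0, j0).
vz_flood <- function(mask, i0, j0) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(FALSE, nr, nc)
  stack <- matrix(c(i0, j0), ncol = 2)
  comp[i0, j0] <- TRUE
  while (nrow(stack) > 0) {
    cur <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    for (di in -1:1) for (dj in -1:1) {
      i <- cur[1] + di; j <- cur[2] + dj
      if (i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j] && !comp[i, j]) {
        comp[i, j] <- TRUE
        stack <- rbind(stack, c(i, j))
      }
    }
  }
  comp
}

#' Detect protein puncta as local intensity maxima
#'
#' Picks local maxima (8-neighborhood) above a threshold inside a ROI,
#' suppresses maxima closer than `min_separation_nm` (the brighter one is
#' kept; ties broken by smallest row then column index), and excludes puncta
#' whose above-half-maximum region is continuous with the ROI edge. Punctum
#' centers are refined to the intensity-weighted centroid of the
#' above-half-maximum connected region.
#'
#' @param image numeric matrix (typically deconvolved).
#' @param pixel_size_nm pixel size in nm.
#' @param roi ROI box `c(row0, col0, row1, col1)` (inclusive, 1-based);
#'   default whole image.
#' @param min_separation_nm minimum punctum separation (default 100 nm).
#' @param threshold_rule either a function(mat) returning a scalar threshold
#'   or `NULL` for the default rule mean + 4 * SD over the ROI.
#' @param channel channel name stored on the result.
#' @return data frame of class `punctum_set`: `id`, `channel`, `x_nm`,
#'   `y_nm`, `peak_intensity`, `peak_row`, `peak_col`. Zero rows when the
#'   ROI is flat or nothing passes the threshold.
#' @export
detect_puncta <- function(image, pixel_size_nm, roi = NULL,
                          min_separation_nm = 100,
                          threshold_rule = NULL, channel = "puncta") {
  if (!is.matrix(image) || length(image) == 0) vz_stop("empty image")
  vz_check_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  if (is.null(roi)) roi <- c(1L, 1L, nrow(image), ncol(image))
  if (roi[1] < 1 || roi[2] < 1 || roi[3] > nrow(image) || roi[4] > ncol(image))
    vz_stop("roi outside image")
  sub <- image[roi[1]:roi[3], roi[2]:roi[4], drop = FALSE]
  empty <- data.frame(id = integer(0), channel = character(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      peak_intensity = numeric(0),
                      peak_row = integer(0), peak_col = integer(0))
  class(empty) <- c("punctum_set", "data.frame")
  if (max(sub) - min(sub) < .Machine$double.eps * max(abs(sub), 1))
    return(empty)
  thr <- if (is.null(threshold_rule)) mean(sub) + 4 * stats::sd(sub)
         else threshold_rule(sub)
  nr <- nrow(sub); nc <- ncol(sub)
  cand <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- sub[i, j]
    if (v <= thr) next
    is_max <- TRUE
    strict <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      nb <- sub[ii, jj]
      if (nb > v) is_max <- FALSE
      if (nb < v) strict <- TRUE
      # plateau tie-break: keep only the smallest (row, col) of equal pixels
      if (nb == v && (ii < i || (ii == i && jj < j))) is_max <- FALSE
    }
    if (is_max && (strict || v > thr)) cand <- rbind(cand, c(i, j, v))
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  # non-maximum suppression by minimum separation (keep brighter)
  keep <- rep(TRUE, nrow(cand))
  for (a in seq_len(nrow(cand))) {
    if (!keep[a]) next
    if (a < nrow(cand)) for (b in (a + 1):nrow(cand)) {
      if (!keep[b]) next
      dnm <- pixel_size_nm * sqrt((cand[a, 1] - cand[b, 1])^2 + (cand[a, 2] - cand[b, 2])^2)
      if (dnm < min_separation_nm) keep[b] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- NULL
  for (a in seq_len(nrow(cand))) {
    i <- cand[a, 1]; j <- cand[a, 2]; v <- cand[a, 3]
    comp <- vz_flood(sub >= v / 2, i, j)
    touches <- any(comp[1, ]) || any(comp[nr, ]) || any(comp[, 1]) || any(comp[, nc])
    if (touches) next  # continuous with the ROI edge: excluded
    idx <- which(comp, arr.ind = TRUE)
    w <- sub[comp]
    ci <- sum(idx[, 1] * w) / sum(w)
    cj <- sum(idx[, 2] * w) / sum(w)
    out <- rbind(out, data.frame(
      id = NA_integer_, channel = channel,
      x_nm = (cj + roi[2] - 1 - 0.5) * pixel_size_nm,
      y_nm = (ci + roi[1] - 1 - 0.5) * pixel_size_nm,
      peak_intensity = v,
      peak_row = i + roi[1] - 1L, peak_col = j + roi[2] - 1L))
  }
  if (is.null(out)) return(empty)
  out$id <- seq_len(nrow(out))
  class(out) <- c("punctum_set", "data.frame")
  out
}

#' Extract the half-intensity boundary contour around a peak
#'
#' Returns the iso-intensity contour at half the local peak intensity that
#' encloses the peak; when such contours are nested the innermost (smallest
#' area) one is returned.
#'
#' @param image numeric matrix.
#' @param peak either `c(row, col)` pixel indices of a detected maximum or a
#'   one-row `punctum_set`.
#' @param pixel_size_nm pixel size in nm.
#' @return object of class `boundary_contour`: list with `polygon_nm`
#'   (closed n x 2 matrix), `level`, `parent_peak_nm`.
#' @export
extract_boundary <- function(image, peak, pixel_size_nm) {
  if (!is.matrix(image) || length(image) == 0) vz_stop("empty image")
  vz_check_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  if (inherits(peak, "punctum_set")) peak <- c(peak$peak_row[1], peak$peak_col[1])
  i <- peak[1]; j <- peak[2]
  pv <- image[i, j]
  level <- pv / 2
  if (max(image) - min(image) < .Machine$double.eps * max(abs(image), 1) ||
      level <= min(image))
    vz_stop("no closed contour: level %g is below background everywhere", level)
  ynm <- (seq_len(nrow(image)) - 0.5) * pixel_size_nm
  xnm <- (seq_len(ncol(image)) - 0.5) * pixel_size_nm
  # contourLines treats x as the first matrix index (rows)
  cls <- grDevices::contourLines(x = ynm, y = xnm, z = image, levels = level)
  if (length(cls) == 0) vz_stop("no closed contour at half-maximum level")
  px_peak <- c((j - 0.5) * pixel_size_nm, (i - 0.5) * pixel_size_nm)
  best <- NULL; best_area <- Inf
  for (cl in cls) {
    poly <- cbind(x = cl$y, y = cl$x)
    closed <- isTRUE(all.equal(poly[1, ], poly[nrow(poly), ], tolerance = 1e-8))
    if (!closed) next
    if (!vz_point_in_polygon(px_peak[1], px_peak[2], poly)) next
    a <- vz_polygon_area(poly)
    if (a < best_area) { best <- poly; best_area <- a }
  }
  if (is.null(best)) vz_stop("no closed contour encloses the peak")
  structure(list(polygon_nm = best, level = level, parent_peak_nm = px_peak),
            class = "boundary_contour")
}

#' Fit the scaffold-bar midline along its long axis
#'
#' Thresholds the bar channel at half its maximum inside the ROI and takes
#' the principal axis of the resulting pixel mass. The midline is the major
#' axis clipped to the mass's extent. The width estimate is the full width
#' at half maximum of the transverse (minor-axis) intensity profile,
#' obtained by binning pixel intensities along the minor axis at pixel
#' resolution and interpolating the half-maximum crossings linearly (this
#' avoids the upward bias a binary pixel mask incurs from pixel
#' quantization). Near-isotropic masses (axis ratio < 1.2) trigger a
#' warning and a deterministic tie-break picking the axis with the larger
#' x-extent.
#'
#' @param bar_channel numeric matrix of the scaffold (e.g. Bassoon) channel.
#' @param pixel_size_nm pixel size in nm.
#' @param roi ROI box `c(row0, col0, row1, col1)`; default whole image.
#' @return object of class `midline`: list with `endpoints_nm` (2 x 2),
#'   `midpoint_nm`, `direction`, `width_estimate_nm`, `length_nm`.
#' @export
fit_midline <- function(bar_channel, pixel_size_nm, roi = NULL) {
  if (!is.matrix(bar_channel) || length(bar_channel) == 0) vz_stop("empty image")
  vz_check_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  if (is.null(roi)) roi <- c(1L, 1L, nrow(bar_channel), ncol(bar_channel))
  sub <- bar_channel[roi[1]:roi[3], roi[2]:roi[4], drop = FALSE]
  mx <- max(sub)
  if (mx <= 0 || mx == min(sub)) vz_stop("bar channel has no suprathreshold component in roi")
  mask <- sub >= mx / 2
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) vz_stop("bar channel has no suprathreshold component in roi")
  xs <- (idx[, 2] + roi[2] - 1 - 0.5) * pixel_size_nm
  ys <- (idx[, 1] + roi[1] - 1 - 0.5) * pixel_size_nm
  cx <- mean(xs); cy <- mean(ys)
  cov <- matrix(c(vz_pop_var(xs), mean((xs - cx) * (ys - cy)),
                  mean((xs - cx) * (ys - cy)), vz_pop_var(ys)), 2, 2)
  eg <- eigen(cov, symmetric = TRUE)
  v1 <- eg$vectors[, 1]; v2 <- eg$vectors[, 2]
  ratio <- sqrt(max(eg$values[1], 0) / max(eg$values[2], .Machine$double.eps))
  if (!is.finite(ratio) || ratio < 1.2) {
    warning("near-isotropic bar mass (axis ratio < 1.2); using x-extent tie-break")
    if (abs(v2[1]) > abs(v1[1])) { tmp <- v1; v1 <- v2; v2 <- tmp }
  }
  if (v1[1] < 0) v1 <- -v1  # deterministic orientation
  proj1 <- (xs - cx) * v1[1] + (ys - cy) * v1[2]
  e1 <- c(cx, cy) + min(proj1) * v1
  e2 <- c(cx, cy) + max(proj1) * v1
  width <- vz_transverse_fwhm(sub, roi, pixel_size_nm, c(cx, cy), v1, v2,
                              range(proj1))
  structure(list(endpoints_nm = rbind(e1, e2),
                 midpoint_nm = (e1 + e2) / 2,
                 direction = v1,
                 width_estimate_nm = width,
                 length_nm = max(proj1) - min(proj1)),
            class = "midline")
}

# FWHM of the transverse intensity profile of the bar: bin all ROI pixels
# lying within the bar's major-axis extent by their minor-axis coordinate
# (pixel-sized bins) and interpolate the half-maximum crossings.
vz_transverse_fwhm <- function(sub, roi, pixel_size_nm, center, v1, v2,
                               major_range) {
  idx <- which(sub > -Inf, arr.ind = TRUE)
  xs <- (idx[, 2] + roi[2] - 1 - 0.5) * pixel_size_nm
  ys <- (idx[, 1] + roi[1] - 1 - 0.5) * pixel_size_nm
  p1 <- (xs - center[1]) * v1[1] + (ys - center[2]) * v1[2]
  keep <- p1 >= major_range[1] & p1 <= major_range[2]
  p2 <- (xs - center[1]) * v2[1] + (ys - center[2]) * v2[2]
  bin <- round(p2[keep] / pixel_size_nm)
  prof <- tapply(as.numeric(sub)[keep], bin, mean)
  tpos <- as.numeric(names(prof)) * pixel_size_nm
  o <- order(tpos)
  tpos <- tpos[o]; prof <- as.numeric(prof[o])
  ipk <- which.max(prof)
  half <- prof[ipk] / 2
  cross <- function(side) {
    ids <- if (side < 0) rev(seq_len(ipk)) else ipk:length(prof)
    for (k in seq_along(ids)[-1]) {
      a <- ids[k - 1]; b <- ids[k]
      if (prof[b] < half) {
        frac <- (prof[a] - half) / (prof[a] - prof[b])
        return(tpos[a] + frac * (tpos[b] - tpos[a]))
      }
    }
    tpos[ids[length(ids)]]  # profile never drops below half on this side
  }
  abs(cross(+1) - cross(-1))
}

#' Quantify punctum distances to the midline, midpoint and boundary
#'
#' For each punctum: `d_midline_nm` is the perpendicular distance to the
#' midline's supporting line, `d_midpoint_nm` the Euclidean distance to the
#' midline midpoint, and (when a contour is supplied) `d_boundary_nm` the
#' signed Euclidean distance to the nearest contour point, negative inside
#' the contour.
#'
#' @param puncta a `punctum_set` (or data frame with `x_nm`, `y_nm`).
#' @param midline a [fit_midline()] result.
#' @param contour optional [extract_boundary()] result.
#' @return data frame of class `distance_records`: `punctum_id`, `channel`,
#'   `d_midline_nm`, `d_midpoint_nm`, `d_boundary_nm` (NA without contour).
#' @export
measure_distances <- function(puncta, midline, contour = NULL) {
  stopifnot(inherits(midline, "midline"))
  n <- nrow(puncta)
  dir <- midline$direction
  nrm <- c(-dir[2], dir[1])
  p0 <- midline$endpoints_nm[1, ]
  dml <- abs((puncta$x_nm - p0[1]) * nrm[1] + (puncta$y_nm - p0[2]) * nrm[2])
  dmp <- sqrt((puncta$x_nm - midline$midpoint_nm[1])^2 +
              (puncta$y_nm - midline$midpoint_nm[2])^2)
  dbd <- rep(NA_real_, n)
  if (!is.null(contour)) {
    poly <- contour$polygon_nm
    for (k in seq_len(n)) {
      d <- vz_point_polyline_distance(c(puncta$x_nm[k], puncta$y_nm[k]), poly)
      inside <- vz_point_in_polygon(puncta$x_nm[k], puncta$y_nm[k], poly)
      dbd[k] <- if (inside) -d else d
    }
  }
  out <- data.frame(punctum_id = if (!is.null(puncta$id)) puncta$id else seq_len(n),
                    channel = if (!is.null(puncta$channel)) puncta$channel else "puncta",
                    d_midline_nm = dml, d_midpoint_nm = dmp,
                    d_boundary_nm = dbd)
  class(out) <- c("distance_records", "data.frame")
  out
}

#' Fraction of puncta within the scaffold half-width window
#'
#' Fraction of puncta whose perpendicular midline distance is at most
#' `halfwidth_nm`. The default of 50 nm is half of the ~100 nm mean scaffold
#' bar width, i.e. the window in which a punctum falls "within" the bar
#' signal.
#'
#' @param records a `distance_records` data frame.
#' @param halfwidth_nm window half-width in nm (default 50).
#' @return scalar in \[0, 1\].
#' @export
fraction_within_window <- function(records, halfwidth_nm = 50) {
  vz_check_number(halfwidth_nm, "halfwidth_nm", positive = TRUE)
  if (is.null(records$d_midline_nm) || nrow(records) == 0)
    vz_stop("'records' must be a non-empty distance_records table")
  mean(records$d_midline_nm <= halfwidth_nm)
}

#' Half-width of the scaffold classification window from the bar width
#'
#' The classification window extends half the mean bar width out from the
#' midline at 0 nm; a ~100 nm bar yields the ~50 nm half-width.
#'
#' @param bar_width_nm mean scaffold bar width in nm.
#' @return half-width in nm.
#' @export
bassoon_window_halfwidth <- function(bar_width_nm) {
  vz_check_number(bar_width_nm, "bar_width_nm", positive = TRUE)
  bar_width_nm / 2
}
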