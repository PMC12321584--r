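# Internal helpers: argument checks, FFT convolution, planar geometry.

vz_stop <- function(...) stop(sprintf(...), call. = FALSE)

vz_check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    vz_stop("'%s' must be a single finite number", name)
  if (positive && x <= 0) vz_stop("'%s' must be > 0", name)
  if (nonneg && x < 0) vz_stop("'%s' must be >= 0", name)
  invisible(x)
}

vz_check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed < 0 || seed != floor(seed))
    vz_stop("'seed' must be a single non-negative integer")
  as.integer(seed %% .Machine$integer.max)
}

# Derive a stream-specific child seed; keeps everything below 2^31.
vz_child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

## ---- FFT convolution (circular) -------------------------------------------

# Embed a small odd-sized kernel into an image-sized array with its center at
# (1, 1), wrapping negative offsets; this makes FFT products implement
# circular convolution with the kernel centered.
vz_embed_kernel <- function(kern, nr, nc) {
  kh <- nrow(kern); kw <- ncol(kern)
  if (kh > nr || kw > nc) vz_stop("kernel larger than image")
  ch <- (kh + 1L) %/% 2L; cw <- (kw + 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (i in seq_len(kh)) {
    ii <- ((i - ch) %% nr) + 1L
    for (j in seq_len(kw)) {
      jj <- ((j - cw) %% nc) + 1L
      out[ii, jj] <- out[ii, jj] + kern[i, j]
    }
  }
  out
}

# Circular convolution of image with kernel (kernel given as small matrix).
vz_conv2 <- function(img, kern) {
  kf <- stats::fft(vz_embed_kernel(kern, nrow(img), ncol(img)))
  Re(stats::fft(stats::fft(img) * kf, inverse = TRUE)) / length(img)
}

# Circular correlation: out(x) = sum_u a(u) b(x + u) for image-sized a, b.
vz_corr2_full <- function(a, b) {
  Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    length(a)
}

# Extract the kernel-support window (centered at origin, wrapped) from an
# image-sized array; inverse of vz_embed_kernel's indexing.
vz_extract_kernel <- function(full, kh, kw) {
  nr <- nrow(full); nc <- ncol(full)
  ch <- (kh + 1L) %/% 2L; cw <- (kw + 1L) %/% 2L
  out <- matrix(0, kh, kw)
  for (i in seq_len(kh)) {
    ii <- ((i - ch) %% nr) + 1L
    for (j in seq_len(kw)) {
      jj <- ((j - cw) %% nc) + 1L
      out[i, j] <- full[ii, jj]
    }
  }
  out
}

# Normalized 2-D Gaussian kernel; sigma in pixels, support +/- 4 sigma.
vz_gaussian_kernel <- function(sigma) {
  h <- max(1L, ceiling(4 * sigma))
  x <- (-h):h
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

vz_fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## ---- Geometry --------------------------------------------------------------

# Distances from one point to each segment of a polyline.
# pts: n x 2 matrix of query points; poly: m x 2 polyline vertices.
# Returns vector of min distances, one per query point. Vectorized over
# segments for each point.
vz_point_polyline_distance <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  if (nrow(poly) < 1L) vz_stop("empty polyline")
  if (nrow(poly) == 1L) {
    return(sqrt((pts[, 1] - poly[1, 1])^2 + (pts[, 2] - poly[1, 2])^2))
  }
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
  len2 <- pmax(dx^2 + dy^2, .Machine$double.eps)
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1]; py <- pts[i, 2]
    t <- ((px - a[, 1]) * dx + (py - a[, 2]) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    qx <- a[, 1] + t * dx; qy <- a[, 2] + t * dy
    sqrt(min((px - qx)^2 + (py - qy)^2))
  }, numeric(1))
}

# Even-odd point-in-polygon test. poly need not repeat its first vertex.
vz_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (n >= 2L && all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- poly[i, 1] + (py - yi) / (yj - yi) * (poly[j, 1] - poly[i, 1])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Signed polygon area (shoelace); used for innermost-contour selection.
vz_polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n >= 2L && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Population variance (divides by n, not n - 1); the dispersion metrics and
# midline width use the population convention.
vz_pop_var <- function(x) mean((x - mean(x))^2)

vz_sem <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  stats::sd(x) / sqrt(n)
}
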