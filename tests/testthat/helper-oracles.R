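# Independent brute-force oracles used across test files. These must stay
# independent of the package's own geometry code paths.

# Min distance from point (px, py) to a polyline by dense sampling every
# `step` nm along each segment.
oracle_polyline_dist <- function(px, py, poly, step = 0.1) {
  best <- Inf
  for (k in seq_len(nrow(poly) - 1)) {
    a <- poly[k, ]; b <- poly[k + 1, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = n)
    xs <- a[1] + t * (b[1] - a[1]); ys <- a[2] + t * (b[2] - a[2])
    best <- min(best, sqrt(min((xs - px)^2 + (ys - py)^2)))
  }
  best
}

# Winding-number point-in-polygon (angle summation) -- deliberately a
# different algorithm from the package's even-odd crossing test.
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  dx <- poly[, 1] - px; dy <- poly[, 2] - py
  th <- atan2(dy, dx)
  dth <- diff(c(th, th[1]))
  dth <- ifelse(dth > pi, dth - 2 * pi, ifelse(dth < -pi, dth + 2 * pi, dth))
  abs(sum(dth)) > pi
}

# Random gently-bending polyline for geometry oracle tests.
random_polyline <- function(n_seg = 10, step_nm = 40) {
  ang <- cumsum(c(stats::runif(1, 0, 2 * pi),
                  stats::runif(n_seg - 1, -0.4, 0.4)))
  pts <- apply(rbind(c(0, 0), cbind(cos(ang), sin(ang)) * step_nm), 2, cumsum)
  pts
}
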