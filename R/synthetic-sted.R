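#' Configuration for a synthetic side-view STED scene
#'
#' Describes an idealized side-view synapse as imaged by 2D STED: a
#' presynaptic scaffold "bar" (the Bassoon-like active-zone signal, by default
#' 100 nm wide, matching the mean width reported for Bassoon STED signal), an
#' opposing postsynaptic bar, and point-like protein puncta placed at
#' controlled perpendicular offsets from the bar midline. The ideal scene is
#' convolved with an isotropic Gaussian PSF of known FWHM and corrupted with
#' Poisson photon noise.
#'
#' @param image_size_px integer pair, image height and width in pixels.
#' @param pixel_size_nm pixel size in nm (default 20, i.e. a 40 px ROI spans
#'   800 nm).
#' @param bar_length_nm,bar_width_nm bar dimensions in nm.
#' @param psf_fwhm_nm full width at half maximum of the Gaussian PSF in nm.
#' @param puncta_offsets_nm signed perpendicular punctum offsets from the bar
#'   midline in nm; positive points away from the postsynaptic side.
#' @param photon_scale expected photons at unit ideal intensity; `Inf`
#'   disables photon noise.
#' @param background_level uniform background in photons per pixel.
#' @return an object of class `sted_scene_config`.
#' @export
sted_scene_config <- function(image_size_px = c(64L, 64L),
                              pixel_size_nm = 20,
                              bar_length_nm = 400,
                              bar_width_nm = 100,
                              psf_fwhm_nm = 50,
                              puncta_offsets_nm = c(-30, 0, 40),
                              photon_scale = 1e4,
                              background_level = 2) {
  if (length(image_size_px) != 2L || any(image_size_px < 8))
    vz_stop("'image_size_px' must be two integers >= 8")
  vz_check_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  vz_check_number(bar_length_nm, "bar_length_nm", positive = TRUE)
  vz_check_number(bar_width_nm, "bar_width_nm", positive = TRUE)
  vz_check_number(psf_fwhm_nm, "psf_fwhm_nm", positive = TRUE)
  if (!is.numeric(photon_scale) || length(photon_scale) != 1L ||
      is.na(photon_scale) || photon_scale <= 0)
    vz_stop("'photon_scale' must be a single positive number (Inf allowed)")
  vz_check_number(background_level, "background_level", nonneg = TRUE)
  fov <- rev(image_size_px) * pixel_size_nm  # (x extent, y extent)
  if (bar_length_nm >= fov[1]) vz_stop("bar does not fit inside the image")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_nm = pixel_size_nm,
                 bar_length_nm = bar_length_nm,
                 bar_width_nm = bar_width_nm,
                 psf_fwhm_nm = psf_fwhm_nm,
                 puncta_offsets_nm = as.numeric(puncta_offsets_nm),
                 photon_scale = photon_scale,
                 background_level = background_level),
            class = "sted_scene_config")
}

# Bilinear splat of a subpixel point source onto a pixel grid; preserves the
# first moment so the blurred blob's centroid sits exactly at (x, y) nm.
# Coordinate convention: pixel (i, j) center at ((j - 0.5), (i - 0.5)) * px.
vz_splat <- function(img, x_nm, y_nm, px, amplitude = 1) {
  cj <- x_nm / px + 0.5  # fractional column index of the point
  ci <- y_nm / px + 0.5
  j0 <- floor(cj); i0 <- floor(ci)
  fj <- cj - j0; fi <- ci - i0
  for (di in 0:1) for (dj in 0:1) {
    i <- i0 + di; j <- j0 + dj
    if (i >= 1 && i <= nrow(img) && j >= 1 && j <= ncol(img)) {
      w <- (if (di == 0) 1 - fi else fi) * (if (dj == 0) 1 - fj else fj)
      img[i, j] <- img[i, j] + amplitude * w
    }
  }
  img
}

#' Generate a synthetic STED scene with planted ground truth
#'
#' Renders the ideal three-channel scene described by `config` (channels
#' `bar`, `puncta` and `psd`, the postsynaptic marker), convolves each channel
#' with the Gaussian PSF, scales to photons, adds uniform background and
#' applies Poisson noise (unless `photon_scale` is infinite). The returned
#' truth record carries the exact punctum coordinates and midline endpoints.
#'
#' @param config a [sted_scene_config()].
#' @param seed non-negative integer seed; the generator is a pure function of
#'   `(config, seed)`.
#' @return a list with elements `scene` (class `sted_scene`: named channel
#'   matrices, `pixel_size_nm`, `roi_boxes`) and `truth` (class
#'   `synthetic_truth`).
#' @export
gen_sted_scene <- function(config, seed) {
  stopifnot(inherits(config, "sted_scene_config"))
  seed <- vz_check_seed(seed)
  px <- config$pixel_size_nm
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  cx <- nc * px / 2; cy <- nr * px / 2

  # Bar: long axis horizontal through (cx, cy). Postsynapse sits at lower y,
  # so positive punctum offsets (away from the postsynapse) increase y.
  half_l <- config$bar_length_nm / 2
  half_w <- config$bar_width_nm / 2
  # Area-weighted rasterization: each pixel gets the fraction of its extent
  # covered by the bar, so the rendered bar width is exact, not quantized to
  # whole pixels.
  coverage <- function(centers, lo, hi) {
    pmax(pmin(centers + px / 2, hi) - pmax(centers - px / 2, lo), 0) / px
  }
  xc <- (seq_len(nc) - 0.5) * px
  yc <- (seq_len(nr) - 0.5) * px
  in_x <- coverage(xc, cx - half_l, cx + half_l)
  bar <- outer(coverage(yc, cy - half_w, cy + half_w), in_x)
  psd_cy <- cy - (half_w + 80)  # postsynaptic density bar 80 nm below the bar
  psd <- outer(coverage(yc, psd_cy - 35, psd_cy + 35), in_x)
  if (psd_cy - 35 < 0) vz_stop("bar does not fit inside the image vertically")

  offs <- config$puncta_offsets_nm
  pun <- matrix(0, nr, nc)
  n_off <- length(offs)
  # Spread puncta laterally along the bar, deterministically.
  if (n_off > 0) {
    xs <- cx + seq(-half_l * 0.6, half_l * 0.6, length.out = max(n_off, 2))[seq_len(n_off)]
    ys <- cy + offs
    for (k in seq_len(n_off)) {
      if (ys[k] < px || ys[k] > (nr - 1) * px || xs[k] < px || xs[k] > (nc - 1) * px)
        vz_stop("punctum offset %g nm places the punctum outside the image", offs[k])
      pun <- vz_splat(pun, xs[k], ys[k], px, amplitude = 1)
    }
  } else {
    xs <- numeric(0); ys <- numeric(0)
  }

  kern <- vz_gaussian_kernel(vz_fwhm_to_sigma(config$psf_fwhm_nm) / px)
  blur <- function(im) {
    out <- vz_conv2(im, kern)
    out[out < 0] <- 0
    out
  }
  ideal <- list(bar = blur(bar), puncta = blur(pun), psd = blur(psd))

  set.seed(seed)
  channels <- lapply(ideal, function(im) {
    if (is.infinite(config$photon_scale)) {
      im + config$background_level
    } else {
      lam <- im * config$photon_scale + config$background_level
      matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    }
  })

  roi <- c(1L, 1L, nr, nc)  # row0, col0, row1, col1 (whole image by default)
  scene <- structure(list(channels = channels, pixel_size_nm = px,
                          roi_boxes = list(roi)),
                     class = "sted_scene")
  truth <- structure(list(
    modality = "sted",
    puncta_nm = cbind(x = xs, y = ys),
    offsets_nm = offs,
    midline = list(endpoints = rbind(c(cx - half_l, cy), c(cx + half_l, cy)),
                   midpoint = c(cx, cy)),
    bar_width_nm = config$bar_width_nm,
    psf_fwhm_nm = config$psf_fwhm_nm), class = "synthetic_truth")
  list(scene = scene, truth = truth)
}
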