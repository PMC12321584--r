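#' Configuration for a synthetic EM annotation cohort
#'
#' Describes a cohort of annotated synaptic cross-sections: a gently curved
#' plasma-membrane polyline with a marked active-zone (AZ) sub-segment,
#' docked vesicles placed exactly tangent to the membrane (edge distance 0),
#' replacement-pool vesicles at edge distances drawn from a law supported on
#' (0, 20] nm, and reserve vesicles farther out. Per-profile counts are
#' Poisson with the configured means.
#'
#' Distance laws are descriptors `list(law = "uniform"|"exponential",
#' min =, max =, rate =)`; the default laws are uniform on their supports.
#'
#' @param n_profiles number of profiles to generate.
#' @param az_length_nm active-zone length along the membrane in nm.
#' @param docked_mean,replacement_mean,reserve_mean Poisson means of
#'   per-profile vesicle counts in each pool.
#' @param replacement_distance_law,reserve_distance_law distance-law
#'   descriptors (see Details).
#' @param vesicle_radius_nm vesicle radius in nm (default 20, i.e. 40 nm
#'   diameter vesicles).
#' @param pits_mean Poisson mean of per-profile pit count.
#' @param condition,timepoint labels stamped into every profile's `meta`.
#' @return object of class `em_cohort_config`.
#' @export
em_cohort_config <- function(n_profiles = 50L,
                             az_length_nm = 600,
                             docked_mean = 1.5,
                             replacement_mean = 1.8,
                             reserve_mean = 12,
                             replacement_distance_law = list(law = "uniform", min = 0.5, max = 20),
                             reserve_distance_law = list(law = "uniform", min = 20, max = 120),
                             vesicle_radius_nm = 20,
                             pits_mean = 0.3,
                             condition = "synthetic",
                             timepoint = "no-stim") {
  vz_check_number(n_profiles, "n_profiles", positive = TRUE)
  vz_check_number(az_length_nm, "az_length_nm", positive = TRUE)
  vz_check_number(docked_mean, "docked_mean", nonneg = TRUE)
  vz_check_number(replacement_mean, "replacement_mean", nonneg = TRUE)
  vz_check_number(reserve_mean, "reserve_mean", nonneg = TRUE)
  vz_check_number(vesicle_radius_nm, "vesicle_radius_nm", positive = TRUE)
  vz_check_number(pits_mean, "pits_mean", nonneg = TRUE)
  for (law in list(replacement_distance_law, reserve_distance_law))
    if (!is.list(law) || is.null(law$law)) vz_stop("invalid distance law descriptor")
  structure(list(n_profiles = as.integer(n_profiles),
                 az_length_nm = az_length_nm,
                 docked_mean = docked_mean,
                 replacement_mean = replacement_mean,
                 reserve_mean = reserve_mean,
                 replacement_distance_law = replacement_distance_law,
                 reserve_distance_law = reserve_distance_law,
                 vesicle_radius_nm = vesicle_radius_nm,
                 pits_mean = pits_mean,
                 condition = condition, timepoint = timepoint),
            class = "em_cohort_config")
}

vz_draw_distance <- function(law, n) {
  switch(law$law,
         uniform = stats::runif(n, law$min, law$max),
         exponential = law$min + stats::rexp(n, rate = if (is.null(law$rate)) 0.2 else law$rate),
         vz_stop("unknown distance law '%s'", law$law))
}

# Build one profile. The membrane is a circular arc of large radius bulging
# into the terminal, sampled every ~5 nm; anchoring each vesicle on the
# outward radial ray of an AZ vertex makes its minimum distance to the
# polyline *exactly* radius + planted edge distance (the nearest polyline
# point is the anchor vertex itself), so generator truth is exact.
vz_make_em_profile <- function(cfg, id) {
  R <- 1500
  margin <- 200
  half_s <- cfg$az_length_nm / 2 + margin
  ds <- 5
  s <- seq(-half_s, half_s, by = ds)
  th <- s / R
  ctr <- c(0, -R)
  memb <- cbind(x = R * sin(th), y = R * cos(th) - R)
  az_keep <- abs(s) <= cfg$az_length_nm / 2
  i0 <- which(az_keep)[1]
  i1 <- which(az_keep)[sum(az_keep)]
  az_range0 <- c(i0 - 1L, i1)  # 0-based half-open [i0-1, i1)

  r <- cfg$vesicle_radius_nm
  n_d <- stats::rpois(1, cfg$docked_mean)
  n_r <- stats::rpois(1, cfg$replacement_mean)
  n_s <- stats::rpois(1, cfg$reserve_mean)
  d_repl <- vz_draw_distance(cfg$replacement_distance_law, n_r)
  d_repl[d_repl <= 0] <- .Machine$double.eps
  d_res <- vz_draw_distance(cfg$reserve_distance_law, n_s)
  dists <- c(rep(0, n_d), d_repl, d_res)
  pool <- rep(c("docked", "replacement", "reserve"), c(n_d, n_r, n_s))

  az_anchors <- (i0 + 1L):(i1 - 1L)      # strictly interior AZ vertices
  all_anchors <- 2L:(nrow(memb) - 1L)    # reserve vesicles roam the bouton
  place_at <- function(vidx, d) {
    v <- memb[vidx, ]
    u <- (v - ctr) / sqrt(sum((v - ctr)^2))
    v + (r + d) * u
  }
  # Docked/replacement vesicles crowd the AZ shell, so random sequential
  # placement jams well below capacity. Instead the AZ is divided into
  # lateral slots one vesicle diameter (plus margin) wide; each vesicle gets
  # its own randomly assigned slot and is anchored at a membrane vertex in
  # the slot's central region, which guarantees pairwise center distances of
  # at least one diameter. Packing is infeasible only when the count truly
  # exceeds the slot capacity.
  near <- pool != "reserve"
  n_near <- sum(near)
  centers <- matrix(numeric(0), 0, 2)
  if (n_near > 0) {
    s_az <- s[az_anchors]
    span <- max(s_az) - min(s_az)
    ns <- max(1L, floor(span / (2 * r + 5)))
    if (n_near > ns)
      vz_stop("infeasible vesicle packing: %d AZ-proximal vesicles exceed the %d-slot capacity of a %g-nm active zone (profile %d)",
              n_near, ns, cfg$az_length_nm, id)
    W <- span / ns
    slots <- sample(ns, n_near)
    margin <- (W - 2 * r) / 2
    d_near <- dists[near]
    for (k in seq_len(n_near)) {
      cslot <- min(s_az) + (slots[k] - 0.5) * W
      cand <- az_anchors[abs(s_az - cslot) <= pmax(margin, ds / 2 + 1e-9)]
      vidx <- if (length(cand) > 0) cand[sample.int(length(cand), 1L)]
              else az_anchors[which.min(abs(s_az - cslot))]
      centers <- rbind(centers, place_at(vidx, d_near[k]))
    }
    if (n_near > 1) {
      dd <- as.matrix(stats::dist(centers))
      diag(dd) <- Inf
      if (min(dd) < 2 * r - 1e-9)
        vz_stop("infeasible vesicle packing in profile %d (slot collision)", id)
    }
  }
  # Reserve vesicles have the whole membrane and 20+ nm of depth: plain
  # rejection sampling with a 1000-retry cap.
  d_res_all <- dists[!near]
  for (k in seq_along(d_res_all)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      cen <- place_at(sample(all_anchors, 1L), d_res_all[k])
      if (nrow(centers) == 0 ||
          all((centers[, 1] - cen[1])^2 + (centers[, 2] - cen[2])^2 >= (2 * r)^2)) {
        centers <- rbind(centers, cen)
        ok <- TRUE
        break
      }
    }
    if (!ok) vz_stop("infeasible vesicle packing: could not place reserve vesicle %d of profile %d after 1000 retries", k, id)
  }
  # restore generation order: near-AZ vesicles first, then reserve
  dists <- c(dists[near], d_res_all)
  pool <- c(pool[near], pool[!near])

  n_p <- stats::rpois(1, cfg$pits_mean)
  pits <- NULL
  if (n_p > 0) {
    kinds <- sample(c("exocytic", "endocytic", "clathrin"), n_p, replace = TRUE)
    vtx <- sample(seq_len(nrow(memb)), n_p, replace = TRUE)
    pits <- data.frame(x = memb[vtx, 1], y = memb[vtx, 2], kind = kinds,
                       stringsAsFactors = FALSE)
    pits$in_az <- vtx >= i0 & vtx < (i1 + 1L) & vtx <= i1
  }

  vesicles <- if (length(dists) > 0)
    data.frame(x = centers[, 1], y = centers[, 2], r = r) else
    data.frame(x = numeric(0), y = numeric(0), r = numeric(0))

  profile <- structure(list(membrane = memb, az_range = az_range0,
                            vesicles = vesicles,
                            pits = if (is.null(pits)) data.frame(x = numeric(0), y = numeric(0), kind = character(0)) else pits[, c("x", "y", "kind")],
                            meta = list(condition = cfg$condition,
                                        timepoint = cfg$timepoint,
                                        section_thickness_nm = 40,
                                        id = id)),
                       class = "em_profile")
  truth <- list(docked = n_d, replacement = n_r, reserve = n_s,
                total = n_d + n_r + n_s,
                distances_nm = dists, pool = pool,
                pits_in_az = if (is.null(pits)) 0L else sum(pits$in_az),
                pits_total = n_p)
  list(profile = profile, truth = truth)
}

#' Generate a cohort of synthetic EM profiles with planted ground truth
#'
#' @param config an [em_cohort_config()].
#' @param seed non-negative integer seed.
#' @return list with `profiles` (list of `em_profile`) and `truth` (class
#'   `synthetic_truth`, holding per-profile counts and exact edge distances).
#' @export
gen_em_cohort <- function(config, seed) {
  stopifnot(inherits(config, "em_cohort_config"))
  seed <- vz_check_seed(seed)
  set.seed(seed)
  out <- lapply(seq_len(config$n_profiles), function(i) vz_make_em_profile(config, i))
  profiles <- lapply(out, `[[`, "profile")
  per <- lapply(out, `[[`, "truth")
  counts <- data.frame(profile = seq_along(per),
                       docked = vapply(per, `[[`, 0L, "docked"),
                       replacement = vapply(per, `[[`, 0L, "replacement"),
                       reserve = vapply(per, `[[`, 0L, "reserve"),
                       total = vapply(per, `[[`, 0L, "total"),
                       pits_in_az = vapply(per, function(p) as.integer(p$pits_in_az), 0L),
                       pits_total = vapply(per, function(p) as.integer(p$pits_total), 0L))
  truth <- structure(list(modality = "em", counts = counts,
                          distances_nm = lapply(per, `[[`, "distances_nm"),
                          pool = lapply(per, `[[`, "pool")),
                     class = "synthetic_truth")
  list(profiles = profiles, truth = truth)
}

## ---- annotation JSON I/O ---------------------------------------------------

#' Write / read EM annotation JSON
#'
#' One JSON file per micrograph with fields `pixel_size_nm`, `membrane`
#' (ordered vertex list, nm), `az_range` (0-based half-open index interval),
#' `vesicles` (`{x, y, r}`), `pits` (`{x, y, kind}`) and `meta`
#' (`condition`, `timepoint`). Coordinates are nm with y increasing into the
#' terminal.
#'
#' @param profile an `em_profile`.
#' @param path file path.
#' @return `write_em_annotation` returns `path` invisibly;
#'   `read_em_annotation` returns an `em_profile`.
#' @export
write_em_annotation <- function(profile, path) {
  stopifnot(inherits(profile, "em_profile"))
  obj <- list(pixel_size_nm = 1,
              membrane = unname(apply(profile$membrane, 1, function(v) c(v[1], v[2]), simplify = FALSE)),
              az_range = profile$az_range,
              vesicles = profile$vesicles,
              pits = profile$pits,
              meta = profile$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_em_annotation
#' @export
read_em_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("membrane", "az_range", "vesicles", "meta"))
    if (is.null(obj[[f]])) vz_stop("annotation %s missing field '%s'", path, f)
  memb <- obj$membrane
  if (is.list(memb)) memb <- do.call(rbind, lapply(memb, unlist))
  memb <- matrix(as.numeric(memb), ncol = 2,
                 dimnames = list(NULL, c("x", "y")))
  azr <- as.integer(obj$az_range)
  if (length(azr) != 2L || azr[1] < 0 || azr[2] > nrow(memb) || azr[1] >= azr[2])
    vz_stop("annotation %s has invalid az_range", path)
  ves <- as.data.frame(obj$vesicles)
  if (nrow(ves) > 0 && any(ves$r <= 0)) vz_stop("annotation %s has non-positive vesicle radius", path)
  pits <- if (is.null(obj$pits)) data.frame(x = numeric(0), y = numeric(0), kind = character(0)) else as.data.frame(obj$pits)
  structure(list(membrane = memb, az_range = azr, vesicles = ves, pits = pits,
                 meta = obj$meta), class = "em_profile")
}

# 1-based vertex indices of the active-zone sub-polyline.
vz_az_vertices <- function(profile) {
  (profile$az_range[1] + 1L):profile$az_range[2]
}
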