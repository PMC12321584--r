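#' Vesicle edge distance to the active-zone membrane
#'
#' Minimum Euclidean distance from a vesicle center to the active-zone
#' polyline minus the vesicle radius; negative values (annotations that
#' touch or overlap the membrane) are clamped to 0.
#'
#' @param center vesicle center `c(x, y)` in nm, or an n x 2 matrix.
#' @param radius vesicle radius in nm (scalar or length n).
#' @param az_polyline m x 2 matrix of active-zone vertices in nm.
#' @return edge distance(s) in nm, >= 0.
#' @export
edge_distance <- function(center, radius, az_polyline) {
  if (any(radius <= 0)) vz_stop("vesicle radius must be > 0")
  if (is.null(dim(az_polyline)) || nrow(az_polyline) == 0) vz_stop("empty polyline")
  d <- vz_point_polyline_distance(center, az_polyline) - radius
  pmax(d, 0)
}

#' Classify vesicles of a profile as docked / replacement-zone / outside
#'
#' Computes every vesicle's edge distance to the active-zone sub-polyline
#' (not the whole membrane). A vesicle is `docked` when its edge distance is
#' at most `docking_tol_nm` (vesicles touching the membrane; the small
#' positive tolerance absorbs tracing noise). An undocked vesicle is in the
#' replacement zone when its edge distance is at most 20 nm (closed upper
#' bound).
#'
#' @param profile an `em_profile`.
#' @param docking_tol_nm docking tolerance in nm (default 0.5).
#' @param replacement_zone_nm replacement-zone extent in nm (default 20).
#' @return data frame of class `vesicle_measures`: `vesicle`,
#'   `edge_distance_nm`, `status` (docked/undocked), `in_replacement_zone`.
#' @export
classify_vesicles <- function(profile, docking_tol_nm = 0.5,
                              replacement_zone_nm = 20) {
  stopifnot(inherits(profile, "em_profile"))
  vz_check_number(docking_tol_nm, "docking_tol_nm", nonneg = TRUE)
  az <- profile$membrane[vz_az_vertices(profile), , drop = FALSE]
  n <- nrow(profile$vesicles)
  if (n == 0) {
    out <- data.frame(vesicle = integer(0), edge_distance_nm = numeric(0),
                      status = character(0), in_replacement_zone = logical(0))
    class(out) <- c("vesicle_measures", "data.frame")
    return(out)
  }
  d <- edge_distance(cbind(profile$vesicles$x, profile$vesicles$y),
                     profile$vesicles$r, az)
  docked <- d <= docking_tol_nm
  out <- data.frame(vesicle = seq_len(n), edge_distance_nm = d,
                    status = ifelse(docked, "docked", "undocked"),
                    in_replacement_zone = !docked & d <= replacement_zone_nm)
  class(out) <- c("vesicle_measures", "data.frame")
  out
}

#' 2-nm binned relative-frequency histogram of undocked vesicle distances
#'
#' Counts undocked vesicles with edge distance in \[2, 50) nm into 24
#' half-open 2-nm bins \[2,4), ..., \[48,50) and normalizes by the total
#' number of vesicles in that range.
#'
#' @param measures a `vesicle_measures` table (possibly row-bound across
#'   profiles) or a numeric vector of undocked edge distances in nm.
#' @return object of class `distance_histogram`: list with `bin_edges_nm`
#'   (length 25), `counts`, `rel_freq`, `n_total`.
#' @export
distance_histogram <- function(measures) {
  if (is.data.frame(measures)) {
    d <- measures$edge_distance_nm[measures$status == "undocked"]
  } else d <- as.numeric(measures)
  edges <- seq(2, 50, by = 2)
  d <- d[d >= 2 & d < 50]
  n_total <- length(d)
  counts <- as.integer(table(cut(d, breaks = edges, right = FALSE,
                                 include.lowest = FALSE)))
  if (n_total == 0) {
    warning("no undocked vesicles in the 2-50 nm range; all-zero histogram")
    rel <- rep(0, 24)
  } else rel <- counts / n_total
  structure(list(bin_edges_nm = edges, counts = counts, rel_freq = rel,
                 n_total = n_total),
            class = "distance_histogram")
}

#' Count membrane pits by kind, inside and outside the active zone
#'
#' A pit belongs to the active zone when its nearest membrane vertex index
#' falls inside the profile's `az_range`.
#'
#' @param profile an `em_profile`.
#' @return data frame with columns `kind`, `in_az`, `outside_az`, `total`,
#'   one row per pit kind (exocytic, endocytic, clathrin).
#' @export
count_pits <- function(profile) {
  stopifnot(inherits(profile, "em_profile"))
  kinds <- c("exocytic", "endocytic", "clathrin")
  az_idx <- vz_az_vertices(profile)
  inaz <- outaz <- stats::setNames(rep(0L, 3), kinds)
  if (nrow(profile$pits) > 0) {
    for (k in seq_len(nrow(profile$pits))) {
      dx <- profile$membrane[, 1] - profile$pits$x[k]
      dy <- profile$membrane[, 2] - profile$pits$y[k]
      nearest <- which.min(dx^2 + dy^2)
      kk <- profile$pits$kind[k]
      if (!kk %in% kinds) vz_stop("unknown pit kind '%s'", kk)
      if (nearest %in% az_idx) inaz[kk] <- inaz[kk] + 1L else outaz[kk] <- outaz[kk] + 1L
    }
  }
  data.frame(kind = kinds, in_az = as.integer(inaz),
             outside_az = as.integer(outaz),
             total = as.integer(inaz + outaz), row.names = NULL)
}

#' Per-profile counts for one EM profile
#'
#' @param profile an `em_profile`.
#' @param docking_tol_nm docking tolerance passed to [classify_vesicles()].
#' @return one-row data frame: condition, timepoint, docked, replacement,
#'   undocked, total vesicles and pit counts.
#' @export
summarize_profile <- function(profile, docking_tol_nm = 0.5) {
  vm <- classify_vesicles(profile, docking_tol_nm)
  pits <- count_pits(profile)
  data.frame(condition = profile$meta$condition %||% "unknown",
             timepoint = profile$meta$timepoint %||% "unknown",
             docked = sum(vm$status == "docked"),
             replacement = sum(vm$in_replacement_zone),
             undocked = sum(vm$status == "undocked"),
             total = nrow(vm),
             pits = sum(pits$total),
             pits_in_az = sum(pits$in_az))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort summary: per-group mean, SEM and n of EM counts
#'
#' Groups per-profile counts by condition x timepoint and reports mean, SEM
#' and n for docked, replacement-zone, total vesicle and pit counts. SEM
#' with a single profile is reported as 0 and flagged via `n = 1`.
#'
#' @param profiles list of `em_profile` objects.
#' @param docking_tol_nm docking tolerance in nm.
#' @return list with `per_profile` (one row per profile) and `summary`
#'   (per-group mean/SEM/n for each metric).
#' @export
summarize_cohort <- function(profiles, docking_tol_nm = 0.5) {
  if (length(profiles) == 0) vz_stop("no profiles")
  per <- do.call(rbind, lapply(profiles, summarize_profile,
                               docking_tol_nm = docking_tol_nm))
  per$profile <- seq_len(nrow(per))
  metrics <- c("docked", "replacement", "undocked", "total", "pits", "pits_in_az")
  grp <- interaction(per$condition, per$timepoint, drop = TRUE, sep = " / ")
  rows <- list()
  for (g in levels(grp)) {
    sel <- per[grp == g, , drop = FALSE]
    for (m in metrics) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, mean = mean(sel[[m]]),
        sem = vz_sem(sel[[m]]), n = nrow(sel))
    }
  }
  list(per_profile = per, summary = do.call(rbind, rows))
}
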