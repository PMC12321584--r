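# Pipeline orchestration: config validation, stage execution, manifest and
# fixture generation. Images travel as one CSV matrix per channel plus a JSON
# metadata sidecar (no binary formats); traces/trains as CSV; annotations and
# truth records as JSON.

vz_stage_order <- c("simulate_sted", "simulate_em", "simulate_traces",
                    "simulate_frap", "simulate_train", "simulate_axon",
                    "analyze_sted", "analyze_em", "analyze_traces",
                    "analyze_frap", "analyze_train", "analyze_cv", "report")

#' Read / write a pipeline run configuration
#'
#' Configurations are JSON (always supported) or YAML (when the `yaml`
#' package is installed). Top-level keys: `seed` (required for simulate
#' stages), `outdir`, `stages` (named list of per-stage parameter blocks),
#' `log_level`. Unknown keys are rejected before any computation.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) vz_stop("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      vz_stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  vz_validate_config(cfg)
  cfg
}

vz_validate_config <- function(config) {
  allowed <- c("seed", "outdir", "stages", "log_level")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    vz_stop("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(config$stages) || length(config$stages) == 0)
    vz_stop("config must name at least one stage")
  bad <- setdiff(names(config$stages), vz_stage_order)
  if (length(bad))
    vz_stop("unknown stage(s): %s", paste(bad, collapse = ", "))
  sims <- grep("^simulate_", names(config$stages), value = TRUE)
  if (length(sims) && is.null(config$seed))
    vz_stop("simulate stages require an explicit 'seed'")
  invisible(config)
}

vz_write_image_csv <- function(mat, path) {
  utils::write.table(mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

vz_read_image_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write / read a scene as plain-text files
#'
#' One CSV matrix per channel (`<stem>_<channel>.csv`) plus
#' `<stem>_meta.json` with `pixel_size_nm` and channel names.
#'
#' @param scene a `sted_scene`.
#' @param stem path stem (no extension).
#' @return `write_sted_scene` returns the files written; `read_sted_scene`
#'   a `sted_scene`.
#' @export
write_sted_scene <- function(scene, stem) {
  files <- character(0)
  for (ch in names(scene$channels)) {
    p <- paste0(stem, "_", ch, ".csv")
    vz_write_image_csv(scene$channels[[ch]], p)
    files <- c(files, p)
  }
  meta <- paste0(stem, "_meta.json")
  jsonlite::write_json(list(pixel_size_nm = scene$pixel_size_nm,
                            channels = names(scene$channels)),
                       meta, auto_unbox = TRUE, digits = NA)
  c(files, meta)
}

#' @rdname write_sted_scene
#' @export
read_sted_scene <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  channels <- lapply(meta$channels, function(ch)
    vz_read_image_csv(paste0(stem, "_", ch, ".csv")))
  names(channels) <- meta$channels
  structure(list(channels = channels, pixel_size_nm = meta$pixel_size_nm,
                 roi_boxes = list(c(1L, 1L, dim(channels[[1]])))),
            class = "sted_scene")
}

vz_write_trace_csv <- function(time, value, path,
                               names = c("time_ms", "value")) {
  df <- data.frame(a = time, b = value)
  names(df) <- names
  utils::write.csv(df, path, row.names = FALSE)
}

vz_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Execute a pipeline run
#'
#' Validates the configuration, executes the requested stages in canonical
#' dependency order (all simulate stages, then analyze stages, then report),
#' writes each stage's outputs under `outdir/<stage>/` and finishes with a
#' JSON manifest holding the config hash, seed, package version and an md5
#' digest of every file written. Re-running an identical config + seed
#' reproduces identical digests.
#'
#' @param config config list (see [read_run_config()]) or a path to a
#'   config file.
#' @return the manifest, invisibly; also written to
#'   `outdir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  vz_validate_config(config)
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) vz_check_seed(config$seed) else 0L
  stages <- intersect(vz_stage_order, names(config$stages))
  files <- character(0)
  state <- new.env(parent = emptyenv())
  for (st in stages) {
    params <- config$stages[[st]]
    if (isTRUE(params)) params <- list()
    sdir <- file.path(outdir, st)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    vz_log(st, "running")
    files <- c(files, vz_run_stage(st, params, sdir, seed, state))
  }
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = seed,
                   version = as.character(utils::packageVersion("vesiclezone")),
                   files = as.list(tools::md5sum(sort(files))))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

vz_apply_config <- function(ctor, params) {
  keep <- intersect(names(params), names(formals(ctor)))
  bad <- setdiff(names(params), c(names(formals(ctor)), "input"))
  if (length(bad)) vz_stop("unknown stage parameter(s): %s", paste(bad, collapse = ", "))
  do.call(ctor, params[keep])
}

vz_run_stage <- function(stage, params, sdir, seed, state) {
  switch(stage,
    simulate_sted = {
      g <- gen_sted_scene(vz_apply_config(sted_scene_config, params),
                          vz_child_seed(seed, 1))
      state$sted <- g
      f <- write_sted_scene(g$scene, file.path(sdir, "scene"))
      tf <- file.path(sdir, "truth.json")
      jsonlite::write_json(list(offsets_nm = g$truth$offsets_nm,
                                puncta_nm = as.data.frame(g$truth$puncta_nm),
                                bar_width_nm = g$truth$bar_width_nm),
                           tf, auto_unbox = TRUE, digits = NA)
      c(f, tf)
    },
    simulate_em = {
      g <- gen_em_cohort(vz_apply_config(em_cohort_config, params),
                         vz_child_seed(seed, 2))
      state$em <- g
      f <- vapply(seq_along(g$profiles), function(i)
        write_em_annotation(g$profiles[[i]],
                            file.path(sdir, sprintf("profile_%03d.json", i))),
        character(1))
      tf <- file.path(sdir, "truth.json")
      jsonlite::write_json(g$truth$counts, tf, digits = NA)
      c(f, tf)
    },
    simulate_traces = {
      g <- gen_dff_trace(vz_apply_config(trace_config, params),
                         vz_child_seed(seed, 3))
      state$trace <- g
      f1 <- file.path(sdir, "trace.csv")
      vz_write_trace_csv(g$trace$time_ms, g$trace$intensity, f1)
      f2 <- file.path(sdir, "stims.json")
      jsonlite::write_json(list(stim_times_ms = g$trace$stim_times_ms,
                                amp1 = g$truth$amp1, ppr_true = g$truth$ppr_true),
                           f2, auto_unbox = TRUE, digits = NA)
      c(f1, f2)
    },
    simulate_frap = {
      g <- gen_frap_curve(vz_apply_config(frap_config, params),
                          vz_child_seed(seed, 4))
      state$frap <- g
      f <- file.path(sdir, "frap.csv")
      utils::write.csv(as.data.frame(g$curve), f, row.names = FALSE)
      tf <- file.path(sdir, "truth.json")
      jsonlite::write_json(list(tau_s = g$truth$tau_s,
                                mobile_fraction = g$truth$mobile_fraction,
                                prebleach_frames = attr(g$curve, "prebleach_frames")),
                           tf, auto_unbox = TRUE, digits = NA)
      c(f, tf)
    },
    simulate_train = {
      g <- gen_train(vz_apply_config(train_config, params),
                     vz_child_seed(seed, 5))
      state$train <- g
      f1 <- file.path(sdir, "train.csv")
      vz_write_trace_csv(seq_along(g$record$amplitudes),
                         g$record$amplitudes, f1,
                         names = c("pulse_index", "amplitude"))
      f2 <- file.path(sdir, "recovery.csv")
      utils::write.csv(g$record$recovery, f2, row.names = FALSE)
      tf <- file.path(sdir, "truth.json")
      jsonlite::write_json(list(rrp_true = g$truth$rrp_true,
                                p_release = g$truth$p_release,
                                first_amplitude = g$truth$first_amplitude),
                           tf, auto_unbox = TRUE, digits = NA)
      c(f1, f2, tf)
    },
    simulate_axon = {
      g <- do.call(gen_axon_profile, c(
        list(n_condensates = params$n_condensates %||% 8,
             bump_amplitude = params$bump_amplitude %||% 5,
             baseline = params$baseline %||% 10,
             noise_sd = params$noise_sd %||% 0.2,
             seed = vz_child_seed(seed, 6))))
      state$axon <- g
      f <- file.path(sdir, "profiles.csv")
      utils::write.csv(data.frame(px = seq_along(g$punctate),
                                  punctate = g$punctate,
                                  dispersed = g$dispersed),
                       f, row.names = FALSE)
      f
    },
    analyze_sted = {
      stem <- params$input %||% file.path(dirname(sdir), "simulate_sted", "scene")
      scene <- read_sted_scene(stem)
      px <- scene$pixel_size_nm
      pre <- preblur(scene$channels$puncta)
      psf0 <- vz_gaussian_kernel(2)
      dec <- blind_deconvolve(pre, psf0)$image
      ml <- fit_midline(scene$channels$bar, px)
      pts <- detect_puncta(dec, px)
      recs <- measure_distances(pts, ml)
      f1 <- file.path(sdir, "distances.csv")
      utils::write.csv(as.data.frame(recs), f1, row.names = FALSE)
      f2 <- file.path(sdir, "midline.json")
      jsonlite::write_json(list(endpoints_nm = ml$endpoints_nm,
                                midpoint_nm = ml$midpoint_nm,
                                width_estimate_nm = ml$width_estimate_nm),
                           f2, digits = NA)
      c(f1, f2)
    },
    analyze_em = {
      indir <- params$input %||% file.path(dirname(sdir), "simulate_em")
      paths <- sort(list.files(indir, pattern = "^profile_.*\\.json$",
                               full.names = TRUE))
      if (length(paths) == 0) vz_stop("analyze_em: no annotation files in %s", indir)
      profiles <- lapply(paths, read_em_annotation)
      cs <- summarize_cohort(profiles, params$docking_tol_nm %||% 0.5)
      f1 <- file.path(sdir, "per_profile.csv")
      utils::write.csv(cs$per_profile, f1, row.names = FALSE)
      f2 <- file.path(sdir, "summary.csv")
      utils::write.csv(cs$summary, f2, row.names = FALSE)
      vm <- do.call(rbind, lapply(profiles, classify_vesicles))
      h <- suppressWarnings(distance_histogram(vm))
      f3 <- file.path(sdir, "histogram.csv")
      utils::write.csv(data.frame(bin_lo_nm = h$bin_edges_nm[-25],
                                  bin_hi_nm = h$bin_edges_nm[-1],
                                  rel_freq = h$rel_freq),
                       f3, row.names = FALSE)
      state$em_summary <- cs
      c(f1, f2, f3)
    },
    analyze_traces = {
      indir <- params$input %||% file.path(dirname(sdir), "simulate_traces")
      tr <- utils::read.csv(file.path(indir, "trace.csv"))
      meta <- jsonlite::read_json(file.path(indir, "stims.json"),
                                  simplifyVector = TRUE)
      raw <- structure(list(time_ms = tr$time_ms, intensity = tr$value,
                            stim_times_ms = meta$stim_times_ms),
                       class = "raw_trace")
      dff <- compute_dff(raw)
      pk <- extract_peaks(dff)
      intv <- diff(meta$stim_times_ms[1:2])
      ppr <- compute_ppr(pk, intv)
      f1 <- file.path(sdir, "peaks.csv")
      utils::write.csv(as.data.frame(pk), f1, row.names = FALSE)
      f2 <- file.path(sdir, "ppr.csv")
      utils::write.csv(as.data.frame(ppr), f2, row.names = FALSE)
      c(f1, f2)
    },
    analyze_frap = {
      indir <- params$input %||% file.path(dirname(sdir), "simulate_frap")
      cu <- utils::read.csv(file.path(indir, "frap.csv"))
      fit <- fit_frap(cu)
      f <- file.path(sdir, "frap_fit.json")
      jsonlite::write_json(list(tau_s = fit$tau_s,
                                mobile_fraction = fit$mobile_fraction,
                                identifiable = fit$identifiable),
                           f, auto_unbox = TRUE, digits = NA)
      f
    },
    analyze_train = {
      indir <- params$input %||% file.path(dirname(sdir), "simulate_train")
      tr <- utils::read.csv(file.path(indir, "train.csv"))
      rec_path <- file.path(indir, "recovery.csv")
      record <- structure(list(amplitudes = tr$amplitude,
                               rate_hz = params$rate_hz %||% 20,
                               n_pulses = nrow(tr),
                               recovery = if (file.exists(rec_path))
                                 utils::read.csv(rec_path) else NULL),
                          class = "train_record")
      nt <- normalize_train(record)
      est <- backextrapolate_rrp(nt, params$tail_points %||% 20L)
      out <- list(rrp_intercept = est$intercept, slope = est$slope,
                  r_squared = est$r_squared,
                  first_ten = window_average(nt, "first_ten"),
                  last_ten = window_average(nt, "last_ten"))
      if (!is.null(record$recovery)) {
        rc <- recovery_curve(record, record$amplitudes[1])
        out$tau_rec_ms <- attr(rc, "tau_rec_ms")
      }
      f <- file.path(sdir, "train_analysis.json")
      jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
      f
    },
    analyze_cv = {
      indir <- params$input %||% file.path(dirname(sdir), "simulate_axon")
      pr <- utils::read.csv(file.path(indir, "profiles.csv"))
      cvs <- c(punctate = compute_cv(pr$punctate),
               dispersed = compute_cv(pr$dispersed))
      f <- file.path(sdir, "cv.csv")
      utils::write.csv(data.frame(variant = names(cvs), raw_cv = unname(cvs),
                                  normalized_cv = normalize_cv(unname(cvs))$normalized_cv),
                       f, row.names = FALSE)
      f
    },
    report = {
      metrics <- list()
      if (!is.null(state$em_summary)) {
        pp <- state$em_summary$per_profile
        metrics$docked <- data.frame(group = pp$condition, value = pp$docked)
        metrics$replacement <- data.frame(group = pp$condition,
                                          value = pp$replacement)
      }
      if (length(metrics) == 0) {
        message("[report] nothing to report; panel skipped")
        character(0)
      } else {
        render_report(metrics, sdir, svg = isTRUE(params$svg))
      }
    },
    vz_stop("unknown stage '%s'", stage))
}

#' Generate the small fixture set used by the test suite
#'
#' One dataset per modality (STED scene, EM cohort, sensor trace, FRAP
#' curve, fEPSP train, axonal profile), written as plain-text files.
#' Regeneration with the same seed is byte-identical.
#'
#' @param seed non-negative integer seed.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(seed, dir = tempfile("fixtures")) {
  cfg <- list(seed = vz_check_seed(seed), outdir = dir,
              stages = list(
                simulate_sted = list(image_size_px = c(48L, 48L)),
                simulate_em = list(n_profiles = 5L),
                simulate_traces = list(),
                simulate_frap = list(),
                simulate_train = list(),
                simulate_axon = list()))
  run_pipeline(cfg)
  invisible(dir)
}
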