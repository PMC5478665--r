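#' Default end-to-end pipeline configuration
#'
#' Bundles every stage's parameters: acquisition (1 frame/s for 120 s,
#' 0.16 um/px), optics, the per-group motility profiles (a control profile
#' and the built-in "asyn"-like deficit profile with 10 and 20 tracks,
#' mirroring typical control/transgenic group sizes), tracing thresholds,
#' angle cut-offs and size bins.
#'
#' @param seed Integer master seed.
#' @return A named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    acq = acquisition_config(),
    optics = optics_config(),
    groups = list(control = transport_params(),
                  asyn = asyn_like_params()),
    n_tracks = c(control = 10, asyn = 20),
    render_movies = TRUE,
    sampling_step = 1,
    line_width = 5,
    reducer = "max",
    tracing = list(min_snr = 3, max_jump = 2, max_gap = 3,
                   min_track_len = 10, delta = 0.1),
    distance_mode = "path",
    cutoffs = angle_cutoffs(),
    bins = size_bins()),
    class = "pipeline_config")
}

config_hash <- function(config) {
  text_hash(paste(deparse(unclass(config)), collapse = ""))
}

pipeline_scalar_keys <- c(
  "seed", "frame_interval", "duration", "pixel_size", "psf_sigma",
  "amplitude", "background", "noise", "image_height", "render_movies",
  "sampling_step", "line_width", "reducer", "min_snr", "max_jump",
  "max_gap", "min_track_len", "delta", "distance_mode", "groups",
  "n_tracks", "bin_edges")

#' Read a pipeline configuration from a flat key=value text file
#'
#' Scalar keys (`seed`, `frame_interval`, `duration`, `pixel_size`,
#' `psf_sigma`, `amplitude`, `background`, `noise`, `image_height`,
#' `render_movies`, `sampling_step`, `line_width`, `reducer`, `min_snr`,
#' `max_jump`, `max_gap`, `min_track_len`, `delta`, `distance_mode`,
#' `bin_edges`) plus `groups` / `n_tracks` (comma-separated, aligned) and
#' per-group motility parameters as `<group>.<param>` (e.g.
#' `asyn.v_retro=0.635`). Unknown keys are rejected by name; values not
#' given keep the defaults of [default_pipeline_config()].
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  kv <- read_keyvalue(path)
  cfg <- default_pipeline_config()
  num <- function(key) as.numeric(kv[[key]])

  group_names <- if (!is.null(kv[["groups"]])) {
    trimws(strsplit(kv[["groups"]], ",")[[1]])
  } else names(cfg$groups)
  param_names <- names(transport_params())
  for (key in names(kv)) {
    if (grepl(".", key, fixed = TRUE)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2 || !parts[1] %in% group_names ||
          !parts[2] %in% param_names) {
        stop("unknown configuration key: ", key, call. = FALSE)
      }
    } else if (!key %in% pipeline_scalar_keys) {
      stop("unknown configuration key: ", key, call. = FALSE)
    }
  }

  if (!is.null(kv[["seed"]])) cfg$seed <- as.integer(num("seed"))
  acq_args <- list(frame_interval = cfg$acq$frame_interval,
                   duration = cfg$acq$duration,
                   pixel_size = cfg$acq$pixel_size)
  for (k in names(acq_args)) if (!is.null(kv[[k]])) acq_args[[k]] <- num(k)
  cfg$acq <- do.call(acquisition_config, acq_args)
  opt_args <- list(psf_sigma = cfg$optics$psf_sigma,
                   amplitude = cfg$optics$amplitude,
                   background = cfg$optics$background,
                   noise = cfg$optics$noise,
                   image_height = cfg$optics$image_height)
  for (k in setdiff(names(opt_args), "noise")) {
    if (!is.null(kv[[k]])) opt_args[[k]] <- num(k)
  }
  if (!is.null(kv[["noise"]])) opt_args$noise <- kv[["noise"]]
  cfg$optics <- do.call(optics_config, opt_args)

  defaults <- transport_params()
  cfg$groups <- stats::setNames(lapply(group_names, function(g) {
    base <- if (g %in% names(cfg$groups)) cfg$groups[[g]] else defaults
    args <- unclass(base)
    for (p in param_names) {
      key <- paste0(g, ".", p)
      if (!is.null(kv[[key]])) args[[p]] <- as.numeric(kv[[key]])
    }
    do.call(transport_params, args)
  }), group_names)
  if (!is.null(kv[["n_tracks"]])) {
    n <- as.numeric(trimws(strsplit(kv[["n_tracks"]], ",")[[1]]))
    if (length(n) == 1) n <- rep(n, length(group_names))
    if (length(n) != length(group_names)) {
      stop("'n_tracks' must have one entry, or one per group",
           call. = FALSE)
    }
    cfg$n_tracks <- stats::setNames(n, group_names)
  } else {
    cfg$n_tracks <- stats::setNames(
      ifelse(group_names %in% names(cfg$n_tracks),
             cfg$n_tracks[group_names], 10), group_names)
  }
  for (k in c("render_movies")) {
    if (!is.null(kv[[k]])) cfg[[k]] <- tolower(kv[[k]]) %in% c("true", "1", "yes")
  }
  for (k in c("sampling_step", "line_width")) {
    if (!is.null(kv[[k]])) cfg[[k]] <- num(k)
  }
  if (!is.null(kv[["reducer"]])) cfg$reducer <- kv[["reducer"]]
  for (k in c("min_snr", "max_jump", "max_gap", "min_track_len", "delta")) {
    if (!is.null(kv[[k]])) cfg$tracing[[k]] <- num(k)
  }
  if (!is.null(kv[["distance_mode"]])) cfg$distance_mode <- kv[["distance_mode"]]
  if (!is.null(kv[["bin_edges"]])) {
    cfg$bins <- size_bins(as.numeric(trimws(strsplit(kv[["bin_edges"]],
                                                     ",")[[1]])))
  }
  cfg
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir)) {
    if (!force && length(list.files(out_dir))) {
      stop("output directory exists and is not empty: ", out_dir,
           " (use force = TRUE to overwrite)", call. = FALSE)
    }
  } else {
    dir.create(out_dir, recursive = TRUE)
  }
  invisible(out_dir)
}

#' Simulate a cohort and write trajectories (and movies) to disk
#'
#' One movie per simulated neuron/track, rendered on a straight axon path,
#' plus the ground-truth track table (`trajectories.csv`) and a manifest
#' recording seed, config hash and package version.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty existing directory?
#' @return Invisibly, a list with the cohort and the written file paths.
#' @export
cmd_simulate <- function(config = default_pipeline_config(), out_dir,
                         force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  prepare_out_dir(out_dir, force)
  spec <- cohort_spec(config$groups, config$n_tracks, seed = config$seed)
  cohort <- simulate_cohort(spec, config$acq)
  traj_csv <- file.path(out_dir, "trajectories.csv")
  write_trajectories(cohort, traj_csv)
  movie_files <- character(0)
  if (isTRUE(config$render_movies)) {
    for (tr in cohort$trajectories) {
      path <- straight_axon_path(tr$params$axon_length,
                                 config$acq$pixel_size,
                                 y = (config$optics$image_height + 1) / 2,
                                 sampling_step = config$sampling_step,
                                 width = config$line_width)
      stack <- render_stack(tr, path, config$acq, config$optics,
                            seed = derive_seed(config$seed, "render",
                                               tr$track_id))
      f <- file.path(out_dir, paste0(tr$track_id, ".tif"))
      write_stack(stack, f, extra_meta = list(
        group = tr$group, track_id = tr$track_id,
        axon_y = (config$optics$image_height + 1) / 2,
        axon_x0 = path$vertices[1, 1], axon_x1 = path$vertices[2, 1]))
      movie_files <- c(movie_files, f)
    }
  }
  write_keyvalue(list(seed = config$seed,
                      config_hash = config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("kymoquant")),
                      n_movies = length(movie_files)),
                 file.path(out_dir, "manifest.txt"))
  invisible(list(cohort = cohort, trajectories_csv = traj_csv,
                 movies = movie_files))
}

stack_analysis_path <- function(stack, config) {
  h <- nrow(stack$frames[[1]])
  w <- ncol(stack$frames[[1]])
  meta <- stack$meta %||% list()
  if (!is.null(meta$axon_x0)) {
    axon_path(rbind(c(as.numeric(meta$axon_x0), as.numeric(meta$axon_y)),
                    c(as.numeric(meta$axon_x1), as.numeric(meta$axon_y))),
              sampling_step = config$sampling_step,
              width = config$line_width)
  } else {
    m <- (config$line_width + 1) / 2 + 1
    axon_path(rbind(c(m, (h + 1) / 2), c(w - m, (h + 1) / 2)),
              sampling_step = config$sampling_step,
              width = config$line_width)
  }
}

#' Analyze movies (or a track table) into per-track transport metrics
#'
#' The kymograph -> trace -> metrics chain. With `from_tracks = TRUE`, the
#' imaging stages are skipped and metrics are computed directly from a
#' track table (e.g. `trajectories.csv` from [cmd_simulate()]), which
#' yields identical metrics for identical track tables. With stacks, each
#' movie is read (hard error if uncalibrated), a kymograph is built and
#' written, tracks are traced and segmented, and per-track metrics are
#' accumulated; a corrupted file is reported and skipped while the
#' remaining files are still processed.
#'
#' @param input Directory containing `*.tif` stacks, a vector of stack
#'   paths, or (with `from_tracks = TRUE`) a track-table CSV path.
#' @param config A `pipeline_config`.
#' @param out_dir Optional output directory for kymographs and CSVs.
#' @param from_tracks Skip the imaging stages?
#' @return A list with `metrics` (per-track data frame), `tracks`, and
#'   `failed` (character vector of unreadable inputs).
#' @export
cmd_analyze <- function(input, config = default_pipeline_config(),
                        out_dir = NULL, from_tracks = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) prepare_out_dir(out_dir, force = TRUE)
  tr_cfg <- config$tracing
  failed <- character(0)

  if (from_tracks) {
    df <- read_trajectories(input)
    tracks <- lapply(split(df, df$track_id), function(d) {
      d <- d[order(d$frame), ]
      rs <- if (nrow(d) > 1) d$time_s[2] - d$time_s[1] else 1
      cargo_track(frame = d$frame, position_um = d$position_um,
                  row_scale = rs, track_id = d$track_id[1],
                  group = d$group[1])
    })
  } else {
    files <- if (length(input) == 1 && dir.exists(input)) {
      list.files(input, pattern = "\\.tiff?$", full.names = TRUE)
    } else input
    if (!length(files)) stop("no TIFF stacks found in ", input, call. = FALSE)
    tracks <- list()
    for (f in files) {
      res <- tryCatch({
        stack <- read_stack(f)
        path <- stack_analysis_path(stack, config)
        kymo <- build_kymograph(stack, path, reducer = config$reducer)
        if (!is.null(out_dir)) {
          write_kymograph(kymo, file.path(out_dir, paste0(
            sub("\\.tiff?$", "", basename(f)), "_kymo.tif")))
        }
        dets <- detect_per_frame(kymo, min_snr = tr_cfg$min_snr)
        tks <- link_tracks(dets, kymo, max_jump = tr_cfg$max_jump,
                           max_gap = tr_cfg$max_gap,
                           min_track_len = tr_cfg$min_track_len)
        grp <- (stack$meta %||% list())$group %||% NA_character_
        tid <- (stack$meta %||% list())$track_id
        for (i in seq_along(tks)) {
          tks[[i]]$group <- grp
          tks[[i]]$track_id <- if (!is.null(tid) && length(tks) == 1) tid
            else paste0(sub("\\.tiff?$", "", basename(f)), "_", i)
        }
        tks
      }, error = function(e) {
        warning("failed to analyze ", f, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(res)) failed <- c(failed, f) else tracks <- c(tracks, res)
    }
  }
  if (!length(tracks)) stop("no tracks recovered from input", call. = FALSE)
  metrics <- analyze_tracks(tracks, delta = tr_cfg$delta,
                            distance_mode = config$distance_mode)
  if (!is.null(out_dir)) {
    write_csv_prov(metrics, file.path(out_dir, "metrics.csv"),
                   provenance = list(config_hash = config_hash(config),
                                     seed = config$seed,
                                     delta = tr_cfg$delta,
                                     retro_band = c(config$cutoffs$retro_lo,
                                                    config$cutoffs$retro_hi)))
  }
  list(metrics = metrics, tracks = tracks, failed = failed)
}

#' Compare transport metrics between groups
#'
#' Runs the statistics layer on moving velocity, average velocity and pause
#' percentage: a pooled Student t test for two groups, one-way ANOVA with
#' Bonferroni post test for three or more.
#'
#' @param metrics Per-track metrics data frame (or CSV path) with a `group`
#'   column.
#' @param control Name of the control group.
#' @param out_dir Optional directory for the report files.
#' @return A list, one entry per metric, each with `summary` (from
#'   [summarize_groups()]) and `test`.
#' @export
cmd_compare <- function(metrics, control, out_dir = NULL) {
  if (is.character(metrics)) metrics <- read_csv_prov(metrics)
  stopifnot(is.data.frame(metrics), "group" %in% names(metrics))
  groups_present <- unique(metrics$group)
  if (!control %in% groups_present) {
    stop("unknown control group: ", control, call. = FALSE)
  }
  if (length(groups_present) < 2) stop("need >= 2 groups", call. = FALSE)
  out <- list()
  report <- character(0)
  for (v in c("moving_velocity", "average_velocity", "pause_percent")) {
    groups <- split(metrics[[v]], metrics$group)
    test <- if (length(groups) == 2) {
      others <- setdiff(names(groups), control)
      t_test_groups(groups[[control]], groups[[others]])
    } else {
      anova_bonferroni(groups)
    }
    summ <- summarize_groups(groups, control = control)
    out[[v]] <- list(summary = summ, test = test)
    p <- if (inherits(test, "comparison_result")) test$p.value
         else test$omnibus$p.value
    report <- c(report, sprintf("%s: p = %.4g (%s)", v, p,
                                significance_stars(p)),
                utils::capture.output(print(summ, row.names = FALSE)), "")
  }
  if (!is.null(out_dir)) {
    prepare_out_dir(out_dir, force = TRUE)
    writeLines(report, file.path(out_dir, "comparison_report.txt"))
  }
  out
}

read_puncta_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  } else {
    stop("not a supported image format: ", path, call. = FALSE)
  }
}

#' Segment and compare puncta/soma size distributions
#'
#' Runs [segment_objects()] and [bin_areas()] on each image, then (when two
#' or more groups each contribute at least two images) compares the
#' per-image class frequencies between groups with the statistics layer.
#'
#' @param images Named list of image matrices, or a character vector of
#'   TIFF/PNG paths. Unreadable files are skipped with a warning and
#'   reported in `failed`.
#' @param pixel_size um/px calibration applied to all images (required for
#'   matrix input; for files it overrides any sidecar value; omitting it
#'   with mixed sidecar calibrations is an error).
#' @param groups Optional character vector (recycled) assigning each image
#'   to a group.
#' @param bins A [size_bins()] object.
#' @param min_area_px Passed to [segment_objects()].
#' @param out_dir Optional output directory for the records/frequency CSVs.
#' @return List with `records` (per-object rows across images),
#'   `frequencies` (per image x class), `stats` (per class, or NULL for a
#'   single group/image) and `failed`.
#' @export
cmd_puncta <- function(images, pixel_size = NULL, groups = NULL,
                       bins = size_bins(), min_area_px = 4, out_dir = NULL) {
  failed <- character(0)
  if (is.character(images)) {
    paths <- images
    names(paths) <- names(images) %||% basename(paths)
    loaded <- list()
    sizes <- numeric(0)
    for (i in seq_along(paths)) {
      img <- tryCatch(read_puncta_image(paths[i]), error = function(e) {
        warning("skipping ", paths[i], ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(img)) {
        failed <- c(failed, unname(paths[i]))
        next
      }
      meta_path <- paste0(paths[i], ".meta")
      px <- if (file.exists(meta_path)) {
        kv_number(read_keyvalue(meta_path), "pixel_size_um",
                  required = FALSE)
      } else NULL
      loaded[[names(paths)[i]]] <- img
      sizes <- c(sizes, px %||% NA_real_)
    }
    if (is.null(pixel_size)) {
      known <- sizes[!is.na(sizes)]
      if (!length(known) || length(unique(known)) > 1 || anyNA(sizes)) {
        stop("missing or mixed pixel calibrations; supply 'pixel_size'",
             call. = FALSE)
      }
      pixel_size <- known[1]
    }
    images <- loaded
  }
  if (is.null(pixel_size)) {
    stop("'pixel_size' is required for matrix input", call. = FALSE)
  }
  if (!length(images)) stop("no readable images", call. = FALSE)
  if (is.null(names(images))) {
    names(images) <- paste0("image_", seq_along(images))
  }
  groups <- rep_len(groups %||% "all", length(images))

  records <- list()
  freqs <- list()
  for (i in seq_along(images)) {
    rec <- segment_objects(images[[i]], pixel_size = pixel_size,
                           min_area_px = min_area_px)
    if (nrow(rec)) {
      rec$image <- names(images)[i]
      rec$group <- groups[i]
      records[[length(records) + 1L]] <- rec
      fr <- bin_areas(rec, bins)
      fr$image <- names(images)[i]
      fr$group <- groups[i]
      freqs[[length(freqs) + 1L]] <- fr
    }
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  freqs <- if (length(freqs)) do.call(rbind, freqs) else NULL
  if (is.null(freqs)) stop("no objects segmented in any image", call. = FALSE)

  stats_out <- NULL
  by_group <- split(unique(freqs$image), groups[match(unique(freqs$image),
                                                      names(images))])
  if (length(by_group) >= 2 && all(lengths(by_group) >= 2)) {
    stats_out <- lapply(stats::setNames(nm = bins$labels), function(cl) {
      per_group <- lapply(by_group, function(imgs) {
        vapply(imgs, function(im) {
          freqs$percent[freqs$image == im & freqs$class == cl]
        }, numeric(1))
      })
      if (length(per_group) == 2) {
        t_test_groups(per_group[[1]], per_group[[2]])
      } else {
        anova_bonferroni(per_group)
      }
    })
  }
  if (!is.null(out_dir)) {
    prepare_out_dir(out_dir, force = TRUE)
    write_csv_prov(records, file.path(out_dir, "puncta_records.csv"),
                   provenance = list(pixel_size_um = pixel_size,
                                     bin_edges = bins$edges))
    write_csv_prov(freqs, file.path(out_dir, "puncta_frequencies.csv"),
                   provenance = list(bin_edges = bins$edges))
  }
  list(records = records, frequencies = freqs, stats = stats_out,
       failed = failed)
}
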