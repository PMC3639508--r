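#' Read and write movies as multi-page 16-bit TIFF
#'
#' Lossless round trip for 16-bit unsigned integer counts, one page per
#' frame, frame order preserved.
#'
#' @param path File path.
#' @param movie A `vk_movie` (integer array, values in 0..65535).
#' @param frame_interval_s,n_pre_frames,psf_sigma_px Acquisition metadata
#'   restored onto the movie when reading (TIFF pages do not carry them).
#' @return `read_movie()` returns a `vk_movie`; `write_movie()` returns
#'   `path` invisibly.
#' @export
read_movie <- function(path, frame_interval_s = 1, n_pre_frames = 0L,
                       psf_sigma_px = 1.5) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  info <- tryCatch(tiff::readTIFF(path, all = TRUE, payload = FALSE),
                   error = function(e) stop("unreadable TIFF '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
  if (is.data.frame(info)) bits <- info$bits.per.sample else bits <- info[["bits.per.sample"]]
  if (!all(bits == 16L)) {
    stop("expected 16-bit unsigned TIFF, got ", paste(unique(bits), collapse = "/"),
         "-bit: ", path, call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
  if (length(pages) == 0) stop("TIFF has zero pages: ", path, call. = FALSE)
  arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (!identical(dim(p), dim(pages[[1]]))) {
      stop("TIFF page ", i, " has inconsistent dimensions", call. = FALSE)
    }
    arr[, , i] <- p
  }
  structure(arr, class = c("vk_movie", "array"),
            frame_interval_s = frame_interval_s,
            n_pre_frames = as.integer(n_pre_frames),
            psf_sigma_px = psf_sigma_px)
}

#' @rdname read_movie
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie)
  stopifnot(length(d) == 3)
  if (min(movie) < 0 || max(movie) > 65535) {
    stop("movie values outside the 16-bit range", call. = FALSE)
  }
  pages <- lapply(seq_len(d[3]), function(f) movie[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

vk_log <- function(..., quiet = FALSE) {
  if (!quiet) message("[vesiclekit] ", ...)
}

#' Run the Ca2+-triggered fusion experiment end to end
#'
#' Generates (or accepts) movies for one or more fields of view, detects
#' docked spots on the averaged pre-trigger frames, normalizes intensities
#' and excludes very large spots, extracts content-dye traces at the kept
#' spot positions, detects stepwise dequenching events, post-synchronizes
#' them by the first event per field, builds the self-normalized 1-s
#' histogram and cumulative distribution, fits the bi-exponential decay,
#' and computes the fusion probability (events per docked vesicle; docked
#' counted after large-spot exclusion).
#'
#' @param preset A fusion preset from [make_preset()] (or its name).
#' @param n_fov Number of fields of view to simulate (default 1).
#' @param seed Base seed; field i uses `seed + i - 1`. Defaults to the
#'   preset's seed so fixtures are reproducible.
#' @param movies Optional list of pre-made `vk_movie`s (overrides
#'   generation).
#' @param k_thresh,min_sep_px Spot-detection parameters.
#' @param k_step,w,m_sustain,min_ratio Step-detection parameters, see
#'   [detect_step()].
#' @param max_au,max_area_px Large-spot exclusion parameters.
#' @param quiet Suppress stage logging.
#' @return A `vk_fusion_report` list: config echo, per-stage counts, the
#'   spot/event tables, histogram, cumulative distribution, fit (or NULL)
#'   and fusion probability.
#' @export
run_fusion_pipeline <- function(preset, n_fov = 1, seed = NULL, movies = NULL,
                                k_thresh = 5, min_sep_px = 3,
                                k_step = 5, w = 5, m_sustain = 3,
                                min_ratio = 1.5,
                                max_au = 6, max_area_px = 39L,
                                quiet = FALSE) {
  if (is.character(preset)) preset <- make_preset(preset)
  if (is.null(seed)) seed <- preset$seed
  sigma <- preset$optics$psf_sigma_px
  n_pre <- preset$optics$n_pre_frames

  all_spots <- list(); all_events <- list()
  n_detected <- n_excluded <- 0L
  for (fov in seq_len(n_fov)) {
    fov_id <- paste0("fov", fov)
    movie <- if (!is.null(movies)) movies[[fov]] else {
      render_movie(preset, seed = seed + fov - 1L)
    }
    pre_frames <- if (n_pre > 0) seq_len(n_pre) else 1L
    pre_img <- apply(movie[, , pre_frames, drop = FALSE], c(1, 2), mean)
    spots <- detect_spots(pre_img, psf_sigma_px = sigma, k_thresh = k_thresh,
                          min_sep_px = min_sep_px, fov_id = fov_id)
    spots <- suppressWarnings(normalize_au(spots))
    ex <- exclude_large_spots(spots, max_au = max_au, max_area_px = max_area_px)
    vk_log(fov_id, ": ", nrow(spots), " spots detected, ",
           nrow(ex$excluded), " very large spots excluded", quiet = quiet)
    n_detected <- n_detected + nrow(spots)
    n_excluded <- n_excluded + nrow(ex$excluded)
    kept <- ex$kept
    kept$spot_id <- paste0(fov_id, "_s", seq_len(nrow(kept)))
    all_spots[[fov]] <- kept

    events <- purrr::pmap(list(kept$x, kept$y, kept$spot_id),
      function(x, y, id) {
        tr <- tryCatch(extract_trace(movie, x, y, spot_id = id,
                                     psf_sigma_px = sigma),
                       error = function(e) NULL)
        if (is.null(tr)) return(NULL)
        ev <- detect_step(tr, k_step = k_step, w = w, m_sustain = m_sustain,
                          min_ratio = min_ratio)
        if (is.null(ev)) return(NULL)
        ev$fov_id <- fov_id
        ev
      })
    events <- dplyr::bind_rows(purrr::compact(events))
    vk_log(fov_id, ": ", nrow(events), " content-mixing events detected",
           quiet = quiet)
    all_events[[fov]] <- events
  }

  spots <- dplyr::bind_rows(all_spots)
  events <- dplyr::bind_rows(all_events)
  n_docked <- nrow(spots)
  events <- if (nrow(events) > 0) synchronize_events(events) else events

  hist <- NULL; cum <- NULL; fit <- NULL; note <- NULL
  if (nrow(events) > 0) {
    hist <- suppressMessages(build_histogram(events$t_sync_s, n_docked = n_docked))
    cum <- cumulative_distribution(hist)
    fit <- tryCatch(suppressWarnings(fit_biexponential(hist)),
                    error = function(e) { note <<- conditionMessage(e); NULL })
  } else {
    note <- "no fusion events: histogram empty, fit skipped"
    vk_log(note, quiet = quiet)
  }

  structure(list(
    config = list(preset = preset$name, n_fov = n_fov, seed = seed,
                  k_thresh = k_thresh, min_sep_px = min_sep_px,
                  k_step = k_step, w = w, m_sustain = m_sustain,
                  min_ratio = min_ratio,
                  max_au = max_au, max_area_px = max_area_px),
    n_spots_detected = n_detected,
    n_spots_excluded = n_excluded,
    n_docked = n_docked,
    n_events = nrow(events),
    spots = spots, events = events,
    histogram = hist, cumulative = cum, fit = fit,
    fusion_probability = if (n_docked > 0) nrow(events) / n_docked else NA_real_,
    note = note), class = "vk_fusion_report")
}

#' @export
print.vk_fusion_report <- function(x, ...) {
  cat("<vk_fusion_report> preset ", x$config$preset, ", ", x$config$n_fov,
      " FOV, seed ", x$config$seed, "\n", sep = "")
  cat("  docked (after exclusion): ", x$n_docked, ", events: ", x$n_events,
      ", fusion probability: ", signif(x$fusion_probability, 4), "\n", sep = "")
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Run the v-/v-vesicle clustering experiment end to end
#'
#' For each condition, renders `n_locations` two-channel fields (saturated
#' DiD surface + DiI docked spots), checks surface homogeneity, counts DiI
#' spots per location after large-spot exclusion, and compares every
#' condition against the first (control) with the pooled-variance Student's
#' t-test.
#'
#' @param presets Named list of `cluster_*` presets (or preset names);
#'   first = control.
#' @param n_locations Imaging locations per condition (default 10). With a
#'   single location the SD is undefined and t-tests are refused.
#' @param surface_preset DiD surface preset.
#' @param seed Base seed; per-condition, per-location seeds are derived.
#' @param quiet Suppress stage logging.
#' @return A `vk_clustering_report` list: config, per-condition
#'   [count_per_fov()] rows, and a comparison tibble vs the control.
#' @export
run_clustering_pipeline <- function(presets, n_locations = 10,
                                    surface_preset = make_preset("saturated_surface"),
                                    seed = 1L, quiet = FALSE) {
  stopifnot(length(presets) >= 1)
  presets <- lapply(presets, function(p) if (is.character(p)) make_preset(p) else p)
  if (is.null(names(presets)) || any(names(presets) == "")) {
    names(presets) <- vapply(presets, function(p) p$name, character(1))
  }
  counts <- purrr::imap(presets, function(p, nm) {
    i <- match(nm, names(presets))
    fields <- lapply(seq_len(n_locations), function(loc) {
      render_clustering_field(surface_preset, p, seed = seed + 1000L * i + loc)
    })
    fc <- count_vv_interactions(fields)
    vk_log(nm, ": mean ", signif(fc$mean, 4), " DiI spots over ",
           n_locations, " locations", quiet = quiet)
    fc$condition <- nm
    fc
  })
  field_counts <- dplyr::bind_rows(counts)

  comparisons <- NULL
  if (length(presets) >= 2) {
    if (n_locations < 2) {
      vk_log("single imaging location: t-tests refused", quiet = quiet)
    } else {
      ctrl <- counts[[1]]
      comparisons <- dplyr::bind_rows(lapply(seq_along(counts)[-1], function(i) {
        students_t(counts[[i]]$counts[[1]], ctrl$counts[[1]],
                   labels = c(names(presets)[i], names(presets)[1]))
      }))
    }
  }
  structure(list(
    config = list(presets = names(presets), n_locations = n_locations,
                  surface_preset = surface_preset$name, seed = seed),
    field_counts = field_counts,
    comparisons = comparisons), class = "vk_clustering_report")
}

#' @export
print.vk_clustering_report <- function(x, ...) {
  cat("<vk_clustering_report> ", length(x$config$presets), " condition(s), ",
      x$config$n_locations, " locations each, seed ", x$config$seed, "\n", sep = "")
  print(dplyr::select(x$field_counts, "condition", "n_locations", "mean", "sd"))
  if (!is.null(x$comparisons)) {
    print(dplyr::select(x$comparisons, "condition_a", "condition_b",
                        "t", "df", "p", "stars"))
  }
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' The configuration names the experiment (`fusion` or `clustering`), the
#' presets (with optional field overrides), pipeline parameters, the number
#' of imaging locations, the seed, and an optional output directory.
#'
#' @param path YAML file.
#' @return Validated config list with presets materialized.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$experiment))
  if (!cfg$experiment %in% c("fusion", "clustering")) {
    stop("experiment must be 'fusion' or 'clustering'", call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$n_locations)) cfg$n_locations <- 10L
  cfg$preset_objects <- lapply(cfg$presets, function(p) {
    if (is.character(p)) make_preset(p)
    else make_preset(p$name, overrides = p[setdiff(names(p), "name")])
  })
  cfg
}

#' Run an experiment described by a config
#' @param config List from [read_run_config()].
#' @param quiet Suppress stage logging.
#' @return The fusion or clustering report.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (config$experiment == "fusion") {
    run_fusion_pipeline(config$preset_objects[[1]],
                        n_fov = config$n_fov %||% 1,
                        seed = config$seed, quiet = quiet)
  } else {
    run_clustering_pipeline(config$preset_objects,
                            n_locations = config$n_locations,
                            seed = config$seed, quiet = quiet)
  }
}

#' Write a pipeline report to JSON (tables to CSV alongside)
#'
#' @param report A `vk_fusion_report` or `vk_clustering_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(report, "vk_fusion_report")) {
    utils::write.csv(report$spots, file.path(dir, "spots.csv"), row.names = FALSE)
    utils::write.csv(report$events, file.path(dir, "events.csv"), row.names = FALSE)
    json <- list(config = report$config,
                 n_spots_detected = report$n_spots_detected,
                 n_spots_excluded = report$n_spots_excluded,
                 n_docked = report$n_docked,
                 n_events = report$n_events,
                 fusion_probability = report$fusion_probability,
                 fit = if (!is.null(report$fit)) {
                   report$fit[c("y0", "A1", "tau1_s", "A2", "tau2_s",
                                "residual_ss", "n_events", "n_docked")]
                 })
  } else {
    utils::write.csv(dplyr::select(report$field_counts, -"counts"),
                     file.path(dir, "field_counts.csv"), row.names = FALSE)
    if (!is.null(report$comparisons)) {
      utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    json <- list(config = report$config,
                 field_counts = dplyr::select(report$field_counts, -"counts"))
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
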