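#' Sample fusion event times from a preset's bi-exponential law
#'
#' Event times are drawn i.i.d. from the density proportional to
#' A1*exp(-t/tau1) + A2*exp(-t/tau2) truncated to the 50-s observation
#' window. The small negative offset y0 of the published fits is a baseline
#' artifact and is ignored for sampling (a density must be non-negative).
#' Component i is selected with probability proportional to
#' Ai*taui*(1 - exp(-50/taui)), then a truncated exponential is drawn by
#' inversion.
#'
#' @param preset A [make_preset()] object (its `kinetic_params` are used).
#' @param n_events Number of times to draw.
#' @param t_max Truncation time in seconds (default 50).
#' @return Numeric vector of `n_events` times in `[0, t_max]`.
#' @export
sample_event_times <- function(preset, n_events, t_max = 50) {
  stopifnot(n_events >= 0)
  kp <- preset$kinetic_params
  A <- c(kp[["A1"]], kp[["A2"]])
  tau <- c(kp[["tau1_s"]], kp[["tau2_s"]])
  if (all(A <= 0)) stop("both kinetic amplitudes are zero; no event-time law", call. = FALSE)
  if (n_events == 0) return(numeric(0))
  mass <- A * tau * (1 - exp(-t_max / tau))
  comp <- sample.int(2L, n_events, replace = TRUE, prob = mass / sum(mass))
  u <- stats::runif(n_events)
  -tau[comp] * log(1 - u * (1 - exp(-t_max / tau[comp])))
}

# Normalized truncated bi-exponential density / CDF of the event-time law;
# used by tests and plotting.
#' Event-time density and cumulative distribution of a preset
#' @param preset A [make_preset()] object.
#' @param t Times (seconds).
#' @param t_max Truncation time (default 50).
#' @return Numeric vector of density (or CDF) values at `t`.
#' @export
event_time_density <- function(preset, t, t_max = 50) {
  kp <- preset$kinetic_params
  A <- c(kp[["A1"]], kp[["A2"]]); tau <- c(kp[["tau1_s"]], kp[["tau2_s"]])
  norm <- sum(A * tau * (1 - exp(-t_max / tau)))
  out <- (A[1] * exp(-t / tau[1]) + A[2] * exp(-t / tau[2])) / norm
  out[t < 0 | t > t_max] <- 0
  out
}

#' @rdname event_time_density
#' @export
event_time_cdf <- function(preset, t, t_max = 50) {
  kp <- preset$kinetic_params
  A <- c(kp[["A1"]], kp[["A2"]]); tau <- c(kp[["tau1_s"]], kp[["tau2_s"]])
  norm <- sum(A * tau * (1 - exp(-t_max / tau)))
  tt <- pmin(pmax(t, 0), t_max)
  (A[1] * tau[1] * (1 - exp(-tt / tau[1])) +
   A[2] * tau[2] * (1 - exp(-tt / tau[2]))) / norm
}

# Frame times of a preset's movie: n_pre_frames pre-trigger frames at
# t = -n_pre..-1 s, then the observation window. One frame beyond the 50-s
# window is included so an event landing in the final 1-s bin still has an
# at-or-after frame and remains observable.
frame_times <- function(preset) {
  o <- preset$optics
  (seq_len(o$n_frames) - 1 - o$n_pre_frames) * o$frame_interval_s
}

# Noiseless per-frame content-dye level of one spot: baseline before the
# event, baseline * dequench_factor from the first frame at or after the
# event time.
trace_levels <- function(preset, baseline, fused, event_time) {
  t <- frame_times(preset)
  lev <- rep(baseline, length(t))
  if (isTRUE(fused)) {
    lev[t >= event_time] <- baseline * preset$dequench_factor
  }
  lev
}

#' Generate one synthetic content-dye trace
#'
#' Simulates the integrated content-dye intensity of a docked vesicle at the
#' preset's frame interval: a constant self-quenched baseline, multiplied by
#' the dequenching factor from the first frame at or after the event time if
#' the vesicle fuses. Shot noise (Poisson) and Gaussian read noise are added
#' according to the preset's noise model.
#'
#' @param preset A [make_preset()] object.
#' @param fused Logical; does this vesicle fuse?
#' @param event_time Event time in seconds (required if `fused`), within the
#'   observation window.
#' @param baseline Pre-fusion integrated intensity (counts); defaults to the
#'   preset's single-vesicle flux.
#' @param seed Optional RNG seed for reproducibility.
#' @return A tibble with columns `frame` (0-based), `t_s`, `intensity`, and
#'   attributes `fused`, `event_time`, `baseline`.
#' @export
synth_trace <- function(preset, fused, event_time = NA_real_,
                        baseline = preset$baseline, seed = NULL) {
  if (isTRUE(fused)) {
    stopifnot(is.finite(event_time), event_time >= 0,
              event_time <= 50)
  }
  if (!is.null(seed)) set.seed(seed)
  lev <- trace_levels(preset, baseline, fused, event_time)
  x <- lev
  if (isTRUE(preset$noise$shot_noise)) x <- stats::rpois(length(lev), lev)
  if (preset$noise$read_noise_sd > 0) {
    x <- x + stats::rnorm(length(lev), 0, preset$noise$read_noise_sd)
  }
  out <- tibble::tibble(frame = seq_along(lev) - 1L,
                        t_s = frame_times(preset),
                        intensity = as.numeric(x))
  attr(out, "fused") <- isTRUE(fused)
  attr(out, "event_time") <- if (isTRUE(fused)) event_time else NA_real_
  attr(out, "baseline") <- baseline
  attr(out, "frame_interval_s") <- preset$optics$frame_interval_s
  out
}

# Rejection-sample n spot centers uniformly on the field interior with a
# minimum pairwise separation. Fails loudly if the field cannot accommodate
# the requested density.
place_spots <- function(n, field_size_px, min_sep_px, margin_px,
                        max_tries_per_spot = 300L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  lo <- margin_px
  hi <- field_size_px - 1 - margin_px
  if (hi <= lo) stop("field too small for the placement margin", call. = FALSE)
  xs <- numeric(n); ys <- numeric(n)
  sep2 <- min_sep_px^2
  # coarse grid for neighbour lookup
  cell <- max(min_sep_px, 1)
  ncell <- ceiling((hi - lo + 1) / cell)
  grid <- vector("list", ncell * ncell)
  cell_of <- function(x, y) {
    cx <- pmin(pmax(floor((x - lo) / cell), 0), ncell - 1)
    cy <- pmin(pmax(floor((y - lo) / cell), 0), ncell - 1)
    cx * ncell + cy + 1
  }
  tries_total <- 0L
  max_tries <- max_tries_per_spot * n
  i <- 1L
  while (i <= n) {
    if (tries_total > max_tries) {
      stop("could not place ", n, " spots at separation ", min_sep_px,
           " px on a ", field_size_px, " px field", call. = FALSE)
    }
    tries_total <- tries_total + 1L
    x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
    cx <- floor((x - lo) / cell); cy <- floor((y - lo) / cell)
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      gx <- cx + dx; gy <- cy + dy
      if (gx < 0 || gy < 0 || gx >= ncell || gy >= ncell) next
      for (j in grid[[gx * ncell + gy + 1]]) {
        if ((xs[j] - x)^2 + (ys[j] - y)^2 < sep2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      xs[i] <- x; ys[i] <- y
      ci <- cell_of(x, y)
      grid[[ci]] <- c(grid[[ci]], i)
      i <- i + 1L
    }
  }
  cbind(x = xs, y = ys)
}

# Render one isotropic Gaussian patch (flux-normalized within its window) of
# total flux 1 centered at (x, y); returns list(xs, ys, patch).
gaussian_patch <- function(x, y, sigma, field_size_px, r = ceiling(4 * sigma)) {
  cx <- round(x); cy <- round(y)
  xs <- max(0, cx - r):min(field_size_px - 1, cx + r)
  ys <- max(0, cy - r):min(field_size_px - 1, cy + r)
  gx <- exp(-(xs - x)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y)^2 / (2 * sigma^2))
  patch <- outer(gy, gx)          # rows = y, cols = x
  list(xs = xs + 1L, ys = ys + 1L, patch = patch / sum(patch))
}

#' Render a synthetic TIRF movie with ground truth
#'
#' Places a Poisson-distributed number of docked-vesicle spots (mean
#' `n_docked`) uniformly at random with a minimum center separation of
#' `min_sep_factor * psf_sigma_px`, renders each as an isotropic Gaussian of
#' the PSF width whose integrated flux is `baseline * k` (multiplicity `k`
#' drawn from the preset's cluster-size law) scaled per frame by its
#' content-dye trace, adds rare large aggregates where the preset requests
#' them, then adds constant background, Poisson shot noise and Gaussian read
#' noise, and quantizes to 16-bit counts.
#'
#' For fusion presets carrying an exact planted event total (`n_events`),
#' exactly that many spots fuse, at times drawn from the preset's
#' bi-exponential law; otherwise each spot fuses independently with
#' probability `p_fusion`.
#'
#' @param preset A [make_preset()] object.
#' @param seed RNG seed; defaults to the preset's own seed so fixtures are
#'   bit-reproducible.
#' @return A `vk_movie`: integer array (y, x, frame) with attributes
#'   `frame_interval_s`, `n_pre_frames`, `psf_sigma_px` and a `ground_truth`
#'   tibble (`spot`, `x`, `y`, `k`, `aggregate`, `fused`, `t_event_s`,
#'   `baseline`).
#' @export
render_movie <- function(preset, seed = preset$seed) {
  if (!is.null(seed)) set.seed(seed)
  o <- preset$optics
  fs <- o$field_size_px
  n_frames <- o$n_frames
  sigma <- o$psf_sigma_px

  n_spots <- stats::rpois(1, preset$n_docked)
  n_agg <- if (preset$large_aggregate_rate > 0) {
    stats::rpois(1, preset$large_aggregate_rate)
  } else 0L
  pos <- place_spots(n_spots + n_agg, fs, o$min_sep_factor * sigma, o$margin_px)
  is_agg <- c(rep(FALSE, n_spots), rep(TRUE, n_agg))

  k <- integer(0)
  if (n_spots > 0) {
    k <- sample.int(length(preset$cluster_size_law), n_spots, replace = TRUE,
                    prob = preset$cluster_size_law)
  }
  if (n_agg > 0) k <- c(k, sample(15:40, n_agg, replace = TRUE))

  fused <- rep(FALSE, n_spots + n_agg)
  t_event <- rep(NA_real_, n_spots + n_agg)
  if (n_spots > 0 && preset$kind == "fusion") {
    if (!is.null(preset$n_events)) {
      n_ev <- min(preset$n_events, n_spots)
      idx <- sample.int(n_spots, n_ev)
    } else {
      idx <- which(stats::runif(n_spots) < preset$p_fusion)
    }
    fused[idx] <- TRUE
    if (length(idx)) t_event[idx] <- sample_event_times(preset, length(idx))
  }

  signal <- array(0, dim = c(fs, fs, n_frames))
  if (n_spots + n_agg > 0) {
    for (i in seq_len(n_spots + n_agg)) {
      sg <- if (is_agg[i]) 2 * sigma else sigma
      gp <- gaussian_patch(pos[i, "x"], pos[i, "y"], sg, fs)
      lev <- trace_levels(preset, preset$baseline * k[i], fused[i], t_event[i])
      signal[gp$ys, gp$xs, ] <- signal[gp$ys, gp$xs, , drop = FALSE] +
        outer(gp$patch, lev)
    }
  }

  movie <- array(0L, dim = c(fs, fs, n_frames))
  bg <- preset$noise$background
  rn <- preset$noise$read_noise_sd
  for (f in seq_len(n_frames)) {
    fr <- signal[, , f] + bg
    if (isTRUE(preset$noise$shot_noise)) {
      fr <- stats::rpois(length(fr), fr)
    }
    if (rn > 0) fr <- fr + stats::rnorm(length(fr), 0, rn)
    movie[, , f] <- as.integer(pmin(pmax(round(fr), 0), 65535))
  }

  gt <- tibble::tibble(
    spot = seq_len(n_spots + n_agg),
    x = if (n_spots + n_agg > 0) pos[, "x"] else numeric(0),
    y = if (n_spots + n_agg > 0) pos[, "y"] else numeric(0),
    k = k, aggregate = is_agg, fused = fused, t_event_s = t_event,
    baseline = preset$baseline * k)

  structure(movie,
            class = c("vk_movie", "array"),
            frame_interval_s = o$frame_interval_s,
            n_pre_frames = o$n_pre_frames,
            psf_sigma_px = sigma,
            preset_name = preset$name,
            ground_truth = gt)
}

#' @export
print.vk_movie <- function(x, ...) {
  d <- dim(x)
  cat("<vk_movie> ", d[1], "x", d[2], " px, ", d[3], " frame(s), ",
      attr(x, "n_pre_frames"), " pre-trigger, dt = ",
      attr(x, "frame_interval_s"), " s\n", sep = "")
  gt <- attr(x, "ground_truth")
  if (!is.null(gt)) {
    cat("  ground truth: ", nrow(gt), " spots (", sum(gt$fused), " fused, ",
        sum(gt$aggregate), " aggregates)\n", sep = "")
  }
  invisible(x)
}

#' Ground-truth sidecar of a synthetic movie
#' @param movie A `vk_movie` from [render_movie()].
#' @return The ground-truth tibble planted by the generator.
#' @export
ground_truth <- function(movie) attr(movie, "ground_truth")

#' Render a two-channel clustering field
#'
#' Channel "DiD" is the saturated immobilized-vesicle layer (dense but
#' individually resolvable spots forming a spatially homogeneous surface);
#' channel "DiI" carries the docked clustering spots whose count scales with
#' the docked preset's clustering efficiency.
#'
#' @param surface_preset Preset for the DiD surface (usually
#'   `make_preset("saturated_surface")`).
#' @param docked_preset A `cluster_*` preset for the DiI channel.
#' @param seed RNG seed; defaults to the docked preset's seed.
#' @return List with elements `DiD` and `DiI` (single-frame `vk_movie`s) and
#'   `ground_truth` (the DiI ground-truth tibble).
#' @export
render_clustering_field <- function(surface_preset, docked_preset,
                                    seed = docked_preset$seed) {
  if (!is.null(seed)) set.seed(seed)
  did <- render_movie(surface_preset, seed = NULL)
  dii <- render_movie(docked_preset, seed = NULL)
  list(DiD = did, DiI = dii, ground_truth = ground_truth(dii))
}
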