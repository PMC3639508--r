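#' Estimate the smooth background of a frame
#'
#' Moving-median background: medians are computed in `window_px`-sized
#' windows on a coarse grid of centers and interpolated bilinearly back to
#' full resolution. Diffraction-limited spots much narrower than the window
#' barely move the local median, so subtracting the estimate from a
#' pure-background frame leaves a zero-median residual.
#'
#' @param frame 2-D numeric matrix.
#' @param window_px Odd window size in pixels (>= 3).
#' @return Matrix of the same shape as `frame`.
#' @export
estimate_background <- function(frame, window_px = 65L) {
  stopifnot(is.matrix(frame))
  if (window_px %% 2 != 1 || window_px < 3) {
    stop("window_px must be odd and >= 3", call. = FALSE)
  }
  if (window_px > min(dim(frame))) {
    stop("window_px larger than the frame", call. = FALSE)
  }
  ny <- nrow(frame); nx <- ncol(frame)
  h <- (window_px - 1) / 2
  step <- max(1, floor(window_px / 2))
  cy <- unique(c(seq(1, ny, by = step), ny))
  cx <- unique(c(seq(1, nx, by = step), nx))
  med <- matrix(0, length(cy), length(cx))
  for (i in seq_along(cy)) {
    ys <- max(1, cy[i] - h):min(ny, cy[i] + h)
    for (j in seq_along(cx)) {
      xs <- max(1, cx[j] - h):min(nx, cx[j] + h)
      med[i, j] <- stats::median(frame[ys, xs])
    }
  }
  .bilinear_expand(med, cy, cx, ny, nx)
}

# Bilinear interpolation of grid values (at rows cy, cols cx) to a full
# ny x nx matrix.
.bilinear_expand <- function(vals, cy, cx, ny, nx) {
  interp_axis <- function(centers, n) {
    idx <- findInterval(seq_len(n), centers, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1), length(centers) - 1)
    lo <- centers[idx]; hi <- centers[idx + 1]
    w <- ifelse(hi > lo, (seq_len(n) - lo) / (hi - lo), 0)
    list(i = idx, w = pmin(pmax(w, 0), 1))
  }
  if (length(cy) == 1 && length(cx) == 1) {
    return(matrix(vals[1, 1], ny, nx))
  }
  if (length(cy) == 1) {
    ax <- interp_axis(cx, nx)
    row <- vals[1, ax$i] * (1 - ax$w) + vals[1, ax$i + 1] * ax$w
    return(matrix(row, ny, nx, byrow = TRUE))
  }
  if (length(cx) == 1) {
    ay <- interp_axis(cy, ny)
    col <- vals[ay$i, 1] * (1 - ay$w) + vals[ay$i + 1, 1] * ay$w
    return(matrix(col, ny, nx))
  }
  ay <- interp_axis(cy, ny); ax <- interp_axis(cx, nx)
  v11 <- vals[ay$i, ax$i]
  v21 <- vals[ay$i + 1, ax$i]
  v12 <- vals[ay$i, ax$i + 1]
  v22 <- vals[ay$i + 1, ax$i + 1]
  wy <- matrix(ay$w, ny, nx); wx <- matrix(ax$w, ny, nx, byrow = TRUE)
  v11 * (1 - wy) * (1 - wx) + v21 * wy * (1 - wx) +
    v12 * (1 - wy) * wx + v22 * wy * wx
}

# Robust pixel-noise sigma from horizontal first differences
# (MAD-based, insensitive to sparse spots and smooth background structure).
robust_noise_sigma <- function(frame) {
  d <- frame[, -1, drop = FALSE] - frame[, -ncol(frame), drop = FALSE]
  stats::mad(as.numeric(d), center = 0) / sqrt(2)
}

#' Detect diffraction-limited spots in a frame
#'
#' The background-subtracted frame is smoothed with a Gaussian matched to
#' the PSF; local maxima (8-neighbourhood) exceeding `k_thresh` times the
#' robust noise sigma of the smoothed frame are kept and non-maximum
#' suppressed within `min_sep_px`. Centers are refined by an iterated
#' intensity-weighted centroid in a window of half-width
#' `ceiling(3 * psf_sigma_px)`, restricted at each iteration to a disc of
#' radius `3 * psf_sigma_px` about the running center (so a neighbour at the
#' window edge cannot drag the center off the spot);
#' `intensity_raw` is the integrated counts in a disc of radius
#' `3 * psf_sigma_px` minus the local annulus median background, and
#' `area_px` counts window pixels above half the peak elevation.
#'
#' @param frame 2-D numeric matrix (raw counts; background is estimated
#'   internally) with finite values.
#' @param psf_sigma_px PSF sigma in pixels.
#' @param k_thresh Detection threshold in robust noise sigmas (default 5).
#' @param min_sep_px Non-maximum-suppression radius in pixels (default 3).
#' @param fov_id Field-of-view label stored in the output.
#' @param frame_index 0-based frame index stored in the output.
#' @param background_window Window for [estimate_background()].
#' @return Tibble of spot records: `fov_id`, `frame`, `x`, `y` (0-based
#'   fractional pixel centers, x = column), `intensity_raw`, `intensity_au`
#'   (NA until [normalize_au()]), `area_px`.
#' @export
detect_spots <- function(frame, psf_sigma_px, k_thresh = 5, min_sep_px = 3,
                         fov_id = "fov1", frame_index = 0L,
                         background_window = 65L) {
  if (!all(is.finite(frame))) stop("frame contains non-finite pixels", call. = FALSE)
  frame <- unclass(frame)
  bw <- min(background_window,
            if (min(dim(frame)) %% 2 == 1) min(dim(frame)) else min(dim(frame)) - 1)
  bg <- estimate_background(frame, bw)
  sub <- frame - bg
  sigma_raw <- robust_noise_sigma(sub)
  sm <- as.matrix(EBImage::gblur(sub, sigma = psf_sigma_px, boundary = "replicate"))
  # noise sigma of the smoothed frame: raw sigma times the kernel L2 norm
  sigma_sm <- sigma_raw / (2 * psf_sigma_px * sqrt(pi))
  # floor keeps noiseless synthetic frames from flagging numerical ripple
  thresh <- max(k_thresh * sigma_sm, 1e-6 * max(abs(sm)), .Machine$double.eps)

  peaks <- .local_maxima(sm, thresh)
  if (nrow(peaks) == 0) return(.empty_spots(fov_id, frame_index))
  peaks <- peaks[order(-peaks[, "value"]), , drop = FALSE]
  keep <- .greedy_nms(peaks[, "px"], peaks[, "py"], min_sep_px)
  peaks <- peaks[keep, , drop = FALSE]

  w <- ceiling(3 * psf_sigma_px)
  r_disc <- 3 * psf_sigma_px
  r_out <- 5 * psf_sigma_px
  ny <- nrow(sub); nx <- ncol(sub)

  n <- nrow(peaks)
  xs <- ys <- inten <- numeric(n); area <- integer(n)
  for (i in seq_len(n)) {
    px <- peaks[i, "px"]; py <- peaks[i, "py"]
    wy <- max(1, py - w):min(ny, py + w)
    wx <- max(1, px - w):min(nx, px + w)
    win <- pmax(sub[wy, wx, drop = FALSE], 0)
    wxm <- matrix(wx, length(wy), length(wx), byrow = TRUE)
    wym <- matrix(wy, length(wy), length(wx))
    # iterated centroid restricted to a disc of radius 3 sigma around the
    # current center estimate, so a bright neighbour at the window edge
    # cannot drag the center off the spot
    cx <- px; cy <- py
    for (it in 1:3) {
      mask <- (wxm - cx)^2 + (wym - cy)^2 <= r_disc^2
      tot <- sum(win[mask])
      if (tot <= 0) break
      cx <- sum((win * wxm)[mask]) / tot
      cy <- sum((win * wym)[mask]) / tot
    }
    xs[i] <- cx - 1; ys[i] <- cy - 1   # 0-based
    m <- .disc_measure(sub, xs[i], ys[i], r_disc, r_out)
    inten[i] <- max(m$intensity, 0)
    peak_el <- sub[py, px] - m$annulus_bg
    area[i] <- max(1L, sum(win - m$annulus_bg > peak_el / 2))
  }
  tibble::tibble(fov_id = fov_id, frame = as.integer(frame_index),
                 x = xs, y = ys,
                 intensity_raw = inten, intensity_au = NA_real_,
                 area_px = area)
}

.empty_spots <- function(fov_id, frame_index) {
  tibble::tibble(fov_id = character(0), frame = integer(0),
                 x = numeric(0), y = numeric(0),
                 intensity_raw = numeric(0), intensity_au = numeric(0),
                 area_px = integer(0))
}

# 8-neighbour local maxima above an absolute threshold; returns matrix with
# 1-based columns px (col), py (row) and value. Border pixels are excluded.
.local_maxima <- function(m, thresh) {
  ny <- nrow(m); nx <- ncol(m)
  if (ny < 3 || nx < 3) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("px", "py", "value"))))
  }
  c0 <- m[2:(ny - 1), 2:(nx - 1)]
  ok <- c0 >= thresh &
    c0 >= m[1:(ny - 2), 2:(nx - 1)] & c0 >= m[3:ny, 2:(nx - 1)] &
    c0 >= m[2:(ny - 1), 1:(nx - 2)] & c0 >= m[2:(ny - 1), 3:nx] &
    c0 >  m[1:(ny - 2), 1:(nx - 2)] & c0 >  m[1:(ny - 2), 3:nx] &
    c0 >  m[3:ny, 1:(nx - 2)] & c0 >  m[3:ny, 3:nx]
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("px", "py", "value"))))
  }
  cbind(px = idx[, 2] + 1, py = idx[, 1] + 1, value = c0[ok])
}

# Greedy non-maximum suppression: peaks assumed sorted by decreasing value.
.greedy_nms <- function(px, py, min_sep) {
  n <- length(px)
  keep <- logical(n)
  sep2 <- min_sep^2
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kx) == 0 || all((kx - px[i])^2 + (ky - py[i])^2 >= sep2)) {
      keep[i] <- TRUE
      kx <- c(kx, px[i]); ky <- c(ky, py[i])
    }
  }
  keep
}

# Integrated disc intensity minus annulus-median background around a
# 0-based center; annulus spans (r_disc, r_out].
.disc_measure <- function(sub, x0, y0, r_disc, r_out) {
  ny <- nrow(sub); nx <- ncol(sub)
  r <- ceiling(r_out)
  cx <- round(x0) + 1; cy <- round(y0) + 1
  wy <- max(1, cy - r):min(ny, cy + r)
  wx <- max(1, cx - r):min(nx, cx + r)
  d2 <- outer((wy - 1 - y0)^2, (wx - 1 - x0)^2, `+`)
  win <- sub[wy, wx, drop = FALSE]
  in_disc <- d2 <= r_disc^2
  in_ann <- d2 > r_disc^2 & d2 <= r_out^2
  ann_bg <- if (any(in_ann)) stats::median(win[in_ann]) else 0
  list(intensity = sum(win[in_disc]) - ann_bg * sum(in_disc),
       annulus_bg = ann_bg)
}

#' Normalize spot intensities to arbitrary units
#'
#' The a.u. scale anchors the single-vesicle modal intensity at 1, so the
#' published classification thresholds (singles < 1.5 a.u., clusters up to
#' 6 a.u.) apply directly. The mode is located as the peak of a kernel
#' density estimate of `intensity_raw`; with fewer than 20 spots the mode is
#' unreliable and the median is used instead (with a warning).
#'
#' @param spots Spot tibble from [detect_spots()].
#' @return The tibble with `intensity_au = intensity_raw / mode`.
#' @export
normalize_au <- function(spots) {
  x <- spots$intensity_raw
  if (length(x) == 0) return(spots)
  if (all(x == 0)) stop("all spot intensities are zero; cannot normalize", call. = FALSE)
  if (length(x) < 20) {
    warning("fewer than 20 spots; using median instead of modal intensity")
    anchor <- stats::median(x)
  } else if (stats::sd(x) == 0) {
    anchor <- x[1]
  } else {
    d <- stats::density(x, n = 2048)
    anchor <- d$x[which.max(d$y)]
  }
  dplyr::mutate(spots, intensity_au = .data$intensity_raw / anchor)
}

#' Exclude very large fluorescent spots from scoring
#'
#' Spots brighter than `max_au` or larger than `max_area_px` (defaults: the
#' upper end of the observed cluster range, 6 a.u., and four times the PSF
#' half-maximum area) are removed from scoring and returned separately.
#'
#' @param spots Spot tibble with `intensity_au` populated.
#' @param max_au Intensity cutoff in a.u. (default 6).
#' @param max_area_px Area cutoff in pixels; default `4 * pi * (1.1774 *
#'   psf_sigma_px)^2` for `psf_sigma_px = 1.5`, i.e. ~39 px.
#' @return List with tibbles `kept` and `excluded`; their union is the input.
#' @export
exclude_large_spots <- function(spots, max_au = 6, max_area_px = 39L) {
  big <- spots$intensity_au > max_au | spots$area_px > max_area_px
  big[is.na(big)] <- FALSE
  list(kept = spots[!big, , drop = FALSE], excluded = spots[big, , drop = FALSE])
}

#' Summarize per-location spot counts
#'
#' Counts are averaged over the imaged random locations within one sample
#' channel; the dispersion is the sample standard deviation (denominator
#' N - 1), matching how error bars over 10-20 random imaging locations are
#' reported.
#'
#' @param counts_per_location Numeric vector of per-location counts (N >= 1).
#' @return One-row tibble: `n_locations`, `mean`, `sd` (NA with a message
#'   when N = 1), plus the raw counts as a list column.
#' @export
count_per_fov <- function(counts_per_location) {
  if (length(counts_per_location) == 0) {
    stop("no per-location counts supplied", call. = FALSE)
  }
  n <- length(counts_per_location)
  s <- if (n >= 2) stats::sd(counts_per_location) else NA_real_
  if (n < 2) message("single imaging location: standard deviation undefined")
  tibble::tibble(n_locations = n,
                 mean = mean(counts_per_location),
                 sd = s,
                 counts = list(as.numeric(counts_per_location)))
}
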