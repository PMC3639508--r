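#' Extract a per-spot content-dye trace from a movie
#'
#' Per-frame integrated intensity in a disc of radius `3 * psf_sigma_px`
#' around the fixed spot center, minus the per-frame local annulus median
#' background times the disc area.
#'
#' @param movie A `vk_movie`.
#' @param x,y Spot center (0-based fractional pixels).
#' @param spot_id Identifier carried into the output.
#' @param psf_sigma_px PSF sigma; defaults to the movie's own.
#' @return Tibble: `spot_id`, `frame` (0-based), `t_s` (relative to the
#'   trigger; pre-trigger frames are negative), `intensity`.
#' @export
extract_trace <- function(movie, x, y, spot_id = 1L,
                          psf_sigma_px = attr(movie, "psf_sigma_px")) {
  d <- dim(movie)
  r_disc <- 3 * psf_sigma_px
  r_out <- 5 * psf_sigma_px
  r <- ceiling(r_out)
  if (x < r || y < r || x > d[2] - 1 - r || y > d[1] - 1 - r) {
    stop("spot ", spot_id, " at (", round(x, 1), ", ", round(y, 1),
         ") is too close to the field border for trace extraction", call. = FALSE)
  }
  cx <- round(x) + 1; cy <- round(y) + 1
  wy <- (cy - r):(cy + r); wx <- (cx - r):(cx + r)
  d2 <- outer((wy - 1 - y)^2, (wx - 1 - x)^2, `+`)
  in_disc <- d2 <= r_disc^2
  in_ann <- d2 > r_disc^2 & d2 <= r_out^2
  block <- movie[wy, wx, , drop = FALSE]
  bm <- matrix(block, nrow = length(wy) * length(wx), ncol = d[3])
  disc_sum <- colSums(bm[as.vector(in_disc), , drop = FALSE])
  ann_med <- apply(bm[as.vector(in_ann), , drop = FALSE], 2, stats::median)
  dt <- attr(movie, "frame_interval_s") %||% 1
  n_pre <- attr(movie, "n_pre_frames") %||% 0L
  tibble::tibble(spot_id = spot_id,
                 frame = seq_len(d[3]) - 1L,
                 t_s = (seq_len(d[3]) - 1L - n_pre) * dt,
                 intensity = disc_sum - ann_med * sum(in_disc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Robust per-frame noise estimate of a trace
#'
#' Median absolute deviation of the first differences, divided by sqrt(2)
#' (each difference carries the noise of two frames) and scaled by 1.4826 to
#' be consistent for Gaussian noise. A single step contributes one outlying
#' difference and is ignored by the median.
#'
#' @param intensity Numeric vector of per-frame intensities (>= 10 frames
#'   recommended), or a trace tibble with an `intensity` column.
#' @return Noise sigma in counts.
#' @export
estimate_noise_sigma <- function(intensity) {
  if (is.data.frame(intensity)) intensity <- intensity$intensity
  stats::mad(diff(intensity), center = 0) / sqrt(2)
}

#' Detect a stepwise dequenching (content-mixing) event in a trace
#'
#' A two-sided sliding window scans the trace; the candidate step is the
#' frame maximizing mean(next `w` frames) - mean(previous `w` frames). It is
#' reported as an event iff the difference is upward, exceeds `k_step` times
#' the robust noise sigma, and the elevation persists for `m_sustain` frames
#' (or to the end of the trace if fewer remain). Windows truncate at the
#' trace edges; there the threshold is scaled up by the ratio of the
#' truncated-window noise to the full-window noise so edge candidates are
#' not easier to pass. At most one event is reported per trace ("complete
#' fusion"); later candidate steps are not scored.
#'
#' In a crowded field a spot can sit close enough to a fusing neighbour
#' that its integration disc picks up a fraction of the neighbour's
#' dequenching step - a statistically significant but physically
#' sub-dequenching upward step. Complete fusion dilutes the self-quenched
#' content dye about twofold, so real events have a post/pre ratio near the
#' dequench factor; `min_ratio` (default 1.5, halfway between no step and
#' the twofold dequenching) rejects such crosstalk steps.
#'
#' @param trace Trace tibble from [extract_trace()] or [synth_trace()]
#'   (columns `t_s`, `intensity`), length > 2.
#' @param k_step Threshold in noise sigmas (default 5).
#' @param w Window half-width in frames (default 5).
#' @param m_sustain Frames the elevation must persist (default 3).
#' @param min_ratio Minimum post/pre level ratio for a step to count as a
#'   dequenching event (default 1.5); set to 1 to accept any upward step.
#' @return One-row tibble (`spot_id`, `t_event_s`, `step_frame`,
#'   `step_size`, `step_ratio`) or `NULL` if no event.
#' @export
detect_step <- function(trace, k_step = 5, w = 5, m_sustain = 3,
                        min_ratio = 1.5) {
  v <- trace$intensity
  n <- length(v)
  stopifnot(n > 2)
  sigma <- estimate_noise_sigma(v)
  best_i <- NA_integer_; best_d <- 0; best_scale <- 1; best_score <- 0
  for (i in 2:n) {                     # first elevated frame (1-based)
    w1 <- min(w, i - 1); w2 <- min(w, n - i + 1)
    d <- mean(v[i:(i + w2 - 1)]) - mean(v[(i - w1):(i - 1)])
    scale <- sqrt((1 / w1 + 1 / w2) / (2 / w))
    if (d / scale > best_score) {
      best_i <- i; best_d <- d; best_scale <- scale; best_score <- d / scale
    }
  }
  i <- best_i
  if (is.na(i) || best_d <= 0) return(NULL)
  if (best_d < k_step * sigma * best_scale) return(NULL)
  pre <- mean(v[1:(i - 1)])
  post <- mean(v[i:n])
  # sustain: every frame from the step to m_sustain (or trace end) must stay
  # above the midpoint between the pre level and the stepped level
  mid <- pre + best_d / 2
  sustain_end <- min(n, i + m_sustain - 1)
  if (!all(v[i:sustain_end] > mid)) return(NULL)
  if (!(post > pre) || post / pre <= 1) return(NULL)
  if (post / pre < min_ratio) return(NULL)
  tibble::tibble(spot_id = if ("spot_id" %in% names(trace)) trace$spot_id[1] else NA,
                 t_event_s = trace$t_s[i],
                 step_frame = i - 1L,
                 step_size = best_d,
                 step_ratio = post / pre)
}

#' Post-synchronize fusion events by the first event per field of view
#'
#' The Ca2+ arrival time in the evanescent field is taken as the instance of
#' the first content-mixing event among all docked vesicles of a field of
#' view; within each field `t_sync_s = t_event_s - min(t_event_s)`, so the
#' first event of each field lands at 0. Fields are then pooled. Applying
#' the operation twice changes nothing.
#'
#' @param events Tibble with columns `fov_id` and `t_event_s`.
#' @return The tibble with `t_sync_s` added.
#' @export
synchronize_events <- function(events) {
  if (nrow(events) == 0) {
    message("no events to synchronize")
    return(dplyr::mutate(events, t_sync_s = numeric(0)))
  }
  events |>
    dplyr::group_by(.data$fov_id) |>
    dplyr::mutate(t_sync_s = .data$t_event_s - min(.data$t_event_s)) |>
    dplyr::ungroup()
}

#' Build the self-normalized 1-s fusion-event histogram
#'
#' Events are counted in half-open 1-s bins over the 50-s observation window
#' and divided by the total event count ("self-normalized"). Times at or
#' beyond 50 s are dropped with a message.
#'
#' @param sync_times Synchronized event times in seconds.
#' @param n_docked Number of docked vesicles (the denominator of the fusion
#'   probability), stored alongside.
#' @param t_max Window length in seconds (default 50).
#' @param bin_s Bin width in seconds (default 1).
#' @return A `vk_event_histogram`: list with `bins` (tibble `bin_left`,
#'   `bin_mid`, `bin_right`, `count`, `prob`), `n_events`, `n_docked`,
#'   `n_dropped`.
#' @export
build_histogram <- function(sync_times, n_docked = NA_real_, t_max = 50, bin_s = 1) {
  stopifnot(all(sync_times >= 0))
  dropped <- sum(sync_times >= t_max)
  if (dropped > 0) {
    message(dropped, " event(s) at or beyond ", t_max, " s dropped from the histogram")
  }
  tt <- sync_times[sync_times < t_max]
  edges <- seq(0, t_max, by = bin_s)
  counts <- if (length(tt)) {
    tabulate(findInterval(tt, edges), nbins = length(edges) - 1)
  } else rep(0L, length(edges) - 1)
  n_ev <- length(tt)
  bins <- tibble::tibble(bin_left = edges[-length(edges)],
                         bin_mid = edges[-length(edges)] + bin_s / 2,
                         bin_right = edges[-1],
                         count = counts,
                         prob = if (n_ev > 0) counts / n_ev else rep(NA_real_, length(counts)))
  structure(list(bins = bins, n_events = n_ev, n_docked = n_docked,
                 n_dropped = dropped),
            class = "vk_event_histogram")
}

#' @export
print.vk_event_histogram <- function(x, ...) {
  cat("<vk_event_histogram> ", x$n_events, " events / ", x$n_docked,
      " docked, ", nrow(x$bins), " bins of ",
      x$bins$bin_right[1] - x$bins$bin_left[1], " s\n", sep = "")
  invisible(x)
}

#' Cumulative distribution of a fusion-event histogram
#'
#' Running sum of the self-normalized histogram at each bin edge;
#' non-decreasing with final value 1.
#'
#' @param hist A `vk_event_histogram`.
#' @return Tibble `t_s` (right bin edges), `cumulative`.
#' @export
cumulative_distribution <- function(hist) {
  if (hist$n_events == 0) {
    stop("empty histogram (0 events): cumulative distribution undefined", call. = FALSE)
  }
  tibble::tibble(t_s = hist$bins$bin_right,
                 cumulative = cumsum(hist$bins$prob))
}

# Box constraints for the bi-exponential polish: the data are self-normalized
# bin probabilities, so offsets and amplitudes beyond +/-1 and +/-10 are
# unphysical, and time constants far outside the observation window are not
# identifiable (a tau >> window trades off exactly against the offset).
.biexp_lower <- c(-1, -10, log(0.05), -10, log(0.05))
.biexp_upper <- c(1, 10, log(500), 10, log(500))

# f(t) = y0 + A1 exp(-t/tau1) + A2 exp(-t/tau2)
biexp_f <- function(t, p) {
  p[["y0"]] + p[["A1"]] * exp(-t / p[["tau1_s"]]) + p[["A2"]] * exp(-t / p[["tau2_s"]])
}

#' Fit a bi-exponential decay to a fusion-event histogram
#'
#' Least-squares fit of `y0 + A1*exp(-t/tau1) + A2*exp(-t/tau2)` to the
#' (bin-center, probability) pairs over the full observation window.
#' Initialization is a variable-projection grid: for every pair of time
#' constants from a log-spaced grid the linear parameters (y0, A1, A2) are
#' solved exactly, and the best grid cells are polished with
#' Levenberg-Marquardt on all five parameters. Components are re-ordered so
#' `tau1_s >= tau2_s` (slow component first). The offset may be negative.
#'
#' @param hist A `vk_event_histogram`, or a data frame with columns `t` and
#'   `y`.
#' @param n_tau Number of grid time constants, log-spaced in
#'   `tau_range` (default 16 in [0.1, 100] s).
#' @param tau_range Range of grid time constants in seconds.
#' @param n_polish How many best grid starts to polish (default 4).
#' @return A `vk_biexp_fit`: list with the five parameters, `residual_ss`,
#'   `n_events`, `n_docked`, `degenerate` flag and the fitted data.
#' @export
fit_biexponential <- function(hist, n_tau = 16, tau_range = c(0.1, 100),
                              n_polish = 4) {
  if (inherits(hist, "vk_event_histogram")) {
    if (hist$n_events == 0) stop("empty histogram: nothing to fit", call. = FALSE)
    dat <- data.frame(t = hist$bins$bin_mid, y = hist$bins$prob)
    n_events <- hist$n_events; n_docked <- hist$n_docked
  } else {
    dat <- data.frame(t = hist$t, y = hist$y)
    n_events <- NA_integer_; n_docked <- NA_real_
  }
  if (sum(dat$y != 0) < 10) {
    warning("fewer than 10 non-empty bins; bi-exponential fit may be unreliable")
  }
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_tau))
  pairs <- expand.grid(tau1 = taus, tau2 = taus)
  pairs <- pairs[pairs$tau1 > pairs$tau2, ]

  lin_fit <- function(tau1, tau2) {
    X <- cbind(1, exp(-dat$t / tau1), exp(-dat$t / tau2))
    co <- tryCatch(stats::lm.fit(X, dat$y)$coefficients, error = function(e) NULL)
    if (is.null(co) || any(!is.finite(co))) return(list(ss = Inf, co = NULL))
    r <- dat$y - X %*% co
    list(ss = sum(r^2), co = co)
  }
  ss <- mapply(function(a, b) lin_fit(a, b)$ss, pairs$tau1, pairs$tau2)
  ord <- order(ss)[seq_len(min(n_polish, nrow(pairs)))]

  resid_fun <- function(par) {
    biexp_f(dat$t, list(y0 = par[1], A1 = par[2], tau1_s = exp(par[3]),
                        A2 = par[4], tau2_s = exp(par[5]))) - dat$y
  }
  best <- NULL; best_ss <- Inf
  for (j in ord) {
    lf <- lin_fit(pairs$tau1[j], pairs$tau2[j])
    if (is.null(lf$co)) next
    start <- c(lf$co[1], lf$co[2], log(pairs$tau1[j]), lf$co[3], log(pairs$tau2[j]))
    start <- pmin(pmax(start, .biexp_lower), .biexp_upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fun,
                         lower = .biexp_lower, upper = .biexp_upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssj <- sum(fit$fvec^2)
    if (ssj < best_ss) { best <- fit; best_ss <- ssj }
  }
  if (is.null(best)) {
    stop("bi-exponential fit failed to converge from all ", length(ord),
         " polished starts (grid best SS = ", signif(min(ss), 4), ")", call. = FALSE)
  }
  par <- unname(best$par)
  comp <- list(c(A = par[2], tau = exp(par[3])), c(A = par[4], tau = exp(par[5])))
  if (comp[[1]]["tau"] < comp[[2]]["tau"]) comp <- rev(comp)
  Amax <- max(abs(comp[[1]]["A"]), abs(comp[[2]]["A"]))
  degenerate <- min(abs(comp[[1]]["A"]), abs(comp[[2]]["A"])) < 1e-3 * Amax ||
    abs(comp[[1]]["tau"] - comp[[2]]["tau"]) < 0.05 * comp[[1]]["tau"]
  structure(list(y0 = unname(par[1]),
                 A1 = unname(comp[[1]]["A"]), tau1_s = unname(comp[[1]]["tau"]),
                 A2 = unname(comp[[2]]["A"]), tau2_s = unname(comp[[2]]["tau"]),
                 residual_ss = best_ss,
                 n_events = n_events, n_docked = n_docked,
                 degenerate = degenerate,
                 data = tibble::as_tibble(dat)),
            class = "vk_biexp_fit")
}

#' @export
print.vk_biexp_fit <- function(x, ...) {
  cat("<vk_biexp_fit> f(t) = ", signif(x$y0, 3), " + ", signif(x$A1, 3),
      " exp(-t/", signif(x$tau1_s, 3), ") + ", signif(x$A2, 3),
      " exp(-t/", signif(x$tau2_s, 3), ")\n", sep = "")
  cat("  residual SS: ", signif(x$residual_ss, 4),
      if (isTRUE(x$degenerate)) "  [degenerate: effectively single-exponential]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Fusion probability (events per docked vesicle)
#'
#' @param n_events Number of fusion events.
#' @param n_docked Number of docked vesicles (> 0).
#' @return `n_events / n_docked`.
#' @export
fusion_probability <- function(n_events, n_docked) {
  if (is.na(n_docked) || n_docked <= 0) {
    stop("n_docked must be positive", call. = FALSE)
  }
  n_events / n_docked
}
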