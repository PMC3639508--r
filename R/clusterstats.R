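#' Classification thresholds on the a.u. intensity scale
#'
#' Singles sit below 1.5 a.u. (the major peak of the spot-intensity
#' histogram corresponds to single docked vesicles), small clusters occupy
#' the high-intensity tail above 2 a.u. (up to ~6 a.u.). Spots falling in
#' the [1.5, 2) gap between the two published thresholds are reported as a
#' separate "intermediate" class and pooled with clusters in summary totals.
#'
#' @param single_max_au Upper bound of the singles class (default 1.5).
#' @param cluster_min_au Lower bound of the clusters class (default 2).
#' @param cluster_range_max_au Upper end of the small-cluster range
#'   (default 6; beyond it spots count as very large aggregates).
#' @return List of the three thresholds, validated.
#' @export
classifier_params <- function(single_max_au = 1.5, cluster_min_au = 2,
                              cluster_range_max_au = 6) {
  stopifnot(single_max_au > 0,
            single_max_au <= cluster_min_au,
            cluster_min_au <= cluster_range_max_au)
  list(single_max_au = single_max_au, cluster_min_au = cluster_min_au,
       cluster_range_max_au = cluster_range_max_au)
}

#' Classify spots into singles, intermediates and clusters
#'
#' @param spots Spot tibble with `intensity_au` populated.
#' @param params See [classifier_params()].
#' @return One-row tibble: `singles`, `intermediate`, `clusters`, `total`,
#'   and `clusters_pooled` (= intermediate + clusters).
#' @export
classify_spots <- function(spots, params = classifier_params()) {
  au <- spots$intensity_au
  stopifnot(!anyNA(au))
  singles <- sum(au < params$single_max_au)
  clusters <- sum(au >= params$cluster_min_au)
  inter <- length(au) - singles - clusters
  tibble::tibble(singles = singles, intermediate = inter, clusters = clusters,
                 clusters_pooled = inter + clusters, total = length(au))
}

#' Block-wise homogeneity of a vesicle-saturated surface
#'
#' Coefficient of variation of block-summed intensities over a grid of
#' non-overlapping blocks. A saturated, homogeneously covered DiD surface
#' passes when the CV is below the threshold.
#'
#' @param frame 2-D matrix (one DiD frame), larger than one block.
#' @param block_px Block edge length in pixels (default 128).
#' @param cv_max Pass threshold on the CV (default 0.2).
#' @return One-row tibble: `cv`, `n_blocks`, `pass`.
#' @export
surface_homogeneity <- function(frame, block_px = 128L, cv_max = 0.2) {
  if (length(dim(frame)) == 3L) frame <- frame[, , 1]
  frame <- unclass(frame)
  nby <- nrow(frame) %/% block_px
  nbx <- ncol(frame) %/% block_px
  if (nby * nbx < 2) stop("frame must contain at least two blocks", call. = FALSE)
  sums <- numeric(nby * nbx)
  idx <- 1L
  for (i in seq_len(nby)) {
    for (j in seq_len(nbx)) {
      sums[idx] <- sum(frame[((i - 1) * block_px + 1):(i * block_px),
                             ((j - 1) * block_px + 1):(j * block_px)])
      idx <- idx + 1L
    }
  }
  cv <- stats::sd(sums) / mean(sums)
  tibble::tibble(cv = cv, n_blocks = nby * nbx, pass = cv < cv_max)
}

#' Count v-/v-vesicle interactions across imaging locations
#'
#' For each rendered two-channel field the DiD surface must pass the
#' homogeneity check; DiI spots are then detected, normalized to a.u.,
#' large spots are excluded, and the kept count per location is aggregated
#' with [count_per_fov()].
#'
#' @param fields List of fields from [render_clustering_field()].
#' @param psf_sigma_px PSF sigma used for detection (default: first field's).
#' @param k_thresh,min_sep_px Detection parameters, see [detect_spots()].
#' @param max_au,max_area_px Exclusion parameters, see
#'   [exclude_large_spots()].
#' @return One-row tibble from [count_per_fov()].
#' @export
count_vv_interactions <- function(fields, psf_sigma_px = NULL,
                                  k_thresh = 5, min_sep_px = 3,
                                  max_au = 6, max_area_px = 39L) {
  counts <- purrr::imap_dbl(fields, function(fld, i) {
    hom <- surface_homogeneity(fld$DiD[, , 1])
    if (!hom$pass) {
      stop("DiD surface of field ", i, " failed the homogeneity check (CV = ",
           signif(hom$cv, 3), ")", call. = FALSE)
    }
    sig <- psf_sigma_px %||% attr(fld$DiI, "psf_sigma_px")
    spots <- detect_spots(fld$DiI[, , 1], psf_sigma_px = sig,
                          k_thresh = k_thresh, min_sep_px = min_sep_px,
                          fov_id = paste0("loc", i))
    if (nrow(spots) == 0) return(0)
    spots <- suppressWarnings(normalize_au(spots))
    nrow(exclude_large_spots(spots, max_au = max_au,
                             max_area_px = max_area_px)$kept)
  })
  count_per_fov(counts)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical equal-variance two-sample t statistic with pooled variance,
#' `df = N1 + N2 - 2`, two-tailed p from the t distribution. Stars follow
#' the publication convention (*** p < 0.001, ** p < 0.01, * p < 0.05).
#'
#' @param a,b Numeric vectors of per-location counts (each N >= 2).
#' @param labels Length-2 character vector of condition labels.
#' @return One-row tibble: labels, per-group N/mean/sd, `t`, `df`, `p`,
#'   `stars`, `degenerate`.
#' @export
students_t <- function(a, b, labels = c("a", "b")) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  degenerate <- FALSE
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      tstat <- 0; p <- 1
    } else {
      tstat <- NA_real_; p <- NA_real_; degenerate <- TRUE
      warning("zero pooled variance with unequal means: t undefined")
    }
  } else {
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  stars <- if (is.na(p)) NA_character_
           else if (p < 0.001) "***"
           else if (p < 0.01) "**"
           else if (p < 0.05) "*"
           else "ns"
  tibble::tibble(condition_a = labels[1], condition_b = labels[2],
                 n_a = n1, mean_a = mean(a), sd_a = stats::sd(a),
                 n_b = n2, mean_b = mean(b), sd_b = stats::sd(b),
                 t = tstat, df = df, p = p, stars = stars,
                 degenerate = degenerate)
}

#' Expected free-particle count under finite-volume depletion
#'
#' When a fixed budget of vesicles clusters, the number of free-floating
#' particles (single vesicles or clusters) available to dock drops by the
#' mean cluster size: `particles = n_vesicles / E[k]`. This is the
#' mass-balance explanation for fewer v-/t-vesicle associations in a finite
#' sample volume when clustering is switched on.
#'
#' @param n_vesicles Total vesicle budget (> 0).
#' @param cluster_size_law Probability mass over multiplicity k >= 1,
#'   summing to 1.
#' @return Expected particle count.
#' @export
depletion_spot_count <- function(n_vesicles, cluster_size_law) {
  stopifnot(n_vesicles > 0,
            abs(sum(cluster_size_law) - 1) < 1e-8,
            all(cluster_size_law >= 0))
  ek <- sum(seq_along(cluster_size_law) * cluster_size_law)
  n_vesicles / ek
}

#' Anti-correlation report between clustering and association counts
#'
#' Pairs per-condition mean v-/v clustering counts with mean v-/t
#' association counts and computes the Spearman rank correlation across
#' conditions; only the ordinal structure (more clustering, fewer free
#' particles to associate) is claimed, so a rank correlation is used. For
#' the published condition panel the expected sign is negative.
#'
#' @param clustering Tibble with columns `condition` and `mean` (v-/v
#'   clustering counts).
#' @param associations Tibble with columns `condition` and `mean` (v-/t
#'   association counts).
#' @return List with `table` (paired per-condition means) and
#'   `spearman_rho`.
#' @export
anticorrelation_report <- function(clustering, associations) {
  if (!setequal(clustering$condition, associations$condition)) {
    stop("condition sets differ between clustering and association inputs",
         call. = FALSE)
  }
  tab <- dplyr::inner_join(
    dplyr::select(clustering, "condition", clustering_mean = "mean"),
    dplyr::select(associations, "condition", association_mean = "mean"),
    by = "condition")
  rho <- stats::cor(tab$clustering_mean, tab$association_mean,
                    method = "spearman")
  list(table = tab, spearman_rho = rho)
}

#' Percent lipid-bound protein from a flotation gradient
#'
#' Eight fractions are collected from top to bottom of the gradient; the top
#' two are defined as lipid-bound and quantitated as percent of the total
#' signal.
#'
#' @param fraction_signals Numeric vector of exactly 8 non-negative signals,
#'   top fraction first.
#' @return Percent bound (0-100).
#' @export
flotation_percent_bound <- function(fraction_signals) {
  stopifnot(length(fraction_signals) == 8, all(fraction_signals >= 0))
  if (sum(fraction_signals) == 0) {
    stop("all fraction signals are zero", call. = FALSE)
  }
  100 * sum(fraction_signals[1:2]) / sum(fraction_signals)
}

#' Simulated dose-response of v-/v clustering counts
#'
#' Renders `n_locations` clustering fields per concentration preset, counts
#' DiI spots per location, and tests each concentration against the first
#' (the zero-concentration control) with [students_t()].
#'
#' @param presets Named list of `cluster_*` presets ordered by increasing
#'   concentration; the first element is the control.
#' @param concentrations Numeric vector of concentrations (uM), same length.
#' @param n_locations Imaging locations per condition (default 10).
#' @param surface_preset Preset for the DiD surface layer.
#' @param seed Base RNG seed; location seeds are derived from it.
#' @return Tibble: `condition`, `concentration_uM`, `n_locations`, `mean`,
#'   `sd`, `t`, `df`, `p`, `stars` (t columns NA for the control row).
#' @export
dose_response_table <- function(presets, concentrations,
                                n_locations = 10,
                                surface_preset = make_preset("saturated_surface"),
                                seed = 1L) {
  stopifnot(length(presets) >= 2, length(presets) == length(concentrations))
  counts <- purrr::imap(presets, function(p, nm) {
    fields <- lapply(seq_len(n_locations), function(i) {
      render_clustering_field(surface_preset, p,
                              seed = seed + 1000L * match(nm, names(presets)) + i)
    })
    count_vv_interactions(fields)
  })
  ctrl <- counts[[1]]$counts[[1]]
  rows <- purrr::imap(counts, function(fc, nm) {
    i <- match(nm, names(presets))
    row <- tibble::tibble(condition = nm,
                          concentration_uM = concentrations[i],
                          n_locations = fc$n_locations,
                          mean = fc$mean, sd = fc$sd,
                          t = NA_real_, df = NA_real_, p = NA_real_,
                          stars = NA_character_)
    if (i > 1) {
      tt <- students_t(fc$counts[[1]], ctrl, labels = c(nm, names(presets)[1]))
      row$t <- tt$t; row$df <- tt$df; row$p <- tt$p; row$stars <- tt$stars
    }
    row
  })
  dplyr::bind_rows(rows)
}
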