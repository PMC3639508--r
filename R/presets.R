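#' Experimental condition presets
#'
#' A preset bundles every parameter the synthetic generator needs to emulate
#' one experimental condition of the single-vesicle assays: expected docked
#' spot count per field, per-spot fusion probability and (for the seeded
#' fusion fixtures) the exact planted event total, the bi-exponential
#' event-time model, the vesicle cluster-size law, the optical model and the
#' camera noise model.
#'
#' Two families exist. Fusion presets (`fusion_*`) describe the
#' content-mixing assay: self-quenched content dye in docked v-vesicles, a
#' stepwise ~2x dequenching upon Ca2+-triggered fusion, a 50-s observation
#' window binned at 1 s. Clustering presets (`cluster_*`) describe the
#' two-colour v-/v-vesicle clustering assay: a saturated DiD-labeled surface
#' layer and free-floating DiI-labeled vesicles whose bound count reflects
#' the clustering activity of the condition. `saturated_surface` is the DiD
#' layer itself.
#'
#' The fusion presets carry the published kinetic fit parameters and
#' event/docked ratios for the no-alpha-synuclein and 2 uM alpha-synuclein
#' conditions. The clustering presets encode the relative contrasts of the
#' condition panel: the A30P Parkinson's-disease mutant halves the
#' clustering efficiency of matched wildtype, E46K and A53T match wildtype,
#' and removing synaptobrevin-2, anionic lipid, or the synaptobrevin-binding
#' C-terminus of alpha-synuclein (1-95 truncation) drops clustering to the
#' no-protein background.
#'
#' @param name One of [preset_names()].
#' @param overrides Named list of fields to override in the returned preset
#'   (nested lists such as `optics` and `noise` are merged field-wise).
#' @return An object of class `vk_preset`: a named list with fields `name`,
#'   `kind` ("fusion", "cluster" or "surface"), `n_docked`, `p_fusion`,
#'   `n_events`, `kinetic_params` (y0, A1, tau1_s, A2, tau2_s),
#'   `cluster_size_law`, `clustering_efficiency`, `large_aggregate_rate`,
#'   `dequench_factor`, `baseline`, `optics`, `noise`, `seed`.
#' @examples
#' p <- make_preset("fusion_noSyn")
#' p$kinetic_params
#' make_preset("cluster_A30P")$clustering_efficiency /
#'   make_preset("cluster_WT_20uM")$clustering_efficiency
#' @export
make_preset <- function(name, overrides = list()) {
  if (length(name) != 1L || !is.character(name) || !name %in% preset_names()) {
    stop("Unknown preset '", paste(name, collapse = ","), "'. Valid presets: ",
         paste(preset_names(), collapse = ", "), call. = FALSE)
  }
  p <- .preset_table()[[name]]
  if (length(overrides)) {
    for (nm in names(overrides)) {
      if (is.list(overrides[[nm]]) && is.list(p[[nm]])) {
        p[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
      } else {
        p[[nm]] <- overrides[[nm]]
      }
    }
  }
  validate_preset(p)
}

#' Names of the documented condition presets
#' @return Character vector of valid preset names.
#' @export
preset_names <- function() {
  c("fusion_noSyn", "fusion_Syn2uM",
    "cluster_noSyn", "cluster_WT_2uM", "cluster_WT_20uM",
    "cluster_A30P", "cluster_E46K", "cluster_A53T",
    "cluster_noSyb2", "cluster_PConly", "cluster_Syn1-95",
    "saturated_surface")
}

# Shared optical / camera model: Gaussian PSF point emitters on a 512x512
# 16-bit field, constant background + Poisson shot noise + Gaussian read
# noise. Single-vesicle integrated flux 12000 counts over background 100.
.default_optics <- function(n_pre_frames = 5L, n_frames = 56L) {
  list(psf_sigma_px = 1.5, field_size_px = 512L, frame_interval_s = 1,
       n_frames = as.integer(n_frames), n_pre_frames = as.integer(n_pre_frames),
       min_sep_factor = 4, margin_px = 12L)
}

.default_noise <- function() {
  list(background = 100, shot_noise = TRUE, read_noise_sd = 2)
}

.singles_law <- function() c(1, 0, 0, 0, 0, 0)

.fusion_preset <- function(name, n_docked, n_events, kin, seed) {
  list(name = name, kind = "fusion",
       n_docked = n_docked, n_events = as.integer(n_events),
       p_fusion = n_events / n_docked,
       kinetic_params = kin,
       cluster_size_law = .singles_law(),
       clustering_efficiency = NA_real_,
       large_aggregate_rate = 0,
       dequench_factor = 2,
       baseline = 12000,
       optics = .default_optics(),
       noise = .default_noise(),
       seed = seed)
}

.cluster_preset <- function(name, efficiency, mean_k, aggregate_rate, seed) {
  law <- if (mean_k <= 1) .singles_law() else cluster_law_geometric(mean_k)
  list(name = name, kind = "cluster",
       n_docked = efficiency, n_events = NULL, p_fusion = 0,
       kinetic_params = c(y0 = 0, A1 = 0, tau1_s = 27.1, A2 = 0, tau2_s = 0.58),
       cluster_size_law = law,
       clustering_efficiency = efficiency,
       large_aggregate_rate = aggregate_rate,
       dequench_factor = 2,
       baseline = 12000,
       optics = .default_optics(n_pre_frames = 0L, n_frames = 1L),
       noise = .default_noise(),
       seed = seed)
}

.preset_table <- function() {
  kin_noSyn <- c(y0 = -0.0046, A1 = 0.048, tau1_s = 27.1, A2 = 0.26, tau2_s = 0.58)
  kin_Syn   <- c(y0 = -0.001,  A1 = 0.064, tau1_s = 15.4, A2 = 0.22, tau2_s = 0.51)
  surface <- .cluster_preset("saturated_surface", efficiency = 1800,
                             mean_k = 1, aggregate_rate = 0, seed = 301L)
  surface$kind <- "surface"
  list(
    fusion_noSyn  = .fusion_preset("fusion_noSyn", 2000, 166L, kin_noSyn, 101L),
    fusion_Syn2uM = .fusion_preset("fusion_Syn2uM", 1300, 84L, kin_Syn, 102L),
    cluster_noSyn    = .cluster_preset("cluster_noSyn",    50, 1.0, 0, 201L),
    cluster_WT_2uM   = .cluster_preset("cluster_WT_2uM",  150, 1.5, 2, 202L),
    cluster_WT_20uM  = .cluster_preset("cluster_WT_20uM", 300, 2.0, 3, 203L),
    cluster_A30P     = .cluster_preset("cluster_A30P",    150, 1.5, 1, 204L),
    cluster_E46K     = .cluster_preset("cluster_E46K",    300, 2.0, 3, 205L),
    cluster_A53T     = .cluster_preset("cluster_A53T",    300, 2.0, 3, 206L),
    cluster_noSyb2   = .cluster_preset("cluster_noSyb2",   50, 1.0, 0, 207L),
    cluster_PConly   = .cluster_preset("cluster_PConly",   50, 1.0, 0, 208L),
    `cluster_Syn1-95` = .cluster_preset("cluster_Syn1-95", 50, 1.0, 0, 209L),
    saturated_surface = surface
  )
}

#' Truncated geometric cluster-size law
#'
#' Probability mass over vesicle multiplicity k = 1..k_max proportional to
#' (1-p)^(k-1), with p chosen so the law has the requested mean. Matches the
#' decaying cluster tail seen in spot-intensity histograms, truncated at the
#' upper end of the observed cluster range (6 a.u.); very large aggregates
#' are modeled as a separate rare process.
#'
#' @param mean_k Target mean multiplicity, in (1, (1 + k_max) / 2).
#' @param k_max Truncation point (default 6).
#' @return Numeric vector of length `k_max` summing to 1.
#' @export
cluster_law_geometric <- function(mean_k, k_max = 6L) {
  stopifnot(mean_k > 1, mean_k < (1 + k_max) / 2)
  k <- seq_len(k_max)
  mean_of <- function(q) {
    w <- q ^ (k - 1)
    sum(k * w) / sum(w)
  }
  q <- stats::uniroot(function(q) mean_of(q) - mean_k,
                      interval = c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  w <- q ^ (k - 1)
  w / sum(w)
}

validate_preset <- function(p) {
  stopifnot(is.list(p), !is.null(p$name))
  law <- p$cluster_size_law
  if (abs(sum(law) - 1) > 1e-8 || any(law < 0)) {
    stop("cluster_size_law must be a non-negative vector summing to 1", call. = FALSE)
  }
  if (p$p_fusion < 0 || p$p_fusion > 1) stop("p_fusion must lie in [0, 1]", call. = FALSE)
  kp <- p$kinetic_params
  if (!(kp[["tau1_s"]] > kp[["tau2_s"]] && kp[["tau2_s"]] > 0)) {
    stop("kinetic time constants must satisfy tau1_s > tau2_s > 0", call. = FALSE)
  }
  if (p$optics$psf_sigma_px <= 0) stop("psf_sigma_px must be positive", call. = FALSE)
  if (p$n_docked < 0 || p$large_aggregate_rate < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(p, class = "vk_preset")
}

#' @export
print.vk_preset <- function(x, ...) {
  cat("<vk_preset> ", x$name, " (", x$kind, ")\n", sep = "")
  cat("  n_docked: ", x$n_docked, "  p_fusion: ", signif(x$p_fusion, 4), "\n", sep = "")
  cat("  kinetics (y0, A1, tau1, A2, tau2): ",
      paste(signif(x$kinetic_params, 4), collapse = ", "), "\n", sep = "")
  cat("  E[cluster size]: ",
      signif(sum(seq_along(x$cluster_size_law) * x$cluster_size_law), 4),
      "  aggregates/field: ", x$large_aggregate_rate, "\n", sep = "")
  cat("  field: ", x$optics$field_size_px, "px, frames: ", x$optics$n_frames,
      " (", x$optics$n_pre_frames, " pre-trigger), seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
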