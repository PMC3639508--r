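# Scaled-down presets used across tests: same physics (PSF, noise, flux) as
# the full study conditions, smaller fields and counts so tests stay fast.
small_fusion_preset <- function(n_docked = 150, n_events = 30L, ...) {
  make_preset("fusion_noSyn",
              overrides = c(list(n_docked = n_docked, n_events = n_events,
                                 optics = list(field_size_px = 256L)),
                            list(...)))
}

small_cluster_preset <- function(name = "cluster_WT_20uM", n_docked = 80) {
  make_preset(name, overrides = list(n_docked = n_docked,
                                     clustering_efficiency = n_docked,
                                     optics = list(field_size_px = 256L)))
}

small_surface_preset <- function() {
  make_preset("saturated_surface",
              overrides = list(n_docked = 450, clustering_efficiency = 450,
                               optics = list(field_size_px = 256L)))
}

# Noiseless single-frame field with Gaussian spots planted at given centers
# (0-based coords), flux-normalized amplitudes; background added separately.
plant_field <- function(centers, flux = 12000, sigma = 1.5, size = 128,
                        background = 0) {
  f <- matrix(background, size, size)
  for (i in seq_len(nrow(centers))) {
    gp <- vesiclekit:::gaussian_patch(centers[i, 1], centers[i, 2], sigma, size)
    f[gp$ys, gp$xs] <- f[gp$ys, gp$xs] + flux[min(i, length(flux))] * gp$patch
  }
  f
}
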