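# shared fixture builders (everything is generated in code)

OMEGA80 <- omega_from_period(12.5)   # first harmonic of an 80 MHz source

single_cell_scene <- function(alpha, tau, rate = 1e4, n_bins = 256L,
                              size = 24L, radius = 8, bg = 0, seed = 1L,
                              noise = FALSE, mito_fraction = 0.3,
                              mito_contrast = 4, fad_rate = max(rate / 3, 1)) {
  sp <- scene_spec(
    image_size = c(size, size),
    cells = list(list(center = c(size / 2, size / 2), radius_px = radius,
                      true_alpha_bound = alpha, true_tau_bound = tau,
                      nadph_rate = rate, fad_rate = fad_rate,
                      mito_fraction = mito_fraction,
                      mito_contrast = mito_contrast)),
    background_rate = bg, n_time_bins = n_bins, seed = seed)
  simulate_decay_image(sp, noise = noise)
}

# a one-pixel phasor_map at given coordinates
point_phasor <- function(g, s, omega = OMEGA80) {
  structure(list(g = matrix(g), s = matrix(s), valid = matrix(TRUE),
                 total_photons = matrix(1), harmonic = 1L, omega = omega,
                 laser_period_ns = 2 * pi / omega),
            class = "phasor_map")
}

# benchmark staged populations: 10 informative monotone features (stage means
# spaced 2 SDs apart, direction fixed per feature) + 10 pure-noise features
population_benchmark_spec <- function(seed, signs) {
  means <- cbind(sapply(signs, function(sg) sg * seq(0, 6, length.out = 4)),
                 matrix(0, 4, 10))
  colnames(means) <- sprintf("feat_%02d", 1:20)
  population_spec(n_stages = 4, cells_per_stage = 200, feature_means = means,
                  monotone_mask = c(rep(TRUE, 10), rep(FALSE, 10)),
                  noise_sd = 1, seed = seed)
}
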