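# Small reduced-grid configurations shared across tests. The tiny grids keep
# synthesis and network passes fast; the full-size tensor contract is checked
# separately in the acceptance tests.

tiny_sim <- function(...) {
  sim_config(n_peaks_min = 3, n_peaks_max = 8,
             n_c_min = 12, n_c_max = 16, n_h_min = 12, n_h_max = 16,
             zf_c = 16, zf_h = 16, ...)
}

clean_sim <- function(...) {
  tiny_sim(noise_sd_frac = 0, phase_max_deg = 0, solvent = FALSE, ...)
}

tiny_net <- function(...) {
  network_config(width = 4, depth_time = 2, depth_freq = 1,
                 zf_c = 16, zf_h = 16, batch_size = 2, ...)
}

# one singlet spin system at given offsets, no couplings or roofing
singlet_system <- function(delta_c = 0, delta_h = 0, intensity = 1,
                           r2c = 20, r2h = 20) {
  data.frame(delta_c = delta_c, delta_h0 = delta_h, delta_h = delta_h,
             intensity = intensity, r2c_in = r2c, r2c_tar = r2c / 2,
             r2h = r2h, j1c = 0, j2c = 0, j1h = 0, j2h = 0,
             rho1c = 0, rho2c = 0, rho1h = 0, rho2h = 0)
}
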