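# Shared spectral fixtures, generated in code.

# gently curved additive background emulating fluorescence/scattering
curved_baseline_knots <- c(600, 900, 1200, 1500, 1800)
curved_baseline_values <- c(1.2, 0.9, 0.75, 0.55, 0.5)

# wavenumber windows free of library bands (between the heme markers)
quiet_windows <- function(wavenumber) {
  (wavenumber >= 820 & wavenumber <= 1090) |
    (wavenumber >= 1430 & wavenumber <= 1510)
}

noiseless_mixture <- function(f_red, ...) mixture_spectrum(f_red, ...)

noisy_curved_mixture <- function(f_red, noise_sd, seed) {
  mixture_spectrum(f_red,
                   baseline_knots = curved_baseline_knots,
                   baseline_values = curved_baseline_values,
                   noise_sd = noise_sd, seed = seed)
}
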