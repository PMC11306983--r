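# Shared fixtures: the two-solution BSA experiment conditions and small
# synthetic scenes, built in code at test time.

bsa_fractions <- function() {
  phase_fractions(c_conc = 334, c_dilute = 50, density = 1.41)
}

# default noiseless scene on the 10-70 cm^-1 analysis window
noiseless_scene <- function(...) {
  make_scene(noise_sd = 0, seed = 7, ...)
}

# random physical complex permittivities (passive: Im >= 0, Re > 0)
random_eps <- function(n, re = c(2, 8), im = c(0, 6)) {
  complex(real = stats::runif(n, re[1L], re[2L]),
          imaginary = stats::runif(n, im[1L], im[2L]))
}
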