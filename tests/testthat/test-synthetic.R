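test_that("Debye relaxation hits its closed-form landmarks", {
  c_cm <- 2.99792458e10
  tau_ps <- 8
  # wavenumber where omega * tau = 1: the loss peak of a single band
  nu_peak <- 1 / (2 * pi * c_cm * tau_ps * 1e-12)
  m <- relaxation_model(2.5, debye = list(debye_term(10, tau_ps)))
  sp <- relaxation_spectrum(c(nu_peak, 1000), m)
  expect_equal(sp$eps_im[1L], 10 / 2, tolerance = 1e-9)
  expect_equal(sp$eps_re[1L], 2.5 + 10 / 2, tolerance = 1e-9)
  # high-frequency limit approaches eps_inf
  expect_equal(sp$eps_re[2L], 2.5, tolerance = 1e-2)
  # static limit: eps_inf + sum(delta_eps)
  lo <- relaxation_spectrum(c(1e-6, 1), m)
  expect_equal(lo$eps_re[1L], 12.5, tolerance = 1e-6)
})

test_that("water-like two-band model is positive-loss and hand-checkable", {
  w <- water_model()
  sp <- relaxation_spectrum(seq(10, 70, by = 2), w)
  expect_true(all(sp$eps_im > 0))
  # independent term-by-term evaluation at 30 cm^-1
  omega <- 2 * pi * 2.99792458e10 * 30
  hand <- w$eps_inf +
    w$debye[[1L]]$delta_eps / (1 - 1i * omega * w$debye[[1L]]$tau_ps * 1e-12) +
    w$debye[[2L]]$delta_eps / (1 - 1i * omega * w$debye[[2L]]$tau_ps * 1e-12)
  at30 <- relaxation_spectrum(c(10, 30), w)
  expect_equal(at30$eps_re[2L], Re(hand), tolerance = 1e-12)
  expect_equal(at30$eps_im[2L], Im(hand), tolerance = 1e-12)
})

test_that("oscillator bands add Lorentzian structure with positive loss", {
  m <- relaxation_model(2, oscillators = list(c(1.5, 40, 15)))
  sp <- relaxation_spectrum(seq(10, 90, by = 1), m)
  expect_true(all(sp$eps_im >= 0))
  # loss maximal near the center frequency
  expect_equal(sp$wavenumber[which.max(sp$eps_im)], 40, tolerance = 3)
  expect_error(relaxation_model(2, oscillators = list(c(1.5, -40, 15))),
               "positive")
})

test_that("shell model retards and rescales the water bands", {
  w <- water_model()
  same <- make_shell_model(w, 1, 1)
  g <- seq(10, 70, by = 5)
  expect_equal(relaxation_spectrum(g, same), relaxation_spectrum(g, w))
  sh <- make_shell_model(w, slow_factor = 2, strength_factor = 1)
  expect_equal(sh$debye[[1L]]$tau_ps, 2 * w$debye[[1L]]$tau_ps)
  # retardation halves the loss-peak position in frequency
  c_cm <- 2.99792458e10
  one <- relaxation_model(3, debye = list(debye_term(10, 4)))
  two <- make_shell_model(one, slow_factor = 2)
  nu <- seq(0.1, 50, by = 0.01)
  p1 <- nu[which.max(relaxation_spectrum(nu, one)$eps_im)]
  p2 <- nu[which.max(relaxation_spectrum(nu, two)$eps_im)]
  expect_equal(p2 / p1, 0.5, tolerance = 0.01)
  # defaults produce a shell distinct from bulk water on the window
  shd <- make_shell_model(w)
  dw <- relaxation_spectrum(g, w); dsh <- relaxation_spectrum(g, shd)
  expect_true(all(abs(dw$eps_im - dsh$eps_im) > 0))
})

test_that("scenes are deterministic and satisfy the forward residuals", {
  s1 <- make_scene(noise_sd = 0.01, seed = 12)
  s2 <- make_scene(noise_sd = 0.01, seed = 12)
  expect_identical(s1, s2)
  s3 <- make_scene(noise_sd = 0.01, seed = 13)
  expect_false(identical(s1$observed, s3$observed))
  fr <- s1$fractions
  ep <- eps_complex(s1$truth_p); esh <- eps_complex(s1$truth_sh)
  ew <- eps_complex(s1$truth_w)
  expect_lt(max(Mod(bruggeman2_residual(
    ep, esh, eps_complex(s1$derived_cs), fr$f_p))), 1e-10)
  expect_lt(max(Mod(bruggeman3_residual(
    ep, esh, ew, eps_complex(s1$derived_s), fr$f, fr$f_sh))), 1e-10)
  # noiseless scene: observed equals derived exactly
  s0 <- make_scene(noise_sd = 0)
  expect_equal(s0$observed$dilute$eps_re, s0$derived_s$eps_re)
  expect_equal(s0$observed$concentrated$eps_im, s0$derived_cs$eps_im)
  # all generated truths are passive
  expect_true(all(s1$truth_p$eps_im >= 0))
  expect_true(all(s1$truth_sh$eps_im >= 0))
  expect_true(all(s1$truth_w$eps_im >= 0))
})

test_that("roundtrip report quantifies recovery per solver", {
  sc <- noiseless_scene()
  rep <- roundtrip_report(sc)
  expect_setequal(unique(rep$per_frequency$solver), c("reduced", "full"))
  full <- rep$aggregate[rep$aggregate$solver == "full", ]
  red <- rep$aggregate[rep$aggregate$solver == "reduced", ]
  expect_lt(full$max_rel_err, 1e-8)
  # reduced solver carries the bias of the neglected protein term
  expect_gt(red$max_rel_err, full$max_rel_err)
  # noisy scene: finite errors, report only
  noisy <- roundtrip_report(make_scene(noise_sd = 0.01, seed = 2),
                            solver = "reduced")
  expect_true(all(is.finite(noisy$per_frequency$rel_err_mod)))
})
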