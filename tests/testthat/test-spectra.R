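test_that("frequency grid and spectrum invariants are enforced", {
  expect_error(frequency_grid(5), "at least two")
  expect_error(frequency_grid(c(10, 10)), "strictly increasing")
  expect_error(frequency_grid(c(-1, 10)), "strictly positive")
  expect_error(optical_spectrum(c(10, 20), c(2, -1), c(0, 0)), "positive")
  expect_error(optical_spectrum(c(10, 20), c(2, 2), c(-1, 0)), "non-negative")
  expect_error(optical_spectrum(c(10, 20), c(2, 2, 2), c(0, 0, 0)),
               "same length")
  expect_error(dielectric_spectrum(c(10, 20), c(4, 4), c(-0.1, 0)),
               "passive")
  # NA markers admitted only off the strict path
  expect_silent(dielectric_spectrum(c(10, 20), c(4, NA), c(0, NA),
                                    check_passive = FALSE))
})

test_that("absorption from transmission follows the natural-log law", {
  expect_identical(absorption_from_transmission(1, 0.5), 0)
  expect_equal(absorption_from_transmission(exp(-1), 1), 1)
  # 50.48 um difference layer, half transmission
  expect_equal(absorption_from_transmission(0.5, 50.48e-4),
               log(2) / 50.48e-4, tolerance = 1e-12)
  expect_equal(round(absorption_from_transmission(0.5, 50.48e-4), 1), 137.3)
  expect_error(absorption_from_transmission(c(0.5, 0), 1), "index 2")
  expect_error(absorption_from_transmission(1.2, 1), "\\(0, 1\\]")
  expect_error(absorption_from_transmission(0.5, -1), "positive")
})

test_that("optical constants convert to permittivity by the standard ratios", {
  # lossless limit
  lossless <- optical_spectrum(c(10, 30), c(2, 2), c(0, 0))
  d <- permittivity_from_optical(lossless)
  expect_equal(d$eps_re, c(4, 4))
  expect_equal(d$eps_im, c(0, 0))
  # direct evaluation at nu = 30 cm^-1, n = 2.2, alpha = 100 cm^-1
  opt <- optical_spectrum(c(10, 30), c(2.2, 2.2), c(100, 100))
  d <- permittivity_from_optical(opt)
  expect_equal(d$eps_im[2L], 2.2 * 100 / (2 * pi * 30), tolerance = 1e-12)
  expect_equal(d$eps_re[2L], 2.2^2 - (100 / (4 * pi * 30))^2,
               tolerance = 1e-12)
  expect_equal(round(d$eps_im[2L], 3), 1.167)
  expect_equal(round(d$eps_re[2L], 3), 4.770)
})

test_that("optical <-> permittivity roundtrip is the identity", {
  set.seed(11)
  for (k in 1:20) {
    wn <- sort(stats::runif(15, 5, 110))
    opt <- optical_spectrum(wn, stats::runif(15, 1.2, 3),
                            stats::runif(15, 0, 300))
    back <- optical_from_permittivity(permittivity_from_optical(opt))
    expect_equal(back$n, opt$n, tolerance = 1e-12)
    expect_equal(back$alpha, opt$alpha, tolerance = 1e-12)
  }
  # inverse direction, including a metallic-like eps_re < 0 point
  d <- dielectric_spectrum(c(10, 30), c(-2, 4.769641), c(3, 1.167137))
  o <- optical_from_permittivity(d)
  expect_true(all(o$n > 0) && all(o$alpha > 0))
  rt <- permittivity_from_optical(o)
  expect_equal(rt$eps_re, d$eps_re, tolerance = 1e-12)
  expect_equal(rt$eps_im, d$eps_im, tolerance = 1e-12)
  expect_equal(o$n[2L], 2.2, tolerance = 1e-5)
  expect_equal(o$alpha[2L], 100, tolerance = 1e-3)
  expect_error(optical_from_permittivity(
    dielectric_spectrum(c(10, 20), c(4, 4), c(-1, 0),
                        check_passive = FALSE)), "unphysical")
})

test_that("loss vanishes exactly iff absorption vanishes", {
  opt <- optical_spectrum(c(10, 20, 30), c(2, 2.2, 2.4), c(0, 50, 0))
  d <- permittivity_from_optical(opt)
  expect_identical(d$eps_im == 0, opt$alpha == 0)
  back <- optical_from_permittivity(d)
  expect_identical(back$alpha == 0, opt$alpha == 0)
})

test_that("CSV io preserves both dialects and rejects malformed files", {
  dir <- withr::local_tempdir()
  d <- dielectric_spectrum(c(10, 20, 30), c(4.1, 4.2, 4.3), c(1, 2, 3))
  p1 <- file.path(dir, "diel.csv")
  write_spectrum(d, p1)
  rd <- read_spectrum(p1)
  expect_s3_class(rd, "dielectric_spectrum")
  expect_equal(as.data.frame(rd), as.data.frame(d))
  o <- optical_spectrum(c(10, 20, 30), c(2, 2.1, 2.2), c(0, 5, 10))
  p2 <- file.path(dir, "opt.csv")
  write_spectrum(o, p2)
  ro <- read_spectrum(p2)
  expect_s3_class(ro, "optical_spectrum")
  expect_equal(as.data.frame(ro), as.data.frame(o))
  expect_error(read_spectrum(p2, dialect = "dielectric"), "optical")
  # descending grid rejected at the invariant
  writeLines(c("wavenumber_cm-1,eps_real,eps_imag",
               "30,4,1", "20,4,1", "10,4,1"), p1)
  expect_error(read_spectrum(p1), "strictly increasing")
  writeLines(c("wavenumber_cm-1,foo,bar", "10,1,1", "20,1,1"), p1)
  expect_error(read_spectrum(p1), "unrecognized")
})

test_that("grid alignment interpolates onto the intersection, never beyond", {
  a <- dielectric_spectrum(c(10, 20, 30), c(4, 5, 6), c(1, 2, 3))
  b <- dielectric_spectrum(seq(5, 40, by = 5), seq(4, 11, by = 1),
                           rep(1, 8))
  al <- align_grids(a, b)
  expect_equal(al[[1L]]$wavenumber, c(10, 20, 30))
  expect_equal(al[[2L]]$wavenumber, c(10, 20, 30))
  expect_equal(as.data.frame(al[[1L]]), as.data.frame(a))
  expect_equal(al[[2L]]$eps_re, c(5, 7, 9))  # linear in wavenumber
  # identical grids pass through unchanged
  same <- align_grids(a, a)
  expect_equal(as.data.frame(same[[2L]]), as.data.frame(a))
  disjoint <- dielectric_spectrum(c(50, 60), c(4, 4), c(1, 1))
  expect_error(align_grids(a, disjoint), "overlap")
})
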