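test_that("full residual exposes the three terms consistently", {
  fr <- bsa_fractions()
  e0 <- 4.6 + 2.3i
  r <- full_residual(e0, e0, e0, e0, fr)
  expect_equal(r$residual, 0 + 0i, tolerance = 1e-14)
  # term 1 is exactly the protein term of the three-phase rule
  ep <- 3 + 1i; ew <- 4.4 + 5.6i; es <- 4.5 + 5.4i; ecs <- 4.8 + 4.9i
  r <- full_residual(ep, ew, es, ecs, fr)
  expect_equal(r$t1, fr$f * (ep - es) / (ep + 2 * es), tolerance = 1e-14)
  # residual equals the three-phase residual with the implied shell
  esh <- shell_from_concentrated(ep, ecs, fr$f_p)
  expect_equal(r$residual,
               bruggeman3_residual(ep, esh, ew, es, fr$f, fr$f_sh),
               tolerance = 1e-13)
  expect_equal(r$residual, r$t1 + r$t2 + r$t3, tolerance = 1e-14)
})

test_that("reduced solver is closed-form, unique, and kills terms 2+3", {
  fr <- bsa_fractions()
  e0 <- 4.9 + 2.8i
  expect_equal(solve_protein_reduced(e0, e0, e0, fr), e0,
               tolerance = 1e-12)
  sc <- noiseless_scene()
  ew <- eps_complex(sc$truth_w)
  es <- eps_complex(sc$derived_s); ecs <- eps_complex(sc$derived_cs)
  ep <- solve_protein_reduced(ew, es, ecs, fr)
  r <- full_residual(ep, ew, es, ecs, fr)
  expect_lt(max(Mod(r$t2 + r$t3)), 1e-12)
  # |T1| bounds the residual at the reduced output by construction
  expect_equal(r$residual, r$t1, tolerance = 1e-12)
})

test_that("full solver recovers noiseless forward-mixed truth", {
  sc <- noiseless_scene()
  fr <- sc$fractions
  truth <- eps_complex(sc$truth_p)
  ew <- eps_complex(sc$truth_w)
  es <- eps_complex(sc$derived_s); ecs <- eps_complex(sc$derived_cs)
  fs <- solve_protein_full(ew, es, ecs, fr)
  expect_lt(max(Mod(fs$eps_p - truth) / Mod(truth)), 1e-8)
  # residual at the returned root, relative to the largest term
  r <- full_residual(fs$eps_p, ew, es, ecs, fr)
  rel <- Mod(r$residual) / pmax(Mod(r$t1), Mod(r$t2), Mod(r$t3))
  expect_lt(max(rel), 1e-10)
  # degree check: generic frequencies present exactly two roots
  expect_true(all(fs$root_meta$n_roots == 2L))
  expect_false(any(fs$root_meta$degenerate))
  # hinting at the truth also selects it
  fs2 <- solve_protein_full(ew, es, ecs, fr, hint = truth)
  expect_lt(max(Mod(fs2$eps_p - truth) / Mod(truth)), 1e-8)
})

test_that("homogeneous triplet extracts the same spectrum everywhere", {
  fr <- bsa_fractions()
  wn <- seq(10, 70, by = 4)
  e0 <- dielectric_spectrum(wn, rep(4.5, length(wn)), rep(2.1, length(wn)))
  tri <- solution_triplet(e0, e0, e0)
  for (sv in c("reduced", "full")) {
    res <- extract_spectrum(tri, fr, solver = sv)
    expect_equal(res$spectrum$eps_re, e0$eps_re, tolerance = 1e-10)
    expect_equal(res$spectrum$eps_im, e0$eps_im, tolerance = 1e-10)
  }
})

test_that("term-magnitude check implements the order-of-magnitude rule", {
  sc <- noiseless_scene()
  fr <- sc$fractions
  ew <- eps_complex(sc$truth_w)
  es <- eps_complex(sc$derived_s); ecs <- eps_complex(sc$derived_cs)
  ep <- solve_protein_reduced(ew, es, ecs, fr)
  tm <- term_magnitudes(ep, ew, es, ecs, fr, ratio = 10)
  expect_true(all(tm$term_ok))
  expect_true(all(tm$t2 >= 10 * tm$t1 & tm$t3 >= 10 * tm$t1))
  # infinite ratio invalidates every frequency with a nonzero protein term
  tm_inf <- term_magnitudes(ep, ew, es, ecs, fr, ratio = Inf)
  expect_false(any(tm_inf$term_ok[tm_inf$t1 > 0]))
  # f = 0: protein term vanishes identically, always valid
  fr0 <- phase_fractions(f_p = 0.237, f = 1e-300, f_sh = 0.114)
  tm0 <- term_magnitudes(ep, ew, es, ecs, fr0, ratio = 10)
  expect_true(all(tm0$term_ok))
})

test_that("extraction attaches diagnostics and isolates bad frequencies", {
  sc <- noiseless_scene()
  res <- extract_spectrum(sc$observed, sc$fractions)
  d <- res$diagnostics
  expect_named(d, c("wavenumber", "t1", "t2", "t3", "term_ok", "in_window",
                    "solved", "negative_loss", "valid"))
  expect_true(all(d$valid))
  expect_s3_class(res$spectrum, "dielectric_spectrum")
  # frequencies outside the window are computed but flagged
  wn <- c(5, seq(10, 70, by = 10), 90)
  sc2 <- make_scene(wavenumber = wn, noise_sd = 0)
  res2 <- extract_spectrum(sc2$observed, sc2$fractions)
  d2 <- res2$diagnostics
  expect_false(any(d2$valid[!d2$in_window]))
  expect_true(all(d2$solved))
  # a deliberately singular frequency is flagged alone
  bad <- sc$observed
  i_bad <- 3L
  bad$solvent$eps_re[i_bad] <- bad$dilute$eps_re[i_bad] * -2
  bad$solvent$eps_im[i_bad] <- bad$dilute$eps_im[i_bad] * -2
  res3 <- extract_spectrum(bad, sc$fractions)
  expect_false(res3$diagnostics$solved[i_bad])
  expect_false(res3$diagnostics$valid[i_bad])
  expect_true(all(res3$diagnostics$solved[-i_bad]))
  expect_error(extract_spectrum(sc$observed, list(f = 0.1)),
               "phase_fractions")
})

test_that("sensitivity scan is seed-reproducible and collapses at delta 0", {
  sc <- noiseless_scene()
  tri <- sc$observed
  fr <- sc$fractions
  s0 <- sensitivity_scan(tri, fr, delta = 0, n_draws = 5, seed = 3)
  expect_true(all(s0$per_frequency$rel_sd < 1e-14))
  expect_true(all(abs(s0$per_frequency$mag_ratio - 1) < 1e-14))
  s1 <- sensitivity_scan(tri, fr, delta = 0.01, n_draws = 10, seed = 5)
  s2 <- sensitivity_scan(tri, fr, delta = 0.01, n_draws = 10, seed = 5)
  expect_identical(s1$per_frequency, s2$per_frequency)
  s3 <- sensitivity_scan(tri, fr, delta = 0.01, n_draws = 10, seed = 6)
  expect_false(identical(s1$per_frequency$rel_sd,
                         s3$per_frequency$rel_sd))
  expect_error(sensitivity_scan(tri, fr, delta = 0.01, n_draws = 1),
               "at least 2")
})
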