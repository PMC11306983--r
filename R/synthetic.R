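# Synthetic scenes: multi-Debye relaxation models for water, perturbed-water
# hydration shells and protein, forward Bruggeman mixing into solution
# spectra, and additive measurement noise — so the full inverse problem can
# be exercised end-to-end without instrument data.

#' Single Debye relaxation band
#'
#' @param delta_eps relaxation strength (dimensionless, > 0).
#' @param tau_ps relaxation time in picoseconds (> 0).
#' @return a list of class `"debye_term"`.
#' @export
debye_term <- function(delta_eps, tau_ps) {
  stopifnot(is.numeric(delta_eps), is.numeric(tau_ps),
            length(delta_eps) == 1L, length(tau_ps) == 1L)
  if (delta_eps <= 0 || tau_ps <= 0)
    stop("delta_eps and tau_ps must be positive", call. = FALSE)
  structure(list(delta_eps = delta_eps, tau_ps = tau_ps),
            class = "debye_term")
}

#' Relaxation model: Debye bands plus optional damped oscillators
#'
#' \deqn{\epsilon^*(\nu) = \epsilon_\infty
#'   + \sum_j \frac{\Delta\epsilon_j}{1 - i\omega\tau_j}
#'   + \sum_k \frac{S_k \nu_k^2}{\nu_k^2 - \nu^2 - i\gamma_k\nu}, \qquad
#'   \omega = 2\pi c \nu,}
#' with \eqn{\nu} in cm^-1, \eqn{c} in cm/s and \eqn{\tau} in seconds.
#' Under the \eqn{e^{-i\omega t}} convention both band types have
#' non-negative loss.
#'
#' @param eps_inf high-frequency permittivity limit (>= 1).
#' @param debye list of [debye_term()]s (may be empty if oscillators given).
#' @param oscillators optional list of numeric triples
#'   `c(strength, center_cm1, damping_cm1)`.
#' @return a list of class `"relaxation_model"`.
#' @export
relaxation_model <- function(eps_inf, debye = list(), oscillators = list()) {
  stopifnot(is.numeric(eps_inf), length(eps_inf) == 1L)
  if (eps_inf < 1) stop("eps_inf must be >= 1", call. = FALSE)
  if (!length(debye) && !length(oscillators))
    stop("at least one Debye term or oscillator is required", call. = FALSE)
  for (d in debye)
    if (!inherits(d, "debye_term"))
      stop("debye must be a list of debye_term objects", call. = FALSE)
  for (o in oscillators)
    if (!is.numeric(o) || length(o) != 3L || any(o <= 0))
      stop("each oscillator is a positive numeric triple ",
           "(strength, center_cm1, damping_cm1)", call. = FALSE)
  structure(list(eps_inf = eps_inf, debye = debye,
                 oscillators = oscillators), class = "relaxation_model")
}

#' Double-Debye model of bulk water at 25 degrees C
#'
#' Two relaxation bands dominate the 10-70 cm^-1 dielectric response of
#' liquid water: the slow cooperative (bound-water) relaxation and the fast
#' relaxation of weakly bound molecules.  The shipped default parameters
#' (slow band: strength ~73, tau ~8.3 ps; fast band: strength ~2,
#' tau ~0.3 ps; eps_inf 2.5) are literature-typical 25 degree values, not
#' fitted to any particular measurement — treat them as a plausible,
#' configurable stand-in, not an authority.
#'
#' @param delta_eps1,tau1_ps slow (cooperative) band parameters.
#' @param delta_eps2,tau2_ps fast band parameters.
#' @param eps_inf high-frequency limit.
#' @return a [relaxation_model()].
#' @export
water_model <- function(delta_eps1 = 73, tau1_ps = 8.3,
                        delta_eps2 = 2, tau2_ps = 0.3, eps_inf = 2.5) {
  relaxation_model(eps_inf,
                   debye = list(debye_term(delta_eps1, tau1_ps),
                                debye_term(delta_eps2, tau2_ps)))
}

#' Dissolved-protein relaxation model
#'
#' Default ground truth for the protein phase in synthetic scenes.  A
#' protein molecule in solution exhibits pronounced low-frequency
#' dispersion whose dielectric losses closely track those of the aqueous
#' environment — its intramolecular dynamics adjusts to the intermolecular
#' relaxation of the surrounding water.  The default is therefore
#' water-like but retarded and slightly weakened: a slow band of strength
#' 60 at 9.5 ps plus a fast band of strength 1.6 at 0.25 ps over
#' `eps_inf = 2.5`.  This is also the regime in which the extraction method
#' operates: the protein term of the combined equation is genuinely small,
#' so the order-of-magnitude validity check passes across the 10-70 cm^-1
#' window.  A nearly flat, low-permittivity model (like dry protein) would
#' place the scene outside that domain of validity.
#'
#' @param delta_eps1,tau1_ps slow band parameters.
#' @param delta_eps2,tau2_ps fast band parameters.
#' @param eps_inf high-frequency limit.
#' @return a [relaxation_model()].
#' @export
protein_model <- function(delta_eps1 = 60, tau1_ps = 9.5,
                          delta_eps2 = 1.6, tau2_ps = 0.25,
                          eps_inf = 2.5) {
  relaxation_model(eps_inf,
                   debye = list(debye_term(delta_eps1, tau1_ps),
                                debye_term(delta_eps2, tau2_ps)))
}

#' Derive a hydration-shell model from a water model
#'
#' Dynamic hydration shells are water with altered intermolecular dynamics:
#' relaxation is retarded and somewhat depolarized relative to bulk.  This
#' is emulated by scaling every Debye time by `slow_factor` and every
#' strength by `strength_factor`; oscillators and `eps_inf` are kept.
#'
#' @param water a [relaxation_model()] for bulk water.
#' @param slow_factor multiplies each relaxation time (default 1.5).
#' @param strength_factor multiplies each relaxation strength (default 0.9).
#' @return a [relaxation_model()]; identical to `water` when both factors
#'   are 1.
#' @export
make_shell_model <- function(water, slow_factor = 1.5,
                             strength_factor = 0.9) {
  stopifnot(inherits(water, "relaxation_model"))
  if (slow_factor <= 0 || strength_factor <= 0)
    stop("factors must be positive", call. = FALSE)
  relaxation_model(
    water$eps_inf,
    debye = lapply(water$debye, function(d)
      debye_term(d$delta_eps * strength_factor, d$tau_ps * slow_factor)),
    oscillators = water$oscillators)
}

#' Evaluate a relaxation model on a wavenumber grid
#'
#' @param wavenumber wavenumber grid in cm^-1.
#' @param model a [relaxation_model()].
#' @return a [dielectric_spectrum()].
#' @examples
#' relaxation_spectrum(seq(10, 70, by = 2), water_model())
#' @export
relaxation_spectrum <- function(wavenumber, model) {
  stopifnot(inherits(model, "relaxation_model"))
  wavenumber <- frequency_grid(wavenumber)
  omega <- 2 * pi * .speed_of_light_cm_s * wavenumber  # rad/s
  eps <- complex(real = rep(model$eps_inf, length(wavenumber)),
                 imaginary = 0)
  for (d in model$debye)
    eps <- eps + d$delta_eps / (1 - 1i * omega * d$tau_ps * 1e-12)
  for (o in model$oscillators)
    eps <- eps + o[1L] * o[2L]^2 /
      (o[2L]^2 - wavenumber^2 - 1i * o[3L] * wavenumber)
  dielectric_spectrum(wavenumber, Re(eps), Im(eps))
}

#' Generate a synthetic extraction scene
#'
#' Builds ground-truth protein, shell and water permittivities from
#' relaxation models, forward-mixes them into the two observable solution
#' spectra — the concentrated solution by two-phase Bruggeman mixing of
#' protein and shell at `f_p`, the dilute solution by three-phase mixing at
#' `(f, f_sh)` — and finally adds iid Gaussian noise of standard deviation
#' `noise_sd` to the real and imaginary parts of the three observable
#' spectra (solvent, dilute, concentrated).  Ground truths are stored
#' unnoised; the pre-noise derived spectra satisfy their defining mixing
#' residuals to near machine precision.
#'
#' @param wavenumber wavenumber grid in cm^-1 (default `seq(10, 70, 2)`,
#'   the window where the term-magnitude check holds for protein
#'   solutions).
#' @param fractions a [phase_fractions()]; defaults to the two-solution BSA
#'   experiment (334 and 50 mg/mL at density 1.41 g/cm^3).
#' @param water,shell,protein [relaxation_model()]s for the three phases.
#' @param noise_sd standard deviation of the additive permittivity noise
#'   (default 0.01, a realistic experimental spread).
#' @param seed integer RNG seed; identical seed and parameters give a
#'   bit-identical scene.
#' @return object of class `"synthetic_scene"`: list with `truth_p`,
#'   `truth_sh`, `truth_w`, `derived_cs`, `derived_s` (noiseless
#'   [dielectric_spectrum()]s), `observed` (a noisy [solution_triplet()]),
#'   `fractions`, `noise_sd`, `seed`.
#' @export
make_scene <- function(wavenumber = seq(10, 70, by = 2),
                       fractions = phase_fractions(c_conc = 334,
                                                   c_dilute = 50,
                                                   density = 1.41),
                       water = water_model(),
                       shell = make_shell_model(water),
                       protein = protein_model(),
                       noise_sd = 0.01, seed = 1) {
  stopifnot(inherits(fractions, "phase_fractions"))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be non-negative", call. = FALSE)
  wavenumber <- frequency_grid(wavenumber)
  truth_w <- relaxation_spectrum(wavenumber, water)
  truth_sh <- relaxation_spectrum(wavenumber, shell)
  truth_p <- relaxation_spectrum(wavenumber, protein)
  e_p <- eps_complex(truth_p); e_sh <- eps_complex(truth_sh)
  e_w <- eps_complex(truth_w)
  e_cs <- bruggeman2_effective(e_p, e_sh, fractions$f_p)
  e_s <- bruggeman3_effective(e_p, e_sh, e_w, fractions$f, fractions$f_sh)
  derived_cs <- dielectric_spectrum(wavenumber, Re(e_cs), Im(e_cs))
  derived_s <- dielectric_spectrum(wavenumber, Re(e_s), Im(e_s))
  m <- length(wavenumber)
  noisy <- .with_seed(seed, {
    lapply(list(w = e_w, s = e_s, cs = e_cs), function(e)
      e + complex(real = stats::rnorm(m, 0, noise_sd),
                  imaginary = stats::rnorm(m, 0, noise_sd)))
  })
  observed <- solution_triplet(
    solvent = dielectric_spectrum(wavenumber, Re(noisy$w), Im(noisy$w),
                                  check_passive = FALSE),
    dilute = dielectric_spectrum(wavenumber, Re(noisy$s), Im(noisy$s),
                                 check_passive = FALSE),
    concentrated = dielectric_spectrum(wavenumber, Re(noisy$cs),
                                       Im(noisy$cs),
                                       check_passive = FALSE))
  structure(list(wavenumber = wavenumber,
                 truth_p = truth_p, truth_sh = truth_sh, truth_w = truth_w,
                 derived_cs = derived_cs, derived_s = derived_s,
                 observed = observed, fractions = fractions,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d frequencies %.6g-%.6g cm^-1; f_p = %.3g, f = %.3g, f_sh = %.3g; noise_sd = %g, seed = %d\n",
    length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
    x$fractions$f_p, x$fractions$f, x$fractions$f_sh, x$noise_sd, x$seed))
  invisible(x)
}

#' Roundtrip error report for a synthetic scene
#'
#' Runs [extract_spectrum()] on the scene's observed triplet and compares
#' the extracted protein permittivity with the stored ground truth,
#' frequency by frequency.
#'
#' @param scene a [make_scene()] result.
#' @param solver `"both"` (default), `"reduced"` or `"full"`.
#' @param ... further options passed to [extract_spectrum()].
#' @return object of class `"roundtrip_report"`: list with `per_frequency`
#'   (data frame: `wavenumber`, `solver`, relative errors `rel_err_re`,
#'   `rel_err_im`, `rel_err_mod`, `valid`) and `aggregate` (per solver: max
#'   and mean of `rel_err_mod` over solved frequencies).
#' @export
roundtrip_report <- function(scene, solver = c("both", "reduced", "full"),
                             ...) {
  solver <- match.arg(solver)
  stopifnot(inherits(scene, "synthetic_scene"))
  solvers <- if (solver == "both") c("reduced", "full") else solver
  truth <- eps_complex(scene$truth_p)
  per_frequency <- do.call(rbind, lapply(solvers, function(s) {
    res <- extract_spectrum(scene$observed, scene$fractions, solver = s, ...)
    got <- complex(real = res$spectrum$eps_re,
                   imaginary = res$spectrum$eps_im)
    data.frame(
      wavenumber = scene$wavenumber, solver = s,
      rel_err_re = abs(Re(got) - Re(truth)) / Mod(truth),
      rel_err_im = abs(Im(got) - Im(truth)) / Mod(truth),
      rel_err_mod = Mod(got - truth) / Mod(truth),
      valid = res$diagnostics$valid)
  }))
  rownames(per_frequency) <- NULL
  aggregate <- do.call(rbind, lapply(solvers, function(s) {
    e <- per_frequency$rel_err_mod[per_frequency$solver == s]
    data.frame(solver = s,
               max_rel_err = if (all(is.na(e))) NA_real_ else
                 max(e, na.rm = TRUE),
               mean_rel_err = if (all(is.na(e))) NA_real_ else
                 mean(e, na.rm = TRUE))
  }))
  structure(list(per_frequency = per_frequency, aggregate = aggregate),
            class = "roundtrip_report")
}

#' @export
print.roundtrip_report <- function(x, ...) {
  cat("<roundtrip_report>\n")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
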