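# Bruggeman effective-medium mixing: residuals, forward (mixing) solvers and
# the shell-permittivity identity.  All functions are vectorized over
# frequencies and work on complex permittivities under the e^(-i omega t)
# convention (passive media: Im >= 0).

# relative scale used to flag near-singular denominators
.singular_rel_tol <- 1e-12

.check_denominator <- function(den, scale, what) {
  bad <- which(Mod(den) < .singular_rel_tol * pmax(scale, 1))
  if (length(bad))
    stop(sprintf("singular denominator in %s at position %d", what, bad[1L]),
         call. = FALSE)
  invisible(TRUE)
}

#' Two-phase Bruggeman residual
#'
#' Residual of the symmetric Bruggeman mixing rule for a two-phase
#' composite with inclusion permittivities `eps_a`, `eps_b`, volume fraction
#' `f_a` of phase a, and candidate effective permittivity `eps_e`:
#' \deqn{f_a \frac{\epsilon_a - \epsilon_e}{\epsilon_a + 2\epsilon_e}
#'   + (1 - f_a) \frac{\epsilon_b - \epsilon_e}{\epsilon_b + 2\epsilon_e}.}
#' Zero exactly when `eps_e` solves the mixture; antisymmetric under
#' swapping the phases together with `f_a -> 1 - f_a`.
#'
#' @param eps_a,eps_b complex permittivities of the two phases.
#' @param eps_e candidate effective permittivity.
#' @param f_a volume fraction of phase a, in \[0, 1\].
#' @return complex residual (vectorized).
#' @export
bruggeman2_residual <- function(eps_a, eps_b, eps_e, f_a) {
  stopifnot(f_a >= 0, f_a <= 1)
  eps_a <- as.complex(eps_a); eps_b <- as.complex(eps_b)
  eps_e <- as.complex(eps_e)
  scale <- pmax(Mod(eps_a), Mod(eps_b), Mod(eps_e))
  .check_denominator(eps_a + 2 * eps_e, scale, "bruggeman2_residual (phase a)")
  .check_denominator(eps_b + 2 * eps_e, scale, "bruggeman2_residual (phase b)")
  f_a * (eps_a - eps_e) / (eps_a + 2 * eps_e) +
    (1 - f_a) * (eps_b - eps_e) / (eps_b + 2 * eps_e)
}

# Physical-branch selector shared by the forward solvers: keep roots with
# non-negative loss (within a tiny numerical slack) and positive real part,
# then take the one nearest the volume-weighted linear mixture.
.pick_physical_root <- function(roots, target, what) {
  scale <- max(Mod(roots), Mod(target), 1)
  phys <- Im(roots) >= -1e-9 * scale & Re(roots) > 0
  if (!any(phys))
    stop(sprintf("no physical root found in %s", what), call. = FALSE)
  cand <- roots[phys]
  cand[which.min(Mod(cand - target))]
}

#' Forward two-phase Bruggeman mixing
#'
#' Solves the two-phase Bruggeman rule for the effective permittivity.
#' Clearing denominators gives the quadratic
#' \eqn{2\epsilon_e^2 - p\,\epsilon_e - \epsilon_a\epsilon_b = 0} with
#' \eqn{p = (3f_a - 1)\epsilon_a + (2 - 3f_a)\epsilon_b}; both roots are
#' formed and the physical branch (non-negative loss, positive real part,
#' nearest the linear volume-weighted mixture) is returned.  For real
#' lossless inputs the result respects the Wiener bounds
#' \eqn{\min(\epsilon_a,\epsilon_b) \le \epsilon_e \le
#' \max(\epsilon_a,\epsilon_b)}.
#'
#' @inheritParams bruggeman2_residual
#' @return complex effective permittivity (vectorized over frequencies).
#' @export
bruggeman2_effective <- function(eps_a, eps_b, f_a) {
  stopifnot(f_a >= 0, f_a <= 1)
  eps_a <- as.complex(eps_a); eps_b <- as.complex(eps_b)
  m <- max(length(eps_a), length(eps_b))
  eps_a <- rep_len(eps_a, m); eps_b <- rep_len(eps_b, m)
  p <- (3 * f_a - 1) * eps_a + (2 - 3 * f_a) * eps_b
  disc <- sqrt(p^2 + 8 * eps_a * eps_b)
  target <- f_a * eps_a + (1 - f_a) * eps_b
  vapply(seq_len(m), function(i) {
    roots <- c(p[i] + disc[i], p[i] - disc[i]) / 4
    .pick_physical_root(roots, target[i], "bruggeman2_effective")
  }, complex(1L))
}

#' Shell permittivity from the concentrated-solution mixture
#'
#' In the concentrated solution essentially all water is hydration shell, so
#' the two-phase Bruggeman rule links protein, shell and the measured
#' solution permittivity.  Solving it for the shell gives the closed form
#' \deqn{\epsilon_{sh}^* = \frac{(1 - 3f_p)\epsilon_p^*\epsilon_{cs}^*
#'   + 2\epsilon_{cs}^{*2}}{\epsilon_p^* + (2 - 3f_p)\epsilon_{cs}^*}.}
#'
#' @param eps_p complex protein permittivity.
#' @param eps_cs complex permittivity of the concentrated solution.
#' @param f_p protein volume fraction in the concentrated solution.
#' @return complex shell permittivity (vectorized).
#' @export
shell_from_concentrated <- function(eps_p, eps_cs, f_p) {
  stopifnot(f_p > 0, f_p < 1)
  eps_p <- as.complex(eps_p); eps_cs <- as.complex(eps_cs)
  den <- eps_p + (2 - 3 * f_p) * eps_cs
  .check_denominator(den, pmax(Mod(eps_p), Mod(eps_cs)),
                     "shell_from_concentrated")
  ((1 - 3 * f_p) * eps_p * eps_cs + 2 * eps_cs^2) / den
}

#' Three-phase Bruggeman residual
#'
#' Residual of the three-phase Bruggeman rule for the dilute solution:
#' protein inclusions (fraction `f`), hydration shells (`f_sh`) and the
#' remaining bulk-water phase (`1 - f - f_sh`), with candidate effective
#' permittivity `eps_s`:
#' \deqn{f\frac{\epsilon_p - \epsilon_s}{\epsilon_p + 2\epsilon_s}
#'  + f_{sh}\frac{\epsilon_{sh} - \epsilon_s}{\epsilon_{sh} + 2\epsilon_s}
#'  + (1 - f - f_{sh})\frac{\epsilon_w - \epsilon_s}{\epsilon_w + 2\epsilon_s}.}
#'
#' @param eps_p,eps_sh,eps_w complex permittivities of protein, shell and
#'   bulk water.
#' @param eps_s candidate effective permittivity of the dilute solution.
#' @param f,f_sh volume fractions of protein and shell; `f + f_sh < 1`.
#' @return complex residual (vectorized).
#' @export
bruggeman3_residual <- function(eps_p, eps_sh, eps_w, eps_s, f, f_sh) {
  stopifnot(f >= 0, f_sh >= 0, f + f_sh < 1)
  eps_p <- as.complex(eps_p); eps_sh <- as.complex(eps_sh)
  eps_w <- as.complex(eps_w); eps_s <- as.complex(eps_s)
  scale <- pmax(Mod(eps_p), Mod(eps_sh), Mod(eps_w), Mod(eps_s))
  .check_denominator(eps_p + 2 * eps_s, scale, "bruggeman3_residual (protein)")
  .check_denominator(eps_sh + 2 * eps_s, scale, "bruggeman3_residual (shell)")
  .check_denominator(eps_w + 2 * eps_s, scale, "bruggeman3_residual (water)")
  f * (eps_p - eps_s) / (eps_p + 2 * eps_s) +
    f_sh * (eps_sh - eps_s) / (eps_sh + 2 * eps_s) +
    (1 - f - f_sh) * (eps_w - eps_s) / (eps_w + 2 * eps_s)
}

# multiply two complex polynomials given as ascending coefficient vectors
.polymul <- function(a, b) {
  out <- complex(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Forward three-phase Bruggeman mixing
#'
#' Solves the three-phase Bruggeman rule for the effective permittivity of
#' the dilute solution.  Clearing the three denominators yields a cubic in
#' \eqn{\epsilon_s}; all roots are computed ([polyroot()]) and the physical
#' branch is selected: non-negative loss, positive real part, nearest the
#' volume-weighted linear mixture
#' \eqn{f\epsilon_p + f_{sh}\epsilon_{sh} + (1 - f - f_{sh})\epsilon_w}.
#'
#' @inheritParams bruggeman3_residual
#' @return complex effective permittivity (vectorized over frequencies).
#' @export
bruggeman3_effective <- function(eps_p, eps_sh, eps_w, f, f_sh) {
  stopifnot(f >= 0, f_sh >= 0, f + f_sh < 1)
  eps_p <- as.complex(eps_p); eps_sh <- as.complex(eps_sh)
  eps_w <- as.complex(eps_w)
  m <- max(length(eps_p), length(eps_sh), length(eps_w))
  eps_p <- rep_len(eps_p, m); eps_sh <- rep_len(eps_sh, m)
  eps_w <- rep_len(eps_w, m)
  f_w <- 1 - f - f_sh
  vapply(seq_len(m), function(i) {
    e <- c(eps_p[i], eps_sh[i], eps_w[i])
    fr <- c(f, f_sh, f_w)
    # numerator polynomial: sum_i f_i (e_i - x) prod_{j != i} (e_j + 2x)
    coef <- complex(4L)
    for (k in 1:3) {
      others <- setdiff(1:3, k)
      pk <- .polymul(c(e[k], -1 + 0i),
                     .polymul(c(e[others[1L]], 2 + 0i),
                              c(e[others[2L]], 2 + 0i)))
      coef <- coef + fr[k] * pk
    }
    target <- sum(fr * e)
    if (Mod(coef[4L]) < 1e-14 * max(Mod(coef))) {
      roots <- polyroot(coef[1:3])
    } else {
      roots <- polyroot(coef)
    }
    root <- .pick_physical_root(roots, target, "bruggeman3_effective")
    # polish with one or two Newton steps on the cleared-denominator cubic
    for (it in 1:3) {
      p_val <- coef[1L] + coef[2L] * root + coef[3L] * root^2 + coef[4L] * root^3
      dp <- coef[2L] + 2 * coef[3L] * root + 3 * coef[4L] * root^2
      if (Mod(dp) == 0) break
      root <- root - p_val / dp
    }
    root
  }, complex(1L))
}
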