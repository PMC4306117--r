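#' Uniaxial test record
#'
#' A force–displacement record from uniaxial extension of a specimen with
#' known gauge length and reference cross-section.  Preconditioning cycles
#' are assumed already removed; `drop_preload = TRUE` discards all samples
#' before the final non-positive-force sample.
#'
#' @param displacement Crosshead displacement in mm, starting at 0,
#'   strictly increasing.
#' @param force Force in N, same length.
#' @param gauge_length Gauge length L0 in mm.
#' @param cross_section Reference cross-section A0 in mm².
#' @param drop_preload Drop samples before the final zero/negative force
#'   crossing (shifting displacement so the retained record starts at 0).
#' @return An object of class `test_record`.
#' @export
test_record <- function(displacement, force, gauge_length, cross_section,
                        drop_preload = FALSE) {
  stopifnot(length(displacement) == length(force),
            is.finite(gauge_length), gauge_length > 0,
            is.finite(cross_section), cross_section > 0)
  if (drop_preload) {
    z <- which(force <= 0)
    if (length(z) && max(z) < length(force)) {
      keep <- max(z):length(force)
      displacement <- displacement[keep] - displacement[keep[1]]
      force <- force[keep]
    }
  }
  if (length(displacement) == 0L) stop("empty record")
  if (displacement[1] != 0) stop("first displacement sample must be 0")
  if (any(diff(displacement) <= 0))
    stop("displacement must be strictly increasing")
  structure(list(displacement = as.numeric(displacement),
                 force = as.numeric(force),
                 gauge_length = gauge_length, cross_section = cross_section),
            class = "test_record")
}

#' Specification of a synthetic uniaxial curve
#'
#' The generator uses the standard exponential soft-tissue stiffening law
#' \deqn{\sigma(\lambda) = a\,(e^{b(\lambda - 1)} - 1)}
#' (Cauchy stress, MPa) truncated at the rupture stretch, with tangent
#' stiffness `a * b` at \eqn{\lambda = 1}.
#'
#' @param a,b Constitutive parameters, both positive (MPa and
#'   dimensionless).
#' @param lambda_u Rupture stretch, > 1.
#' @param gauge_length,cross_section Specimen geometry L0 (mm), A0 (mm²).
#' @param step Stretch sampling step.
#' @param noise_sd Force noise SD in N.
#' @param seed RNG seed.
#' @return A list of class `mech_curve_spec`.
#' @export
mech_curve_spec <- function(a = 0.2, b = 3, lambda_u = 1.44,
                            gauge_length = 10, cross_section = 10,
                            step = 0.002, noise_sd = 0, seed = 1L) {
  stopifnot(a > 0, b > 0, step > 0, noise_sd >= 0,
            gauge_length > 0, cross_section > 0)
  if (lambda_u <= 1) stop("rupture stretch lambda_u must exceed 1")
  structure(list(a = a, b = b, lambda_u = lambda_u,
                 gauge_length = gauge_length, cross_section = cross_section,
                 step = step, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mech_curve_spec")
}

# sigma(lambda) of the generator's constitutive law
.sigma_exp <- function(lambda, a, b) a * (exp(b * (lambda - 1)) - 1)

#' Generate a synthetic force–displacement record
#'
#' Samples the constitutive stress–stretch law on a regular stretch grid
#' from 1 to the rupture stretch (rupture point included) and inverts the
#' incompressible Cauchy-stress definition, `F = sigma(lambda) * A0 /
#' lambda`, so that [to_stress_stretch()] round-trips the stress exactly
#' at zero noise.
#'
#' @param spec A [mech_curve_spec()].
#' @return A [test_record()].
#' @export
generate_mechanical_curve <- function(spec) {
  stopifnot(inherits(spec, "mech_curve_spec"))
  lambda <- seq(1, spec$lambda_u, by = spec$step)
  if (lambda[length(lambda)] < spec$lambda_u)
    lambda <- c(lambda, spec$lambda_u)
  sigma <- .sigma_exp(lambda, spec$a, spec$b)
  force <- sigma * spec$cross_section / lambda
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    force <- force + rnorm(length(force), sd = spec$noise_sd)
    force[1] <- 0
  }
  test_record((lambda - 1) * spec$gauge_length, force,
              spec$gauge_length, spec$cross_section)
}

#' Convert a test record to a Cauchy stress–stretch curve
#'
#' Stretch ratio \eqn{\lambda_i = (L_0 + d_i)/L_0}; Cauchy stress under
#' the incompressibility assumption \eqn{\sigma_i = F_i \lambda_i / A_0}
#' in MPa (N/mm²).  `convention = "engineering"` reports the first
#' Piola-Kirchhoff (engineering) stress \eqn{F_i / A_0} instead.
#'
#' @param record A [test_record()].
#' @param convention `"cauchy"` (default) or `"engineering"`.
#' @return An object of class `stress_stretch_curve` (data frame with
#'   columns `lambda`, `stress`).
#' @export
to_stress_stretch <- function(record, convention = c("cauchy", "engineering")) {
  stopifnot(inherits(record, "test_record"))
  convention <- match.arg(convention)
  lambda <- (record$gauge_length + record$displacement) / record$gauge_length
  stress <- record$force / record$cross_section
  if (convention == "cauchy") stress <- stress * lambda
  structure(data.frame(lambda = lambda, stress = stress),
            class = c("stress_stretch_curve", "data.frame"),
            convention = convention)
}

#' Initial stiffness of a stress–stretch curve
#'
#' Slope (MPa) of the least-squares line of stress against
#' \eqn{\lambda - 1} restricted to the low-stretch fit window.  The
#' default window \eqn{\lambda \in [1.0, 1.1]} matches the 10%-gauge
#' preconditioning regime; both window and method are configuration since
#' tangent, secant and windowed-fit conventions all appear in practice.
#'
#' @param curve A [to_stress_stretch()] result.
#' @param fit_window `c(lambda_min, lambda_max)`.
#' @return Initial stiffness in MPa.
#' @export
initial_stiffness <- function(curve, fit_window = c(1.0, 1.1)) {
  stopifnot(inherits(curve, "stress_stretch_curve"), length(fit_window) == 2)
  keep <- curve$lambda >= fit_window[1] & curve$lambda <= fit_window[2]
  if (sum(keep) < 3L)
    stop(sprintf("fewer than 3 samples in the fit window [%g, %g]",
                 fit_window[1], fit_window[2]))
  unname(coef(lm(stress ~ I(lambda - 1), data = curve[keep, ]))[2])
}

#' Peak strength of a stress–stretch curve
#'
#' Global stress maximum and the stretch at which it occurs (first
#' occurrence on a plateau of equal maxima).
#'
#' @param curve A [to_stress_stretch()] result.
#' @return Named vector `c(peak_stress, stretch_at_peak)`.
#' @export
peak_strength <- function(curve) {
  stopifnot(inherits(curve, "stress_stretch_curve"), nrow(curve) > 0)
  i <- which.max(curve$stress)
  c(peak_stress = curve$stress[i], stretch_at_peak = curve$lambda[i])
}

#' Stiffness-group label
#'
#' Assigns the low/medium/high stiffness group from initial stiffness
#' using half-open intervals: LS for `E < b1`, MS for `b1 <= E < b2`, HS
#' for `E >= b2`.  The default breakpoints (1 and 2 MPa) separate the
#' three stiffness levels observed in the carotid plaque sample set this
#' package models (0.6--0.75, 1.25--1.6 and 3.79 MPa).
#'
#' @param stiffness Initial stiffness in MPa (vectorised).
#' @param breakpoints `c(b1, b2)` with `b1 < b2`, MPa.
#' @return Character vector of `"LS"`, `"MS"`, `"HS"`.
#' @export
assign_group <- function(stiffness, breakpoints = c(1, 2)) {
  stopifnot(length(breakpoints) == 2, breakpoints[1] < breakpoints[2])
  ifelse(stiffness < breakpoints[1], "LS",
         ifelse(stiffness < breakpoints[2], "MS", "HS"))
}

#' Summarise a uniaxial test record
#'
#' Convenience wrapper: stress–stretch conversion, initial stiffness,
#' peak strength and stiffness group in one call.
#'
#' @param record A [test_record()].
#' @param fit_window,breakpoints Passed to [initial_stiffness()] and
#'   [assign_group()].
#' @param convention Stress convention, see [to_stress_stretch()].
#' @return List of class `mechanical_summary` with fields
#'   `initial_stiffness`, `peak_stress`, `stretch_at_peak`, `group` and
#'   the `curve`.
#' @export
summarise_mechanics <- function(record, fit_window = c(1.0, 1.1),
                                breakpoints = c(1, 2),
                                convention = "cauchy") {
  curve <- to_stress_stretch(record, convention)
  e0 <- initial_stiffness(curve, fit_window)
  pk <- peak_strength(curve)
  structure(list(initial_stiffness = e0,
                 peak_stress = unname(pk["peak_stress"]),
                 stretch_at_peak = unname(pk["stretch_at_peak"]),
                 group = assign_group(e0, breakpoints),
                 curve = curve),
            class = "mechanical_summary")
}

#' @export
print.mechanical_summary <- function(x, ...) {
  cat(sprintf("<mechanical_summary> E0 = %.3g MPa (%s); peak %.3g MPa at lambda %.3g\n",
              x$initial_stiffness, x$group, x$peak_stress, x$stretch_at_peak))
  invisible(x)
}
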