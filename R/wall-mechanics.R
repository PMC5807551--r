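# Thick-walled incompressible two-fibre (HGO) artery mechanics.
#
# Geometry conventions: the stress-free configuration is an opened sector of
# opening angle `alpha` (sector subtends 2*pi - 2*alpha), with inner/outer
# radii R_i/R_o. Mapping to the loaded tube applies the sector closure
# (factor k = 2*pi/(2*pi - 2*alpha)), axial pre-stretch lambda_zz, and
# inflation to inner radius r_i. Incompressibility at fixed lambda_zz makes
# the deformed cross-sectional wall area A_w pressure-invariant.
#
# The hydrostatic pressure appearing in the Cauchy stress of an
# incompressible material is eliminated analytically: the pressure and
# reduced-axial-force integrals only involve stress differences
# (sigma_tt - sigma_rr, sigma_zz - sigma_rr).

.gauss_cache <- new.env(parent = emptyenv())

gauss_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gauss_cache[[key]])) {
    .gauss_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  .gauss_cache[[key]]
}

#' Constitutive parameters of the two-fibre HGO wall model
#'
#' Bundles the elastin (neo-Hookean) stiffness and the two collagen
#' parameters of the exponential fibre strain-energy function.
#'
#' @param c_elast elastin stiffness parameter, Pa; must be > 0.
#' @param k1 collagen stress scaling parameter, Pa; must be >= 0.
#' @param k2 collagen stress curve shape parameter, dimensionless; >= 0.
#' @return An object of class `hgo_params`.
#' @examples
#' hgo_params(c_elast = 40e3, k1 = 7e3, k2 = 8.5)
#' @export
hgo_params <- function(c_elast, k1, k2) {
  stopifnot(is.finite(c_elast), is.finite(k1), is.finite(k2))
  if (c_elast <= 0) stop("c_elast must be positive")
  if (k1 < 0 || k2 < 0) stop("k1 and k2 must be non-negative")
  structure(list(c_elast = c_elast, k1 = k1, k2 = k2), class = "hgo_params")
}

#' @export
print.hgo_params <- function(x, ...) {
  cat(sprintf("HGO parameters: c_elast = %.4g kPa, k1 = %.4g kPa, k2 = %.4g\n",
              x$c_elast / 1e3, x$k1 / 1e3, x$k2))
  invisible(x)
}

#' Deformed cross-sectional wall area from diameter and wall thickness
#'
#' The wall is an annulus between the outer diameter `D_d` and the lumen
#' diameter `D_d - 2 * IMT`: `A_w = pi * (D_d^2/4 - (D_d/2 - IMT)^2)`.
#'
#' @param D_d outer (diastolic) diameter, m.
#' @param IMT intima-media thickness, m; must satisfy `0 < IMT <= D_d/2`.
#' @return Wall area in m^2.
#' @examples
#' wall_area(6.37e-3, 539e-6) * 1e6  # mm^2
#' @export
wall_area <- function(D_d, IMT) {
  if (any(D_d <= 0) || any(IMT <= 0)) stop("D_d and IMT must be positive")
  if (any(IMT > D_d / 2)) stop("IMT may not exceed D_d/2")
  pi * (D_d^2 / 4 - (D_d / 2 - IMT)^2)
}

#' Unstressed outer radius closing the opening-angle kinematics
#'
#' The stress-free sector area `(pi - alpha) * (R_o^2 - R_i^2)` maps
#' incompressibly (at axial pre-stretch `lambda_zz`) onto the deformed wall
#' area `A_w`, giving `R_o = sqrt(R_i^2 + k * lambda_zz * A_w / pi)` with
#' sector factor `k = 2*pi / (2*pi - 2*alpha)`.
#'
#' @param R_i unstressed inner radius, m.
#' @param A_w deformed cross-sectional wall area, m^2.
#' @param alpha opening angle, rad (0 <= alpha < pi).
#' @param lambda_zz axial pre-stretch, dimensionless.
#' @return Unstressed outer radius, m.
#' @export
reference_outer_radius <- function(R_i, A_w, alpha, lambda_zz) {
  stopifnot(R_i > 0, A_w > 0, lambda_zz > 0, alpha >= 0, alpha < pi)
  k <- 2 * pi / (2 * pi - 2 * alpha)
  sqrt(R_i^2 + k * lambda_zz * A_w / pi)
}

#' Reference (stress-free) configuration of the artery segment
#'
#' Ties the unstressed sector geometry to the measured, deformed wall area.
#' The outer radius is derived from the area-closure identity, so the
#' invariant `R_o^2 - R_i^2 = k * lambda_zz * A_w / pi` holds by
#' construction.
#'
#' @param R_i unstressed inner radius, m.
#' @param A_w deformed cross-sectional wall area, m^2 (see [wall_area()]).
#' @param alpha opening angle, rad. Default 100 degrees.
#' @param lambda_zz axial pre-stretch. Default 1.20.
#' @param beta0 collagen fibre helix half-angle relative to the
#'   circumferential direction, rad. Default 35.3 degrees.
#' @return An object of class `reference_config` with fields `R_i`, `R_o`,
#'   `alpha`, `lambda_zz`, `beta0`, `A_w` and the sector factor `k`.
#' @examples
#' ref <- reference_config(R_i = 2.5e-3, A_w = wall_area(6.37e-3, 539e-6))
#' ref$k  # 2.25 for alpha = 100 degrees
#' @export
reference_config <- function(R_i, A_w, alpha = 100 * pi / 180,
                             lambda_zz = 1.20, beta0 = 35.3 * pi / 180) {
  stopifnot(R_i > 0, A_w > 0, alpha >= 0, alpha < pi,
            lambda_zz > 0, beta0 >= 0, beta0 <= pi / 2)
  R_o <- reference_outer_radius(R_i, A_w, alpha, lambda_zz)
  structure(list(
    R_i = R_i, R_o = R_o, alpha = alpha, lambda_zz = lambda_zz,
    beta0 = beta0, A_w = A_w, k = 2 * pi / (2 * pi - 2 * alpha)
  ), class = "reference_config")
}

#' @export
print.reference_config <- function(x, ...) {
  cat(sprintf(
    "Reference configuration: R_i = %.3f mm, R_o = %.3f mm, alpha = %.1f deg,\n  lambda_zz = %.2f, beta0 = %.1f deg, A_w = %.3f mm^2\n",
    x$R_i * 1e3, x$R_o * 1e3, x$alpha * 180 / pi, x$lambda_zz,
    x$beta0 * 180 / pi, x$A_w * 1e6))
  invisible(x)
}

#' Principal stretches at an unstressed radius for a given inflation state
#'
#' Maps material points from the stress-free sector to the loaded tube:
#' `r(R) = sqrt(r_i^2 + (R^2 - R_i^2) / (k * lambda_zz))`, circumferential
#' stretch `lambda_tt = k * r / R`, axial stretch fixed at `lambda_zz`, and
#' radial stretch from incompressibility.
#'
#' @param R unstressed radius (vectorised), m; must lie in `[R_i, R_o]`.
#' @param r_i loaded inner radius, m.
#' @param ref a [reference_config()].
#' @return List with components `lambda_rr`, `lambda_tt`, `lambda_zz`
#'   (each the length of `R`) and the mapped radius `r`.
#' @export
stretches_at <- function(R, r_i, ref) {
  if (any(R < ref$R_i - 1e-12 | R > ref$R_o + 1e-12)) {
    stop("R outside the wall [R_i, R_o]")
  }
  r <- sqrt(r_i^2 + (R^2 - ref$R_i^2) / (ref$k * ref$lambda_zz))
  lambda_tt <- ref$k * r / R
  lambda_rr <- 1 / (lambda_tt * ref$lambda_zz)
  list(lambda_rr = lambda_rr, lambda_tt = lambda_tt,
       lambda_zz = rep(ref$lambda_zz, length.out = length(R)), r = r)
}

#' Cauchy stress differences of the HGO wall material
#'
#' Computes `sigma_tt - sigma_rr` and `sigma_zz - sigma_rr` (the hydrostatic
#' pressure cancels in differences), plus the collagen-only part of the
#' circumferential difference. With fibre Green-Lagrange-type strain
#' `E = lambda_fibre^2 - 1` and
#' `lambda_fibre^2 = cos^2(beta0) lambda_tt^2 + sin^2(beta0) lambda_zz^2`:
#' \deqn{\Delta\sigma_{\theta\theta} = 2 c (\lambda_{\theta\theta}^2 -
#'   \lambda_{rr}^2) + 4 k_1 E e^{k_2 E^2} \cos^2\beta_0
#'   \lambda_{\theta\theta}^2}
#' and analogously for the axial difference with `sin^2(beta0) lambda_zz^2`.
#'
#' @param stretch list with `lambda_rr`, `lambda_tt`, `lambda_zz`
#'   (vectorised), e.g. from [stretches_at()].
#' @param params an [hgo_params()] object.
#' @param beta0 fibre helix half-angle, rad.
#' @return List with `dsig_tt`, `dsig_zz`, `dsig_tt_coll` (Pa) and
#'   `lambda_fibre`.
#' @export
stress_differences <- function(stretch, params, beta0) {
  lt2 <- stretch$lambda_tt^2
  lr2 <- stretch$lambda_rr^2
  lz2 <- stretch$lambda_zz^2
  cb2 <- cos(beta0)^2
  sb2 <- sin(beta0)^2
  lf2 <- cb2 * lt2 + sb2 * lz2
  E <- lf2 - 1
  coll <- 4 * params$k1 * E * exp(params$k2 * E^2)
  out <- list(
    dsig_tt = 2 * params$c_elast * (lt2 - lr2) + coll * cb2 * lt2,
    dsig_zz = 2 * params$c_elast * (lz2 - lr2) + coll * sb2 * lz2,
    dsig_tt_coll = coll * cb2 * lt2,
    lambda_fibre = sqrt(lf2)
  )
  if (any(!is.finite(out$dsig_tt)) || any(!is.finite(out$dsig_zz))) {
    stop("non-finite stress difference (exp(k2*E^2) overflow?)")
  }
  out
}

# Pressure / axial-force / collagen-pressure integrals across the wall for a
# vector of loaded inner radii. Fixed-order Gauss-Legendre in r over
# [r_i, r_o]; the integrand is smooth so 40 nodes are spectrally accurate.
# Returns one row per r_i.
wall_integrals <- function(r_i, ref, params, n_gauss = 40L) {
  gl <- gauss_rule(n_gauss)
  r_o <- sqrt(r_i^2 + ref$A_w / pi)
  half <- (r_o - r_i) / 2
  mid <- (r_o + r_i) / 2
  # nodes: length(r_i) x n_gauss
  r <- matrix(mid, nrow = length(r_i), ncol = n_gauss) + outer(half, gl$x)
  R2 <- ref$R_i^2 + ref$k * ref$lambda_zz * (r^2 - r_i^2)
  lambda_tt <- ref$k * r / sqrt(R2)
  lt2 <- lambda_tt^2
  lr2 <- 1 / (lt2 * ref$lambda_zz^2)
  cb2 <- cos(ref$beta0)^2
  sb2 <- sin(ref$beta0)^2
  lf2 <- cb2 * lt2 + sb2 * ref$lambda_zz^2
  E <- lf2 - 1
  coll <- 4 * params$k1 * E * exp(params$k2 * E^2)
  dsig_tt_coll <- coll * cb2 * lt2
  dsig_tt <- 2 * params$c_elast * (lt2 - lr2) + dsig_tt_coll
  dsig_zz <- 2 * params$c_elast * (ref$lambda_zz^2 - lr2) +
    coll * sb2 * ref$lambda_zz^2
  w <- gl$w
  P <- half * as.vector((dsig_tt / r) %*% w)
  P_coll <- half * as.vector((dsig_tt_coll / r) %*% w)
  Fz <- pi * half * as.vector(((2 * dsig_zz - dsig_tt) * r) %*% w)
  list(P = P, Fz = Fz, P_coll = P_coll, r_o = r_o,
       min_lambda_fibre = sqrt(min(lf2)))
}

#' Luminal pressure sustaining a given inflation state
#'
#' Integrates the radial momentum balance across the wall:
#' `P = integral over [r_i, r_o] of (sigma_tt - sigma_rr)/r dr`, by
#' fixed-order Gauss-Legendre quadrature.
#'
#' @param r_i loaded inner radius, m (vectorised).
#' @param ref a [reference_config()].
#' @param params an [hgo_params()].
#' @param n_gauss quadrature order (default 40).
#' @return Pressure(s) in Pa.
#' @export
luminal_pressure <- function(r_i, ref, params, n_gauss = 40L) {
  if (any(r_i <= 0)) stop("r_i must be positive")
  wall_integrals(r_i, ref, params, n_gauss)$P
}

#' Reduced axial force of an inflation state
#'
#' `F_z = pi * integral of (2 sigma_zz - sigma_rr - sigma_tt) r dr`, the
#' axial force in excess of that produced by pressure acting on closed ends.
#' The hydrostatic pressure cancels in the combination of differences.
#'
#' @inheritParams luminal_pressure
#' @return Force(s) in N.
#' @export
reduced_axial_force <- function(r_i, ref, params, n_gauss = 40L) {
  if (any(r_i <= 0)) stop("r_i must be positive")
  wall_integrals(r_i, ref, params, n_gauss)$Fz
}

#' Solve the inflation state at a target luminal pressure
#'
#' Finds the loaded inner radius at which the model pressure equals
#' `P_target`, by bracketed root search on the (monotone) pressure-radius
#' relation, refined to `|P(r_i) - P_target| <= 1e-6 * max(P_target, 1)`.
#'
#' @param P_target target pressure, Pa (>= 0).
#' @param ref a [reference_config()].
#' @param params an [hgo_params()].
#' @param n_gauss quadrature order.
#' @return An object of class `deformed_state`: list with `r_i`, `r_o`,
#'   `P`, `F_z`.
#' @export
solve_inflation <- function(P_target, ref, params, n_gauss = 40L) {
  if (P_target < 0) stop("P_target must be >= 0")
  f <- function(x) {
    val <- luminal_pressure(x, ref, params, n_gauss)
    # overflowed states are far above any physical pressure; cap to keep the
    # bracketing search monotone and warning-free
    if (!is.finite(val)) val <- 1e15
    val - P_target
  }
  lo <- 0.1 * ref$R_i
  hi <- 10 * ref$R_o
  flo <- f(lo)
  fhi <- f(hi)
  if (flo > 0 || fhi < 0) stop("inflation root not bracketed in [0.1 R_i, 10 R_o]")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-14 * ref$R_i + 1e-16)
  r_i <- root$root
  # secant polish on the pressure residual
  tol <- 1e-6 * max(P_target, 1)
  for (it in 1:10) {
    err <- f(r_i)
    if (abs(err) <= tol) break
    h <- 1e-7 * r_i
    slope <- (f(r_i + h) - err) / h
    r_i <- r_i - err / slope
  }
  if (abs(f(r_i)) > tol) stop("inflation solve did not reach pressure tolerance")
  ints <- wall_integrals(r_i, ref, params, n_gauss)
  structure(list(r_i = r_i, r_o = ints$r_o, P = ints$P, F_z = ints$Fz),
            class = "deformed_state")
}

#' @export
print.deformed_state <- function(x, ...) {
  cat(sprintf(
    "Deformed state: r_i = %.3f mm, r_o = %.3f mm, P = %.1f mmHg, F_z = %.3f N\n",
    x$r_i * 1e3, x$r_o * 1e3, Pa_to_mmHg(x$P), x$F_z))
  invisible(x)
}

#' Collagen share of the luminal pressure load
#'
#' At the inflation state solved for pressure `P`, splits the pressure
#' integral into its constituent parts and reports the collagen share as a
#' percentage:
#' `L_coll = 100 * integral(dsig_tt_coll / r) / P`.
#' Physically: the fraction of the blood-pressure load borne by the collagen
#' fibres (0% = all elastin, 100% = all collagen). An assertion verifies that
#' collagen fibres are extended (`lambda_fibre >= 1`) at every quadrature
#' node of the solved state, the condition under which the exponential fibre
#' energy is valid without a tension switch.
#'
#' @param P luminal pressure, Pa (> 0); vectorised.
#' @param ref a [reference_config()].
#' @param params an [hgo_params()].
#' @param n_gauss quadrature order.
#' @return Collagen load-bearing percentage(s) in \[0, 100\].
#' @export
collagen_load_fraction <- function(P, ref, params, n_gauss = 40L) {
  if (any(P <= 0)) stop("P must be positive")
  vapply(P, function(p) {
    st <- solve_inflation(p, ref, params, n_gauss)
    ints <- wall_integrals(st$r_i, ref, params, n_gauss)
    if (ints$min_lambda_fibre < 1) {
      stop("collagen fibres not in tension at the solved state")
    }
    100 * ints$P_coll / ints$P
  }, numeric(1))
}
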