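# Single-exponential (Hayashi-type) diameter-pressure curve anchored at the
# diastolic working point, and the pressure grid over which constitutive
# models are fitted.

#' Non-linearity factor of the exponential diameter-pressure curve
#'
#' `gamma = log(P_s / P_d) / (D_s^2 / D_d^2 - 1)`. The ratio form makes
#' gamma invariant to a common scaling of both pressures.
#'
#' @param P_d,P_s diastolic and systolic pressure, Pa (`P_s > P_d > 0`).
#' @param D_d,D_s diastolic and systolic outer diameter, m (`D_s > D_d > 0`).
#' @return Dimensionless stiffness (non-linearity) factor.
#' @examples
#' gamma_from_endpoints(mmHg_to_Pa(72), mmHg_to_Pa(130), 6.37e-3, 7.159e-3)
#' @export
gamma_from_endpoints <- function(P_d, P_s, D_d, D_s) {
  stopifnot(P_d > 0, P_s > 0, D_d > 0, D_s > 0)
  if (D_s == D_d) stop("D_s equals D_d: gamma undefined")
  log(P_s / P_d) / (D_s^2 / D_d^2 - 1)
}

#' Exponential diameter-pressure curve
#'
#' Constructs the single-exponential curve
#' `P(D) = P_d * exp(gamma * (D^2 / D_d^2 - 1))` through the diastolic and
#' systolic working points of one (possibly virtual) subject.
#'
#' @param P_d diastolic pressure, Pa.
#' @param D_d diastolic outer diameter, m.
#' @param gamma dimensionless non-linearity factor, e.g. from
#'   [gamma_from_endpoints()].
#' @return An object of class `exp_curve`.
#' @export
exp_curve <- function(P_d, D_d, gamma) {
  stopifnot(P_d > 0, D_d > 0, is.finite(gamma))
  structure(list(P_d = P_d, D_d = D_d, gamma = gamma), class = "exp_curve")
}

#' @export
print.exp_curve <- function(x, ...) {
  cat(sprintf("Exponential D-P curve: P_d = %.1f mmHg, D_d = %.2f mm, gamma = %.3f\n",
              Pa_to_mmHg(x$P_d), x$D_d * 1e3, x$gamma))
  invisible(x)
}

#' Evaluate the curve: pressure at diameter
#'
#' @param curve an [exp_curve()].
#' @param D outer diameter(s), m.
#' @return Pressure(s), Pa.
#' @export
pressure_at_diameter <- function(curve, D) {
  stopifnot(all(D > 0))
  curve$P_d * exp(curve$gamma * (D^2 / curve$D_d^2 - 1))
}

#' Invert the curve: diameter at pressure
#'
#' @param curve an [exp_curve()].
#' @param P pressure(s), Pa (> 0).
#' @return Outer diameter(s), m.
#' @export
diameter_at_pressure <- function(curve, P) {
  stopifnot(all(P > 0))
  if (curve$gamma == 0) stop("gamma = 0: curve is not invertible")
  arg <- 1 + log(P / curve$P_d) / curve$gamma
  if (any(arg <= 0)) stop("pressure outside the invertible range of the curve")
  curve$D_d * sqrt(arg)
}

#' Fitting-point grid over the extended pressure range
#'
#' Lays `n_P` pressures equally spaced on
#' `[P_d_sample - margin, P_s_sample + margin]` (the range over which the
#' exponential curve is taken as valid) and inverts the curve for the
#' matching diameters.
#'
#' @param curve an [exp_curve()].
#' @param P_d_sample,P_s_sample the sample's diastolic/systolic pressures, Pa.
#' @param margin extension beyond the diastolic-systolic range, Pa.
#'   Default 15 mmHg.
#' @param n_P number of fitting points (>= 2). Default 50.
#' @return data.frame with columns `P` (Pa) and `D` (m), both strictly
#'   increasing.
#' @export
fitting_grid <- function(curve, P_d_sample, P_s_sample,
                         margin = mmHg_to_Pa(15), n_P = 50L) {
  stopifnot(margin >= 0, n_P >= 2, P_s_sample > P_d_sample)
  lo <- P_d_sample - margin
  if (lo <= 0) stop("P_d - margin must be positive")
  P <- seq(lo, P_s_sample + margin, length.out = n_P)
  data.frame(P = P, D = diameter_at_pressure(curve, P))
}
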