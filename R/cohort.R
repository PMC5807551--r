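# Virtual measurement cohort: low-discrepancy samples inside the 95%
# uncertainty domains of the five measured variables (diastolic pressure,
# pulse pressure, diastolic diameter, distension, intima-media thickness).
#
# The uncertainty domains are Gaussian 95% intervals for the mean of
# N_rep repeated measurements (mean +/- 1.96 * SD_intra / sqrt(N_rep)), but
# the domains are *sampled uniformly* as a worst-case scenario; a Gaussian
# option exists but is off by default.

.default_measurement_spec <- list(
  P_d  = list(mean = 72,    sd = 3.0,   unit = "mmHg"),
  P_p  = list(mean = 58,    sd = 3.1,   unit = "mmHg"),
  D_d  = list(mean = 6.37,  sd = 0.22,  unit = "mm"),
  dD   = list(mean = 0.789, sd = 0.035, unit = "mm"),
  IMT  = list(mean = 539,   sd = 40,    unit = "um")
)

#' Specification of the measured variables and their uncertainty
#'
#' Group means and intra-subject standard deviations of the five measured
#' variables, in clinical units (mmHg, mm, um), plus the number of repeated
#' measurements `N_rep` that sets the width of the 95% uncertainty domain of
#' each mean. The defaults are the group-averaged carotid measurements of
#' twelve healthy volunteers that the study conditions prescribe.
#'
#' @param P_d diastolic pressure `c(mean, sd)` in mmHg. Default `c(72, 3.0)`.
#' @param P_p pulse pressure `c(mean, sd)` in mmHg. Default `c(58, 3.1)`.
#' @param D_d diastolic outer diameter `c(mean, sd)` in mm.
#'   Default `c(6.37, 0.22)`.
#' @param dD distension (systolic minus diastolic diameter) `c(mean, sd)`
#'   in mm. Default `c(0.789, 0.035)`.
#' @param IMT intima-media thickness `c(mean, sd)` in um.
#'   Default `c(539, 40)`.
#' @param N_rep number of repeated measurements (>= 1). Default 3.
#' @return An object of class `measurement_spec`.
#' @examples
#' spec <- measurement_spec()
#' uncertainty_domain(72, 3.0, 3)
#' @export
measurement_spec <- function(P_d = c(72, 3.0), P_p = c(58, 3.1),
                             D_d = c(6.37, 0.22), dD = c(0.789, 0.035),
                             IMT = c(539, 40), N_rep = 3L) {
  vars <- list(P_d = P_d, P_p = P_p, D_d = D_d, dD = dD, IMT = IMT)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    stopifnot(length(v) == 2, v[1] > 0, v[2] >= 0)
  }
  stopifnot(N_rep >= 1)
  structure(list(
    vars = lapply(names(vars), function(nm) {
      list(name = nm, mean = vars[[nm]][1], sd = vars[[nm]][2],
           unit = .default_measurement_spec[[nm]]$unit)
    }) |> stats::setNames(names(vars)),
    N_rep = as.integer(N_rep)
  ), class = "measurement_spec")
}

#' @export
print.measurement_spec <- function(x, ...) {
  cat(sprintf("Measurement spec (N_rep = %d):\n", x$N_rep))
  for (v in x$vars) {
    dom <- uncertainty_domain(v$mean, v$sd, x$N_rep)
    cat(sprintf("  %-4s %8.3f +/- %-6.3f %-4s  domain [%.3f ; %.3f]\n",
                v$name, v$mean, v$sd, v$unit, dom[1], dom[2]))
  }
  invisible(x)
}

#' 95% uncertainty domain of a repeated measurement's mean
#'
#' `mean +/- 1.96 * sd_intra / sqrt(N_rep)`: the Gaussian 95% interval for
#' the mean of `N_rep` independent repeats with intra-subject SD `sd_intra`.
#'
#' @param mean group-averaged value.
#' @param sd_intra intra-subject standard deviation (>= 0).
#' @param N_rep number of repeated measurements (>= 1).
#' @return `c(lo, hi)`.
#' @export
uncertainty_domain <- function(mean, sd_intra, N_rep) {
  stopifnot(sd_intra >= 0, N_rep >= 1)
  half <- 1.96 * sd_intra / sqrt(N_rep)
  c(mean - half, mean + half)
}

#' Generate the virtual measurement cohort
#'
#' Scales a 5-dimensional Sobol low-discrepancy point set onto the five
#' uncertainty domains, yielding `n_samples` virtual subjects. Derived
#' quantities are appended per sample: systolic pressure
#' `P_s = P_d + P_p`, systolic diameter `D_s = D_d + dD` (summands treated
#' as independent), and mean arterial pressure `P_m = P_d + P_p / 3`.
#' Samples violating physical invariants (`IMT < D_d/2`, `dD < D_d`,
#' positivity) are rejected; the number rejected is stored in the
#' `"n_rejected"` attribute (zero under the default spec, whose domains are
#' far from the invariant boundaries).
#'
#' @param spec a [measurement_spec()].
#' @param n_samples number of cohort samples (>= 1).
#' @param skip Sobol points to skip before sampling (default 0).
#' @param sampler `"uniform"` (default; worst-case uniform coverage of the
#'   domains) or `"gaussian"` (inverse-normal transform of the Sobol points,
#'   truncated to the 95% box).
#' @return data.frame of class `virtual_cohort` with columns `sample_id`,
#'   `Pd_mmHg`, `Pp_mmHg`, `Dd_mm`, `dD_mm`, `IMT_um`, `Ps_mmHg`, `Ds_mm`,
#'   `Pm_mmHg`.
#' @examples
#' cohort <- sobol_cohort(measurement_spec(), 16)
#' summary(cohort$Ps_mmHg)
#' @export
sobol_cohort <- function(spec, n_samples, skip = 0L,
                         sampler = c("uniform", "gaussian")) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(spec, "measurement_spec"), n_samples >= 1)
  u <- sobol_points(n_samples, dim = 5L, skip = skip)
  doms <- lapply(spec$vars, function(v) uncertainty_domain(v$mean, v$sd, spec$N_rep))
  vals <- matrix(0, nrow = n_samples, ncol = 5L)
  for (j in 1:5) {
    d <- doms[[j]]
    if (sampler == "uniform") {
      vals[, j] <- d[1] + u[, j] * (d[2] - d[1])
    } else {
      v <- spec$vars[[j]]
      z <- stats::qnorm(0.025 + u[, j] * 0.95)  # truncated to the 95% box
      vals[, j] <- v$mean + z * v$sd / sqrt(spec$N_rep)
    }
  }
  cohort <- data.frame(
    sample_id = seq_len(n_samples),
    Pd_mmHg = vals[, 1], Pp_mmHg = vals[, 2], Dd_mm = vals[, 3],
    dD_mm = vals[, 4], IMT_um = vals[, 5]
  )
  ok <- with(cohort, Pd_mmHg > 0 & Pp_mmHg > 0 & Dd_mm > 0 & dD_mm > 0 &
               IMT_um > 0 & dD_mm < Dd_mm & IMT_um * 1e-3 < Dd_mm / 2)
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(sprintf("sobol_cohort: rejected %d unphysical sample(s)", n_rejected))
    cohort <- cohort[ok, , drop = FALSE]
    cohort$sample_id <- seq_len(nrow(cohort))
  }
  cohort$Ps_mmHg <- cohort$Pd_mmHg + cohort$Pp_mmHg
  cohort$Ds_mm <- cohort$Dd_mm + cohort$dD_mm
  cohort$Pm_mmHg <- cohort$Pd_mmHg + cohort$Pp_mmHg / 3
  attr(cohort, "n_rejected") <- n_rejected
  attr(cohort, "N_rep") <- spec$N_rep
  class(cohort) <- c("virtual_cohort", "data.frame")
  cohort
}

#' Rebuild the cohort for several repetition counts
#'
#' Re-derives the uncertainty domains for each value of `N_rep` (domain
#' half-widths shrink with `1/sqrt(N_rep)`) and resamples the cohort, to
#' study how averaging more measurement repeats tightens the downstream
#' mechanical characteristics.
#'
#' @param spec a [measurement_spec()] (its `N_rep` is overridden).
#' @param n_samples cohort size per repetition count.
#' @param N_rep_values integer vector, e.g. `c(3, 5, 10)`.
#' @param skip,sampler passed to [sobol_cohort()].
#' @return Named list of cohorts, one per `N_rep` value.
#' @export
repetition_sweep <- function(spec, n_samples, N_rep_values = c(3L, 5L, 10L),
                             skip = 0L, sampler = "uniform") {
  out <- lapply(N_rep_values, function(nr) {
    s <- spec
    s$N_rep <- as.integer(nr)
    sobol_cohort(s, n_samples, skip = skip, sampler = sampler)
  })
  names(out) <- paste0("N_rep_", N_rep_values)
  out
}

# Convert one cohort row (clinical units) to SI quantities used by the
# mechanics and fitting layers.
sample_to_si <- function(row) {
  list(
    P_d = mmHg_to_Pa(row$Pd_mmHg), P_p = mmHg_to_Pa(row$Pp_mmHg),
    P_s = mmHg_to_Pa(row$Ps_mmHg), P_m = mmHg_to_Pa(row$Pm_mmHg),
    D_d = row$Dd_mm * 1e-3, D_s = row$Ds_mm * 1e-3,
    dD = row$dD_mm * 1e-3, IMT = row$IMT_um * 1e-6
  )
}

#' The group-averaged sample as a one-row cohort
#'
#' Convenience constructor for the sample whose measured variables equal the
#' group means of the measurement specification (the representative sample).
#'
#' @param spec a [measurement_spec()].
#' @return One-row `virtual_cohort` data.frame.
#' @export
mean_sample <- function(spec = measurement_spec()) {
  m <- vapply(spec$vars, function(v) v$mean, numeric(1))
  cohort <- data.frame(
    sample_id = 1L, Pd_mmHg = m[["P_d"]], Pp_mmHg = m[["P_p"]],
    Dd_mm = m[["D_d"]], dD_mm = m[["dD"]], IMT_um = m[["IMT"]]
  )
  cohort$Ps_mmHg <- cohort$Pd_mmHg + cohort$Pp_mmHg
  cohort$Ds_mm <- cohort$Dd_mm + cohort$dD_mm
  cohort$Pm_mmHg <- cohort$Pd_mmHg + cohort$Pp_mmHg / 3
  class(cohort) <- c("virtual_cohort", "data.frame")
  cohort
}
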