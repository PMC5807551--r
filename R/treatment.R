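# Simulated AGE-breaker (collagen cross-link breaker) therapy: reduce the
# collagen parameters k1 and k2 of every fitted realisation by a fixed
# fraction (40% by default), then re-solve the inflation states to obtain
# post-treatment diameters, collagen load bearing, and area compliance.

#' Apply a simulated AGE-breaker to a fitted parameter set
#'
#' Scales the collagen parameters `k1` and `k2` by `1 - reduction`; the
#' elastin stiffness and the unstressed radius are unchanged (the drug is
#' assumed to act on collagen cross-links only).
#'
#' @param fit an [hgo_params()] object or an `hgo_fit` from [fit_sample()].
#' @param reduction fractional reduction in `0 <= reduction < 1`
#'   (default 0.40).
#' @return An [hgo_params()] with reduced collagen parameters.
#' @examples
#' apply_age_breaker(hgo_params(40.1e3, 6.9e3, 8.5))
#' @export
apply_age_breaker <- function(fit, reduction = 0.40) {
  stopifnot(reduction >= 0, reduction < 1)
  p <- if (inherits(fit, "hgo_fit")) fit$params else fit
  stopifnot(inherits(p, "hgo_params"))
  hgo_params(p$c_elast, p$k1 * (1 - reduction), p$k2 * (1 - reduction))
}

#' Area compliance from diastolic/systolic diameters and pressures
#'
#' `C_A = (A_s - A_d) / (P_s - P_d)` with `A = pi D^2 / 4` the
#' lumen-equivalent cross-sectional areas computed from the outer
#' diameters. SI in, SI out (m^2/Pa); multiply by `1e6 * 133.322` for
#' mm^2/mmHg.
#'
#' @param D_d,D_s diastolic and systolic outer diameter, m (`D_s >= D_d`).
#' @param P_d,P_s diastolic and systolic pressure, Pa (`P_s > P_d`).
#' @return Area compliance in m^2/Pa.
#' @examples
#' # Group-averaged carotid values, reported in mm^2/mmHg:
#' area_compliance(6.37e-3, 7.159e-3, mmHg_to_Pa(72), mmHg_to_Pa(130)) *
#'   1e6 * 133.322
#' @export
area_compliance <- function(D_d, D_s, P_d, P_s) {
  if (any(P_s <= P_d)) stop("degenerate pressures: P_s must exceed P_d")
  stopifnot(all(D_d > 0), all(D_s >= D_d))
  pi * (D_s^2 - D_d^2) / (4 * (P_s - P_d))
}

#' Simulate AGE-breaker treatment across fitted cohort realisations
#'
#' For each converged fit: reduce `k1`, `k2` by `reduction`; re-solve the
#' inflation states at the sample's (unchanged) diastolic and systolic
#' pressures for the post-treatment outer diameters; recompute the collagen
#' load-bearing percentages; and compute area compliance before treatment
#' (from the sample's measured diameters, as observed) and after treatment
#' (from the model-predicted diameters at the same pressures).
#'
#' @param fits an `hgo_cohort_fits` data.frame from [fit_cohort()].
#' @param cohort the matching [sobol_cohort()] (aligned by `sample_id`).
#' @param reduction fractional `k1`/`k2` reduction (default 0.40).
#' @param config the [fit_config()] used for the fits (kinematic constants).
#' @return data.frame of class `treatment_results`: per realisation the
#'   pre/post collagen parameters, pre/post area compliance (mm^2/mmHg),
#'   pre/post `L_coll` at the three pressure levels (percent), and the
#'   post-treatment model diameters (mm).
#' @export
simulate_treatment <- function(fits, cohort, reduction = 0.40,
                               config = attr(fits, "config")) {
  if (is.null(config)) config <- fit_config()
  stopifnot(all(fits$sample_id %in% cohort$sample_id))
  ca_unit <- 1e6 * 133.322  # m^2/Pa -> mm^2/mmHg
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    fr <- fits[i, ]
    out <- data.frame(
      sample_id = fr$sample_id,
      k1_pre_kPa = fr$k1_kPa, k2_pre = fr$k2,
      k1_post_kPa = fr$k1_kPa * (1 - reduction),
      k2_post = fr$k2 * (1 - reduction),
      CA_pre_mm2_mmHg = NA_real_, CA_post_mm2_mmHg = NA_real_,
      Lcoll_Pd_pre_pct = fr$Lcoll_Pd_pct, Lcoll_Pm_pre_pct = fr$Lcoll_Pm_pct,
      Lcoll_Ps_pre_pct = fr$Lcoll_Ps_pct,
      Lcoll_Pd_post_pct = NA_real_, Lcoll_Pm_post_pct = NA_real_,
      Lcoll_Ps_post_pct = NA_real_,
      Dd_post_mm = NA_real_, Ds_post_mm = NA_real_, ok = FALSE
    )
    if (!isTRUE(fr$converged)) return(out)
    samp <- cohort[cohort$sample_id == fr$sample_id, , drop = FALSE]
    si <- sample_to_si(samp)
    out$CA_pre_mm2_mmHg <-
      area_compliance(si$D_d, si$D_s, si$P_d, si$P_s) * ca_unit
    res <- tryCatch({
      A_w <- wall_area(si$D_d, si$IMT)
      pre <- hgo_params(fr$c_elast_kPa * 1e3, fr$k1_kPa * 1e3, fr$k2)
      post <- apply_age_breaker(pre, reduction)
      ref <- reference_config(fr$Ri_mm * 1e-3, A_w, alpha = config$alpha,
                              lambda_zz = config$lambda_zz,
                              beta0 = config$beta0)
      st_d <- solve_inflation(si$P_d, ref, post, config$n_gauss)
      st_s <- solve_inflation(si$P_s, ref, post, config$n_gauss)
      lc <- collagen_load_fraction(c(si$P_d, si$P_m, si$P_s), ref, post,
                                   config$n_gauss)
      list(D_d = 2 * st_d$r_o, D_s = 2 * st_s$r_o, lc = lc)
    }, error = function(e) NULL)
    if (is.null(res)) return(out)
    out$Dd_post_mm <- res$D_d * 1e3
    out$Ds_post_mm <- res$D_s * 1e3
    out$CA_post_mm2_mmHg <-
      area_compliance(res$D_d, res$D_s, si$P_d, si$P_s) * ca_unit
    out$Lcoll_Pd_post_pct <- res$lc[1]
    out$Lcoll_Pm_post_pct <- res$lc[2]
    out$Lcoll_Ps_post_pct <- res$lc[3]
    out$ok <- TRUE
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "reduction") <- reduction
  class(out) <- c("treatment_results", "data.frame")
  out
}

#' Cohort-average model diameter-pressure curve
#'
#' Pointwise mean of the model-predicted outer diameters over the fitted
#' realisations, on a common pressure grid (reporting aid for comparing the
#' pre- and post-treatment average curves).
#'
#' @param fits an `hgo_cohort_fits` data.frame.
#' @param cohort the matching cohort.
#' @param pressures pressure grid, Pa. Default 40 to 160 mmHg in 25 steps.
#' @param reduction optional `k1`/`k2` reduction applied before solving.
#' @param config the [fit_config()] used for the fits.
#' @return data.frame with `P_mmHg` and `D_mean_mm`.
#' @export
average_dp_curve <- function(fits, cohort,
                             pressures = mmHg_to_Pa(seq(40, 160, length.out = 25)),
                             reduction = 0, config = attr(fits, "config")) {
  if (is.null(config)) config <- fit_config()
  ok <- which(fits$converged)
  D <- matrix(NA_real_, length(ok), length(pressures))
  for (jj in seq_along(ok)) {
    i <- ok[jj]
    fr <- fits[i, ]
    samp <- cohort[cohort$sample_id == fr$sample_id, , drop = FALSE]
    si <- sample_to_si(samp)
    A_w <- wall_area(si$D_d, si$IMT)
    par <- hgo_params(fr$c_elast_kPa * 1e3, fr$k1_kPa * 1e3, fr$k2)
    if (reduction > 0) par <- apply_age_breaker(par, reduction)
    ref <- reference_config(fr$Ri_mm * 1e-3, A_w, alpha = config$alpha,
                            lambda_zz = config$lambda_zz, beta0 = config$beta0)
    D[jj, ] <- vapply(pressures, function(p) {
      st <- tryCatch(solve_inflation(p, ref, par, config$n_gauss),
                     error = function(e) NULL)
      if (is.null(st)) NA_real_ else 2 * st$r_o * 1e3
    }, numeric(1))
  }
  data.frame(P_mmHg = Pa_to_mmHg(pressures),
             D_mean_mm = colMeans(D, na.rm = TRUE))
}
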