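test_that("wall area follows the annulus formula and its limits", {
  # group-means geometry: direct evaluation of the annulus formula
  expect_equal(wall_area(6.37e-3, 539e-6) * 1e6, 9.87374, tolerance = 1e-5)
  # degenerate lumen: solid disc
  D <- 5e-3
  expect_equal(wall_area(D, D / 2), pi * D^2 / 4, tolerance = 1e-12)
  # thin-wall limit: A_w ~ pi * D * IMT
  expect_equal(wall_area(D, 1e-9), pi * D * 1e-9, tolerance = 1e-3)
  expect_error(wall_area(5e-3, 3e-3), "IMT")
  expect_error(wall_area(-1, 1e-4), "positive")
})

test_that("reference configuration closes the opening-angle kinematics", {
  # alpha = 100 deg gives sector factor 360/160 = 2.25 exactly
  ref <- reference_config(2.5e-3, 9.874e-6)
  expect_identical(ref$k, 2.25)
  # area-closure identity to 1e-12 relative
  expect_equal(ref$R_o^2 - ref$R_i^2, ref$k * ref$lambda_zz * ref$A_w / pi,
               tolerance = 1e-12)
  # closed ring, no pre-stretch
  R_o <- reference_outer_radius(2.5e-3, 9.874e-6, alpha = 0, lambda_zz = 1)
  expect_equal(R_o^2 - (2.5e-3)^2, 9.874e-6 / pi, tolerance = 1e-12)
  # arithmetic oracle for the group-means-scale case
  expect_equal(reference_outer_radius(2.5e-3, 9.874e-6, 100 * pi / 180, 1.2),
               sqrt(6.25e-6 + 2.7 * 9.874e-6 / pi), tolerance = 1e-12)
})

test_that("stretch mapping is incompressible and conserves wall area", {
  ref <- reference_config(5.8e-3, wall_area(6.37e-3, 539e-6))
  r_i <- 2.6e-3
  R <- seq(ref$R_i, ref$R_o, length.out = 41)
  st <- stretches_at(R, r_i, ref)
  expect_true(all(abs(st$lambda_rr * st$lambda_tt * st$lambda_zz - 1) < 1e-12))
  # deformed annulus area equals A_w (algebraic identity, checked numerically)
  expect_equal(st$r[41]^2 - st$r[1]^2,
               (ref$R_o^2 - ref$R_i^2) / (ref$k * ref$lambda_zz),
               tolerance = 1e-12)
  expect_equal(pi * (st$r[41]^2 - st$r[1]^2), ref$A_w, tolerance = 1e-12)
  # identity map: no opening angle, no pre-stretch, r_i = R_i
  ref0 <- reference_config(2.5e-3, 9.874e-6, alpha = 0, lambda_zz = 1)
  st0 <- stretches_at(ref0$R_i, ref0$R_i, ref0)
  expect_equal(st0$lambda_tt, 1, tolerance = 1e-12)
  expect_equal(st0$lambda_rr, 1, tolerance = 1e-12)
  expect_error(stretches_at(ref$R_o * 1.1, r_i, ref), "outside")
})

test_that("stress differences match the finite-difference SEF oracle", {
  beta0 <- 35.3 * pi / 180
  params <- hgo_params(40e3, 7e3, 8.5)
  st <- random_stretches(100)
  ds <- stress_differences(st, params, beta0)
  h <- 1e-6
  for (i in seq_len(100)) {
    lam <- c(st$lambda_rr[i], st$lambda_tt[i], st$lambda_zz[i])
    dW <- vapply(1:3, function(j) {
      lp <- lam; lm <- lam
      lp[j] <- lp[j] + h
      lm[j] <- lm[j] - h
      (sef_total(lp[1], lp[2], lp[3], params, beta0) -
         sef_total(lm[1], lm[2], lm[3], params, beta0)) / (2 * h)
    }, numeric(1))
    dsig_tt_fd <- lam[2] * dW[2] - lam[1] * dW[1]
    dsig_zz_fd <- lam[3] * dW[3] - lam[1] * dW[1]
    expect_equal(ds$dsig_tt[i], dsig_tt_fd, tolerance = 1e-6)
    expect_equal(ds$dsig_zz[i], dsig_zz_fd, tolerance = 1e-6)
  }
})

test_that("stress differences: identity state and elastin-only closed form", {
  beta0 <- 35.3 * pi / 180
  st1 <- list(lambda_rr = 1, lambda_tt = 1, lambda_zz = 1)
  # at the identity the fibre strain vanishes and so do all differences
  ds1 <- stress_differences(st1, hgo_params(40e3, 7e3, 8.5), beta0)
  expect_equal(ds1$dsig_tt, 0)
  expect_equal(ds1$dsig_zz, 0)
  expect_equal(ds1$dsig_tt_coll, 0)
  # k1 = 0: neo-Hookean tube, exact closed form
  st <- random_stretches(20, seed = 11)
  ds <- stress_differences(st, hgo_params(55e3, 0, 3), beta0)
  expect_equal(ds$dsig_tt, 2 * 55e3 * (st$lambda_tt^2 - st$lambda_rr^2),
               tolerance = 1e-14)
  expect_equal(ds$dsig_tt_coll, rep(0, 20))
})

test_that("pressure quadrature agrees with a dense trapezoid oracle", {
  cs <- ref_case()
  for (r_i in c(2.4e-3, 2.65e-3, 3.0e-3)) {
    r_o <- sqrt(r_i^2 + cs$A_w / pi)
    r <- seq(r_i, r_o, length.out = 20001)
    R <- sqrt(cs$ref$R_i^2 + cs$ref$k * cs$ref$lambda_zz * (r^2 - r_i^2))
    st <- list(lambda_tt = cs$ref$k * r / R,
               lambda_rr = R / (cs$ref$k * r * cs$ref$lambda_zz),
               lambda_zz = rep(cs$ref$lambda_zz, length(r)))
    ds <- stress_differences(st, cs$params, cs$ref$beta0)
    P_trap <- pracma::trapz(r, ds$dsig_tt / r)
    Fz_trap <- pi * pracma::trapz(r, (2 * ds$dsig_zz - ds$dsig_tt) * r)
    expect_equal(luminal_pressure(r_i, cs$ref, cs$params), P_trap,
                 tolerance = 1e-8)
    expect_equal(reduced_axial_force(r_i, cs$ref, cs$params), Fz_trap,
                 tolerance = 1e-8)
  }
})

test_that("elastin-only pressure scales linearly in the stiffness", {
  cs <- ref_case()
  p1 <- hgo_params(30e3, 0, 1)
  p2 <- hgo_params(60e3, 0, 1)
  expect_equal(2 * luminal_pressure(2.7e-3, cs$ref, p1),
               luminal_pressure(2.7e-3, cs$ref, p2), tolerance = 1e-12)
})

test_that("thin-wall limit recovers the Laplace law within 1%", {
  # scale the wall area down by 1e-3: thickness/radius ~ 5e-5
  A_w <- wall_area(6.37e-3, 539e-6) * 1e-3
  ref <- reference_config(5.8e-3, A_w)
  params <- hgo_params(47.9e3, 1.0e3, 9.9)
  r_i <- 2.9e-3
  r_o <- sqrt(r_i^2 + A_w / pi)
  h <- r_o - r_i
  r_mid <- (r_i + r_o) / 2
  R_mid <- sqrt(ref$R_i^2 + ref$k * ref$lambda_zz * (r_mid^2 - r_i^2))
  lt <- ref$k * r_mid / R_mid
  st <- list(lambda_tt = lt, lambda_rr = 1 / (lt * ref$lambda_zz),
             lambda_zz = ref$lambda_zz)
  ds <- stress_differences(st, params, ref$beta0)
  P_laplace <- h * ds$dsig_tt / r_mid
  P_model <- luminal_pressure(r_i, ref, params)
  expect_lt(abs(P_model - P_laplace) / abs(P_laplace), 0.01)
})

test_that("inflation solve round-trips, is monotone, and conserves area", {
  cs <- ref_case()
  P_targets <- mmHg_to_Pa(c(72, 91.33, 130))
  r_prev <- 0
  for (P in P_targets) {
    st <- solve_inflation(P, cs$ref, cs$params)
    expect_lt(abs(luminal_pressure(st$r_i, cs$ref, cs$params) - P), 1e-6 * P)
    # incompressibility: deformed annulus area equals A_w to 1e-10 relative
    expect_equal(pi * (st$r_o^2 - st$r_i^2), cs$A_w, tolerance = 1e-10)
    expect_gt(st$r_i, r_prev)
    r_prev <- st$r_i
  }
  # pressure is monotone in r_i across the physiological range
  ri_range <- seq(0.8 * solve_inflation(mmHg_to_Pa(72), cs$ref, cs$params)$r_i,
                  1.2 * solve_inflation(mmHg_to_Pa(130), cs$ref, cs$params)$r_i,
                  length.out = 30)
  P_seq <- luminal_pressure(ri_range, cs$ref, cs$params)
  expect_true(all(diff(P_seq) > 0))
})

test_that("collagen load fraction is zero without collagen and monotone in pressure", {
  cs <- ref_case()
  elastin_only <- hgo_params(47.9e3, 0, 9.9)
  expect_equal(collagen_load_fraction(mmHg_to_Pa(c(72, 130)), cs$ref, elastin_only),
               c(0, 0), tolerance = 1e-14)
  P_grid <- mmHg_to_Pa(seq(72, 130, length.out = 12))
  lc <- collagen_load_fraction(P_grid, cs$ref, cs$params)
  expect_true(all(diff(lc) >= 0))
  expect_true(all(lc >= 0 & lc <= 100))
})
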