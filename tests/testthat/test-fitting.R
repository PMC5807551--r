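test_that("objective decomposes exactly into its weighted error terms", {
  ms <- means_sample()
  cfg <- fit_config()
  theta <- c(47.9, 1.0, 9.9, 5.78)
  o <- hgo_objective(theta, ms, cfg)
  expect_equal(o$eps_T, cfg$w_P * o$eps_P + cfg$w_Fz * o$eps_Fz,
               tolerance = 1e-12)
  expect_gt(o$eps_P, 0)
  expect_gt(o$eps_Fz, 0)
})

test_that("pressure errors are normalised by pulse pressure", {
  # same absolute residuals, doubled pulse-pressure normaliser: eps_P / 4
  ms <- means_sample()
  cfg <- fit_config()
  prep <- hgowall:::sample_grid(ms, cfg)
  theta <- c(47.9, 1.0, 9.9, 5.78)
  r1 <- hgowall:::fit_residuals(theta, prep, cfg)
  prep2 <- prep
  prep2$si$P_p <- 2 * prep$si$P_p
  r2 <- hgowall:::fit_residuals(theta, prep2, cfg)
  nP <- cfg$n_P
  expect_equal(sum(r2[1:nP]^2), sum(r1[1:nP]^2) / 4, tolerance = 1e-12)
  # the axial-force residuals are untouched
  expect_equal(r2[(nP + 1):(2 * nP)], r1[(nP + 1):(2 * nP)])
})

test_that("start points are deterministic, shared, and bounded", {
  cfg <- fit_config(seed = 3, n_starts = 10)
  s1 <- hgowall:::start_points(cfg)
  s2 <- hgowall:::start_points(cfg)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(10, 4))
  expect_true(all(sweep(s1, 2, cfg$lower, `>=`)))
  expect_true(all(sweep(s1, 2, cfg$upper, `<=`)))
  # a different seed moves the random starts but keeps the centre start
  s3 <- hgowall:::start_points(fit_config(seed = 4, n_starts = 10))
  expect_identical(s1[1, ], s3[1, ])
  expect_false(identical(s1[-1, ], s3[-1, ]))
})

test_that("noise-free model-generated data are recovered within 1%", {
  fx <- make_fixtures(seed = 1)
  f <- fit_dp_data(fx$clean$P, fx$clean$D, fx$A_w, P_p = mmHg_to_Pa(58),
                   config = fit_config(n_starts = 6),
                   f_z_target = fx$clean$Fz)
  expect_true(f$converged)
  # the generating parameters attain exactly zero residual
  expect_lt(f$eps_T, 1e-10)
  expect_equal(f$theta, fx$truth, tolerance = 0.01)
})

test_that("mildly noisy data still recover the truth approximately", {
  fx <- make_fixtures(seed = 2)
  f <- fit_dp_data(fx$noisy$P, fx$noisy$D, fx$A_w, P_p = mmHg_to_Pa(58),
                   config = fit_config(n_starts = 6),
                   f_z_target = fx$clean$Fz)
  expect_true(f$converged)
  # 1 mmHg pressure noise: constitutive parameters within ~15%
  expect_equal(f$theta[1], fx$truth[1], tolerance = 0.15)
  expect_equal(f$theta[4], fx$truth[4], tolerance = 0.15)
})

test_that("group-means fit is robust across starts and n_P choices", {
  ms <- means_sample()
  f <- fit_sample(ms, fit_config(n_starts = 10))
  expect_true(f$converged)
  expect_equal(f$eps_T, 10 * f$eps_P + f$eps_Fz, tolerance = 1e-12)
  expect_equal(f$E_RMS_P, 100 * sqrt(f$eps_P), tolerance = 1e-12)
  # well-identified parameters are insensitive to the grid density;
  # k1 (the ill-conditioned collagen scale) is allowed more play
  f25 <- fit_sample(ms, fit_config(n_starts = 10, n_P = 25))
  f100 <- fit_sample(ms, fit_config(n_starts = 10, n_P = 100))
  for (j in c(1, 3, 4)) {
    expect_equal(f25$theta[j], f$theta[j], tolerance = 0.005)
    expect_equal(f100$theta[j], f$theta[j], tolerance = 0.005)
  }
  expect_equal(f25$theta[2], f$theta[2], tolerance = 0.05)
  expect_equal(f100$theta[2], f$theta[2], tolerance = 0.05)
  # collagen load bearing increases monotonically with pressure
  expect_true(f$L_coll[["P_d"]] < f$L_coll[["P_m"]])
  expect_true(f$L_coll[["P_m"]] < f$L_coll[["P_s"]])
})

test_that("cohort fitting is deterministic and reduces to fit_sample", {
  spec <- measurement_spec()
  cohort <- sobol_cohort(spec, 3)
  cfg <- fit_config(n_starts = 6)
  fits1 <- fit_cohort(cohort, cfg)
  fits2 <- fit_cohort(cohort, cfg)
  expect_equal(as.data.frame(fits1), as.data.frame(fits2))
  # single-sample cohort agrees with a direct fit using the shared starts
  one <- fit_cohort(cohort[1, , drop = FALSE], cfg)
  f1 <- fit_sample(cohort[1, , drop = FALSE], cfg)
  expect_equal(one$c_elast_kPa, f1$theta[1], tolerance = 1e-10)
  expect_equal(one$Lcoll_Ps_pct, unname(f1$L_coll[["P_s"]]), tolerance = 1e-8)
  # identical samples give identical fits
  twin <- cohort[c(1, 1), ]
  twin$sample_id <- 1:2
  ftwin <- fit_cohort(twin, cfg)
  expect_equal(ftwin$c_elast_kPa[1], ftwin$c_elast_kPa[2])
  expect_equal(ftwin$k2[1], ftwin$k2[2])
})
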