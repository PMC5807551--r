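# Shared fixtures for the test suite. Everything is generated in code; the
# group-means reference state uses the default measurement specification.

means_sample <- function() mean_sample(measurement_spec())

# A reference configuration + parameter set in the physiological operating
# range (typical of converged fits to the group-means curve).
ref_case <- function() {
  A_w <- wall_area(6.37e-3, 539e-6)
  list(
    ref = reference_config(R_i = 5.8e-3, A_w = A_w),
    params = hgo_params(c_elast = 47.9e3, k1 = 1.0e3, k2 = 9.9),
    A_w = A_w
  )
}

# Random admissible stretch triples (incompressible).
random_stretches <- function(n, seed = 7) {
  set.seed(seed)
  lambda_tt <- runif(n, 0.9, 1.35)
  lambda_zz <- runif(n, 1.0, 1.3)
  list(lambda_tt = lambda_tt, lambda_zz = lambda_zz,
       lambda_rr = 1 / (lambda_tt * lambda_zz))
}

# One aggregated expectation over a set of published-value comparisons, so a
# block of related comparisons reports as a single (richly annotated)
# pass/failure.
expect_all_close <- function(label, actual, expected, tol,
                             type = c("rel", "abs")) {
  type <- rep(match.arg(type, several.ok = TRUE), length.out = length(actual))
  dev <- ifelse(type == "rel",
                abs(actual - expected) / abs(expected),
                abs(actual - expected))
  ok <- dev <= tol
  msg <- paste(sprintf(
    "  %s: got %.4g, published %.4g (deviation %.3g, tolerance %.3g %s)",
    label, actual, expected, dev, tol, type), collapse = "\n")
  testthat::expect(all(ok),
                   paste0("comparisons outside tolerance:\n", msg))
  invisible(ok)
}

# Total strain energy density (elastin + collagen) for the finite-difference
# stress oracle; independent of the stress_differences() implementation.
sef_total <- function(lrr, ltt, lzz, params, beta0) {
  I1 <- lrr^2 + ltt^2 + lzz^2
  lf2 <- cos(beta0)^2 * ltt^2 + sin(beta0)^2 * lzz^2
  params$c_elast * (I1 - 3) +
    params$k1 / params$k2 * (exp(params$k2 * (lf2 - 1)^2) - 1)
}
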