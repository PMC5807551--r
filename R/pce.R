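# Regression-based polynomial chaos expansion (PCE) over independent
# uniform inputs, with leave-one-out cross-validation (Q2) and
# variance-based Sobol sensitivity indices from the coefficient
# decomposition.
#
# The basis is the tensorised orthonormal Legendre family, matching the
# uniform sampling measure of the virtual cohort's uncertainty boxes; with
# an orthonormal basis the variance decomposition is a sum of squared
# coefficients grouped by multi-index support.

# Orthonormal Legendre polynomials psi_0..psi_p evaluated at u in [-1,1]:
# psi_k = sqrt(2k+1) P_k, orthonormal under the uniform density 1/2.
legendre_orthonormal <- function(u, p) {
  out <- matrix(0, length(u), p + 1)
  out[, 1] <- 1
  if (p >= 1) out[, 2] <- u
  if (p >= 2) {
    for (k in 1:(p - 1)) {
      out[, k + 2] <- ((2 * k + 1) * u * out[, k + 1] - k * out[, k]) / (k + 1)
    }
  }
  sweep(out, 2, sqrt(2 * seq(0, p) + 1), `*`)
}

# All multi-indices of dimension d with total degree <= p (rows).
total_degree_indices <- function(d, p) {
  grid <- as.matrix(expand.grid(rep(list(0:p), d)))
  grid <- grid[rowSums(grid) <= p, , drop = FALSE]
  grid <- grid[order(rowSums(grid)), , drop = FALSE]
  dimnames(grid) <- NULL
  grid
}

# Map inputs (n x d) affinely onto [-1,1]^d given domains (2 x d matrix,
# rows lo/hi).
map_to_unit <- function(inputs, domains) {
  inputs <- as.matrix(inputs)
  lo <- domains[1, ]
  hi <- domains[2, ]
  sweep(sweep(inputs, 2, (lo + hi) / 2, `-`), 2, (hi - lo) / 2, `/`)
}

pce_design <- function(U, index_set) {
  d <- ncol(U)
  p <- max(index_set)
  per_var <- lapply(seq_len(d), function(j) legendre_orthonormal(U[, j], p))
  Phi <- matrix(1, nrow(U), nrow(index_set))
  for (j in seq_len(d)) {
    Phi <- Phi * per_var[[j]][, index_set[, j] + 1, drop = FALSE]
  }
  Phi
}

#' Fit a polynomial chaos meta-model by least squares
#'
#' Regresses an output quantity on the orthonormal Legendre tensor basis of
#' total degree `degree` over the input box, and computes the closed-form
#' leave-one-out cross-validation coefficient Q2 of the regression.
#'
#' @param inputs n x d matrix (or data.frame) of input samples, uniform over
#'   the box given by `domains`.
#' @param outputs numeric vector of length n (the fitted mechanical
#'   characteristic, one value per input sample).
#' @param degree total polynomial degree of the expansion.
#' @param domains 2 x d matrix of input bounds (row 1 = lower, row 2 =
#'   upper); defaults to the observed ranges of `inputs`.
#' @return An object of class `pce_model`: coefficients, multi-index set,
#'   `domains`, `degree`, `q2`, and the output mean/variance implied by the
#'   expansion.
#' @export
fit_pce <- function(inputs, outputs, degree, domains = NULL) {
  inputs <- as.matrix(inputs)
  keep <- is.finite(outputs) & apply(is.finite(inputs), 1, all)
  inputs <- inputs[keep, , drop = FALSE]
  outputs <- outputs[keep]
  n <- nrow(inputs)
  d <- ncol(inputs)
  if (is.null(domains)) {
    domains <- rbind(apply(inputs, 2, min), apply(inputs, 2, max))
  }
  index_set <- total_degree_indices(d, degree)
  m <- nrow(index_set)
  if (n <= m) stop("need more samples than basis terms (n > ", m, ")")
  U <- map_to_unit(inputs, domains)
  Phi <- pce_design(U, index_set)
  qr_ <- qr(Phi)
  if (qr_$rank < m) stop("rank-deficient design: lower the degree or add samples")
  coef <- qr.coef(qr_, outputs)
  fitted <- as.vector(Phi %*% coef)
  resid <- outputs - fitted
  # closed-form leave-one-out residuals of linear least squares
  Qm <- qr.Q(qr_)
  hat <- rowSums(Qm^2)
  loo <- resid / (1 - hat)
  tss <- sum((outputs - mean(outputs))^2)
  # constant output: regression is well defined (constant term only) but the
  # cross-validation coefficient is 0/0
  q2 <- if (tss == 0) NA_real_ else 1 - sum(loo^2) / tss
  structure(list(
    coef = coef, index_set = index_set, domains = domains, degree = degree,
    q2 = q2, n = n, mean = coef[1], variance = sum(coef[-1]^2),
    r2 = 1 - sum(resid^2) / tss
  ), class = "pce_model")
}

#' @export
print.pce_model <- function(x, ...) {
  cat(sprintf(
    "PCE meta-model: degree %d, %d terms, %d samples, Q2 = %.5f\n",
    x$degree, length(x$coef), x$n, x$q2))
  invisible(x)
}

#' Predict from a fitted PCE meta-model
#'
#' @param object a [fit_pce()] model.
#' @param newdata matrix/data.frame of inputs on the original scale.
#' @param ... unused.
#' @return Numeric vector of meta-model predictions.
#' @export
predict.pce_model <- function(object, newdata, ...) {
  U <- map_to_unit(as.matrix(newdata), object$domains)
  as.vector(pce_design(U, object$index_set) %*% object$coef)
}

#' Leave-one-out cross-validation coefficient of a PCE fit
#'
#' `Q2 = 1 - PRESS / TSS` with the closed-form leave-one-out residuals of
#' linear regression. Values near 1 indicate a predictive meta-model; the
#' acceptance gate used downstream is `Q2 > 0.99`.
#'
#' @param model a [fit_pce()] model (Q2 is computed during fitting).
#' @return The Q2 value.
#' @export
q2_loo <- function(model) {
  stopifnot(inherits(model, "pce_model"))
  model$q2
}

#' Main and total Sobol indices from the PCE coefficients
#'
#' With an orthonormal basis the output variance is the sum of squared
#' non-constant coefficients. The main index `S_i` sums the squared
#' coefficients whose multi-index involves only variable `i`; the total
#' index `S_T` sums all terms involving `i` (alone or in interaction).
#' `S_i` is the expected fractional reduction in output variance if input
#' `i` were known exactly; `S_T` is the fraction that would remain if all
#' other inputs were known exactly.
#'
#' @param model a [fit_pce()] model.
#' @param names optional character vector of input names.
#' @return data.frame of class `sensitivity_result` with columns `variable`,
#'   `S_i`, `S_T`; attribute `q2` carries the meta-model's Q2.
#' @export
sobol_indices <- function(model, names = NULL) {
  stopifnot(inherits(model, "pce_model"))
  idx <- model$index_set
  coef2 <- model$coef^2
  total_var <- sum(coef2[-1])
  if (total_var == 0) stop("zero meta-model variance: indices undefined")
  d <- ncol(idx)
  S_i <- S_T <- numeric(d)
  for (i in seq_len(d)) {
    involves_i <- idx[, i] > 0
    only_i <- involves_i & rowSums(idx[, -i, drop = FALSE]) == 0
    S_i[i] <- sum(coef2[only_i]) / total_var
    S_T[i] <- sum(coef2[involves_i]) / total_var
  }
  if (is.null(names)) names <- paste0("x", seq_len(d))
  out <- data.frame(variable = names, S_i = S_i, S_T = S_T)
  attr(out, "q2") <- model$q2
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' Adaptive-degree PCE: lowest degree whose Q2 exceeds a gate
#'
#' Walks a total-degree ladder and returns the first model whose
#' leave-one-out Q2 exceeds `gate` (default 0.99). If no admissible degree
#' reaches the gate (or higher degrees would exceed the sample budget), the
#' best-Q2 model is returned flagged non-compliant (`gate_met = FALSE`).
#'
#' @inheritParams fit_pce
#' @param gate Q2 acceptance threshold.
#' @param degrees candidate total degrees, tried in increasing order.
#' @return A `pce_model` with additional fields `gate`, `gate_met`.
#' @export
adaptive_degree <- function(inputs, outputs, domains = NULL, gate = 0.99,
                            degrees = 2:8) {
  best <- NULL
  for (p in sort(degrees)) {
    m <- tryCatch(fit_pce(inputs, outputs, p, domains), error = function(e) NULL)
    if (is.null(m) || is.na(m$q2)) next  # more terms than samples, or constant output
    if (is.null(best) || m$q2 > best$q2) best <- m
    if (m$q2 > gate) {
      m$gate <- gate
      m$gate_met <- TRUE
      return(m)
    }
  }
  if (is.null(best)) stop("no admissible degree could be fitted")
  best$gate <- gate
  best$gate_met <- FALSE
  best
}

#' Monte-Carlo (pick-freeze) check of the coefficient-based Sobol indices
#'
#' Estimates main and total indices of the meta-model itself with the
#' Saltelli pick-freeze scheme on uniform input samples, as an independent
#' cross-check of the coefficient-based decomposition. Agreement within a
#' few Monte-Carlo standard errors validates the index computation.
#'
#' @param model a [fit_pce()] model.
#' @param n_mc Monte-Carlo sample size per matrix.
#' @param seed RNG seed for the input matrices.
#' @return data.frame with `variable`, `S_i`, `S_T`, `se_S_i`, `se_S_T`.
#' @export
saltelli_check <- function(model, n_mc = 10000L, seed = 1L) {
  stopifnot(inherits(model, "pce_model"))
  d <- ncol(model$index_set)
  lo <- model$domains[1, ]
  hi <- model$domains[2, ]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  A <- sapply(seq_len(d), function(j) stats::runif(n_mc, lo[j], hi[j]))
  B <- sapply(seq_len(d), function(j) stats::runif(n_mc, lo[j], hi[j]))
  fA <- predict(model, A)
  fB <- predict(model, B)
  V <- stats::var(c(fA, fB))
  S_i <- S_T <- se_i <- se_t <- numeric(d)
  for (j in seq_len(d)) {
    ABj <- A
    ABj[, j] <- B[, j]
    fABj <- predict(model, ABj)
    ei <- fB * (fABj - fA)           # Saltelli 2010 main-effect elements
    et <- (fA - fABj)^2 / 2          # Jansen total-effect elements
    S_i[j] <- mean(ei) / V
    S_T[j] <- mean(et) / V
    se_i[j] <- stats::sd(ei) / sqrt(n_mc) / V
    se_t[j] <- stats::sd(et) / sqrt(n_mc) / V
  }
  data.frame(variable = paste0("x", seq_len(d)), S_i = S_i, S_T = S_T,
             se_S_i = se_i, se_S_T = se_t)
}
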