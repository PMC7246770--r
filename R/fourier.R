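#' Period-24 Fourier basis system
#'
#' A harmonic basis on the circle of circumference `period`: the constant
#' function followed by sine/cosine pairs at successive harmonics of
#' \eqn{\omega = 2\pi/\mathrm{period}}.  An odd number of basis functions is
#' required so the system is always "constant + complete pairs"; even requests
#' are rejected rather than silently truncated.
#'
#' @param nbasis odd number of basis functions (constant plus sine/cosine
#'   pairs).
#' @param period period of the basis in the units of the evaluation points
#'   (hours; default 24 for hourly diurnal profiles).
#' @param allow_even permit an even count, truncating the final pair after
#'   its sine term.  Off by default: an even request is normally a user
#'   error and is rejected rather than silently truncated.
#' @return An object of class `fourier_basis` with fields `nbasis`, `period`
#'   and `omega`.
#' @examples
#' fb <- fourier_basis(5)
#' eval_basis(fb, 0:23)
#' @export
fourier_basis <- function(nbasis, period = 24, allow_even = FALSE) {
  if (length(nbasis) != 1L || !is.finite(nbasis) || nbasis < 1 ||
      nbasis != as.integer(nbasis)) {
    stop("'nbasis' must be a positive integer")
  }
  if (nbasis %% 2L == 0L && !allow_even) {
    stop("'nbasis' must be odd (constant plus complete sine/cosine pairs)")
  }
  if (!is.finite(period) || period <= 0) stop("'period' must be positive")
  structure(
    list(nbasis = as.integer(nbasis), period = period, omega = 2 * pi / period),
    class = "fourier_basis"
  )
}

#' @export
print.fourier_basis <- function(x, ...) {
  cat(sprintf("Fourier basis: %d functions, period %g\n", x$nbasis, x$period))
  invisible(x)
}

#' Evaluate a Fourier basis at given hour points
#'
#' Returns the design matrix whose row at hour `h` is
#' \eqn{\phi(h)' = (1, \sin(\omega h), \cos(\omega h), \sin(2\omega h), \dots)}.
#'
#' @param basis a [fourier_basis()].
#' @param hours numeric vector of evaluation points (hours).
#' @return numeric matrix, `length(hours)` by `nbasis`.
#' @export
eval_basis <- function(basis, hours) {
  stopifnot(inherits(basis, "fourier_basis"))
  hours <- as.numeric(hours)
  K <- basis$nbasis
  out <- matrix(0, length(hours), K)
  out[, 1L] <- 1
  if (K > 1L) {
    for (j in seq_len((K - 1L) %/% 2L)) {
      out[, 2L * j]      <- sin(j * basis$omega * hours)
      out[, 2L * j + 1L] <- cos(j * basis$omega * hours)
    }
    if (K %% 2L == 0L) {             # truncated final pair: sine only
      out[, K] <- sin((K %/% 2L) * basis$omega * hours)
    }
  }
  dimnames(out) <- list(NULL, fourier_names(K))
  out
}

fourier_names <- function(K) {
  if (K == 1L) return("const")
  pairs <- as.vector(t(outer(seq_len((K - 1L) %/% 2L), c("sin", "cos"),
                             function(j, f) paste0(f, j))))
  c("const", pairs, if (K %% 2L == 0L) paste0("sin", K %/% 2L))
}

#' Least-squares fit of a Fourier expansion to a sampled curve
#'
#' Ordinary least squares of `values` on the basis evaluated at `hours`,
#' as used for single-series preliminary smoothing of a daily profile.
#'
#' @param values observed values.
#' @param hours sampling points (same length as `values`).
#' @param basis a [fourier_basis()].
#' @return list with `coefs` (length-`nbasis` coefficient vector) and `mse`
#'   (mean squared residual).
#' @export
fit_basis_ls <- function(values, hours, basis) {
  stopifnot(length(values) == length(hours))
  keep <- is.finite(values) & is.finite(hours)
  values <- values[keep]; hours <- hours[keep]
  if (length(values) < basis$nbasis) {
    stop("need at least 'nbasis' observations to fit the expansion")
  }
  Phi <- eval_basis(basis, hours)
  qr_Phi <- qr(Phi)
  if (qr_Phi$rank < basis$nbasis) {
    stop("rank-deficient basis design: hour points do not identify all coefficients")
  }
  coefs <- qr.coef(qr_Phi, values)
  resid <- values - drop(Phi %*% coefs)
  list(coefs = setNames(as.numeric(coefs), colnames(Phi)),
       mse = mean(resid^2))
}

#' Reconstruct a curve from Fourier coefficients
#'
#' Evaluates \eqn{\phi(h)'c} at each requested hour; the curve is periodic so
#' the value at `h = 0` equals the value at `h = period`.
#'
#' @param coefs coefficient vector of length `nbasis`.
#' @param basis a [fourier_basis()].
#' @param hours evaluation points.
#' @return numeric vector of curve values.
#' @export
reconstruct <- function(coefs, basis, hours) {
  stopifnot(length(coefs) == basis$nbasis)
  drop(eval_basis(basis, hours) %*% as.numeric(coefs))
}

#' Hour-of-day measurement-error variance curve
#'
#' The measurement error is heteroskedastic across the day with
#' \eqn{\log \sigma^2_\varepsilon(h) = \phi(h)' c_\varepsilon}; this evaluates
#' the implied (strictly positive) variance curve.
#'
#' @param c_eps coefficient vector for the log-variance expansion.
#' @param basis a [fourier_basis()] with `nbasis == length(c_eps)`.
#' @param hours evaluation points.
#' @return numeric vector of variances, `> 0` everywhere.
#' @export
sigma_eps_curve <- function(c_eps, basis, hours) {
  exp(reconstruct(c_eps, basis, hours))
}
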