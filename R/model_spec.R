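#' Model specification
#'
#' Names the covariates entering the observation equation and the three basis
#' sizes: `p_beta` for the functional covariate effects, `p_eps` for the
#' log-variance curve of the measurement error, and `p_z` for the latent
#' spatio-temporal component.  All basis sizes must be odd (or zero for
#' `p_z`, which drops the latent field entirely; `p_beta = 1` / `p_eps = 1`
#' give constant-in-hour effects/variance).  An intercept curve is included
#' by default.
#'
#' @param covariates character vector of covariate names (may be empty).
#' @param p_z latent-process basis size (0 drops the latent field; even
#'   sizes truncate the final harmonic pair after its sine term).
#' @param p_beta covariate-effect basis size (odd).
#' @param p_eps error-log-variance basis size (odd).
#' @param intercept include an intercept effect curve?
#' @return object of class `stfm_spec`.
#' @export
stfm_spec <- function(covariates = character(), p_z = 7, p_beta = 5,
                      p_eps = 5, intercept = TRUE) {
  chk_odd <- function(x, nm) {
    if (x < 1 || x %% 2 == 0) stop("'", nm, "' must be odd")
  }
  if (p_z < 0) stop("'p_z' must be non-negative")
  chk_odd(p_beta, "p_beta")
  chk_odd(p_eps, "p_eps")
  structure(
    list(covariates = as.character(covariates), p_z = as.integer(p_z),
         p_beta = as.integer(p_beta), p_eps = as.integer(p_eps),
         intercept = isTRUE(intercept)),
    class = "stfm_spec"
  )
}

#' @export
print.stfm_spec <- function(x, ...) {
  cat(sprintf(
    "stfm_spec: %d effect curve(s) [%s], p_beta=%d, p_eps=%d, p_z=%d\n",
    n_effects(x), paste(effect_names(x), collapse = ", "),
    x$p_beta, x$p_eps, x$p_z))
  invisible(x)
}

effect_names <- function(spec) {
  c(if (spec$intercept) "(Intercept)", spec$covariates)
}

n_effects <- function(spec) length(spec$covariates) + spec$intercept

#' Number of free parameters of a model specification
#'
#' Counts `p_eps + b * p_beta + 3 * p_z` where `b` is the number of effect
#' curves (intercept included): the log-variance coefficients, the functional
#' effect coefficients, and one (g, v, theta) triple per latent component.
#' Some published counts omit the error-variance coefficients; set
#' `include_c_eps = FALSE` to match that convention.
#'
#' @param spec an [stfm_spec()].
#' @param include_c_eps count the error-log-variance coefficients?
#' @return integer parameter count.
#' @export
npar <- function(spec, include_c_eps = TRUE) {
  (if (include_c_eps) spec$p_eps else 0L) +
    n_effects(spec) * spec$p_beta + 3L * spec$p_z
}

#' Model parameter set
#'
#' Bundles the full parameter vector: `c_eps` (error log-variance expansion,
#' length `p_eps`), `c_beta` (`p_beta x b` matrix of effect-curve
#' coefficients, one column per effect), and per-latent-component transition
#' diagonals `g` (`|g| < 1` for stationarity), innovation scales `v > 0` and
#' spatial ranges `theta > 0` (km).
#'
#' @param c_eps numeric vector.
#' @param c_beta numeric matrix `p_beta x b` (or vector if `b = 1`).
#' @param g,v,theta numeric vectors of common length `p_z`.
#' @return object of class `parameter_set`.
#' @export
parameter_set <- function(c_eps, c_beta, g = numeric(), v = numeric(),
                          theta = numeric()) {
  if (!is.matrix(c_beta)) c_beta <- matrix(c_beta, ncol = 1L)
  stopifnot(length(g) == length(v), length(g) == length(theta))
  if (length(v) && any(v <= 0)) stop("'v' must be positive")
  if (length(theta) && any(theta <= 0)) stop("'theta' must be positive")
  structure(
    list(c_eps = as.numeric(c_eps), c_beta = c_beta,
         g = as.numeric(g), v = as.numeric(v), theta = as.numeric(theta)),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("parameter_set: p_eps=%d, %d effect curve(s) x p_beta=%d, p_z=%d\n",
              length(x$c_eps), ncol(x$c_beta), nrow(x$c_beta), length(x$g)))
  if (length(x$g)) {
    print(round(data.frame(g = x$g, theta_km = x$theta, v = x$v), 4))
  }
  invisible(x)
}

# --- flat vector mapping (estimation/Hessian coordinates) ------------------
# Unconstrained scale: c_eps, c_beta raw; atanh(g); log(v); log(theta).

#' Flatten a parameter set to a vector
#'
#' Concatenates `c_eps`, `c_beta` (column-major), `g`, `v`, `theta`.  With
#' `transformed = TRUE` the constrained parameters are mapped to the
#' unconstrained scale used for differentiation and standard errors:
#' `atanh(g)`, `log(v)`, `log(theta)`.
#'
#' @param psi a [parameter_set()].
#' @param transformed use the unconstrained scale?
#' @return numeric vector; element names from [psi_names()].
#' @export
psi_to_vector <- function(psi, transformed = TRUE) {
  g <- if (transformed) atanh(psi$g) else psi$g
  v <- if (transformed) log(psi$v) else psi$v
  th <- if (transformed) log(psi$theta) else psi$theta
  c(psi$c_eps, as.numeric(psi$c_beta), g, v, th)
}

#' Rebuild a parameter set from a flat vector
#'
#' Inverse of [psi_to_vector()]; `template` supplies the block sizes and
#' effect names.
#'
#' @param x numeric vector as produced by [psi_to_vector()].
#' @param template a [parameter_set()] of the target shape.
#' @param transformed is `x` on the unconstrained scale?
#' @return a [parameter_set()].
#' @export
vector_to_psi <- function(x, template, transformed = TRUE) {
  p_eps <- length(template$c_eps)
  nb <- length(template$c_beta)
  p <- length(template$g)
  c_eps <- x[seq_len(p_eps)]
  c_beta <- matrix(x[p_eps + seq_len(nb)], nrow(template$c_beta),
                   ncol(template$c_beta), dimnames = dimnames(template$c_beta))
  g <- x[p_eps + nb + seq_len(p)]
  v <- x[p_eps + nb + p + seq_len(p)]
  th <- x[p_eps + nb + 2L * p + seq_len(p)]
  if (transformed) { g <- tanh(g); v <- exp(v); th <- exp(th) }
  parameter_set(c_eps, c_beta, g, v, th)
}

#' Names for the flattened parameter vector
#'
#' @param psi a [parameter_set()].
#' @return character vector matching [psi_to_vector()] element order.
#' @export
psi_names <- function(psi) {
  bnames <- colnames(psi$c_beta) %||% paste0("beta", seq_len(ncol(psi$c_beta)))
  p <- length(psi$g)
  c(paste0("c_eps", seq_along(psi$c_eps)),
    as.vector(outer(seq_len(nrow(psi$c_beta)), bnames,
                    function(k, b) paste0("c_beta.", b, ".", k))),
    if (p) paste0("g", 1:p), if (p) paste0("v", 1:p), if (p) paste0("theta", 1:p))
}
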