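#' Wald chi-square test for a functional effect
#'
#' Tests joint nullity of an effect curve's basis coefficients:
#' under the null `c' Sigma^+ c` is chi-square with degrees of freedom equal
#' to the numerical rank of `Sigma` (singular values above `1e-10` of the
#' largest).  A pseudo-inverse is used so rank-deficient coefficient
#' covariances are handled by restriction to their column space.
#'
#' @param c_j coefficient vector of the effect curve.
#' @param Sigma_j symmetric positive semidefinite covariance of `c_j`.
#' @param name optional effect label carried in the result.
#' @return object of class `wald_test`: `statistic`, `df`, `p_value`, `name`.
#' @export
wald_test <- function(c_j, Sigma_j, name = NULL) {
  c_j <- as.numeric(c_j)
  Sigma_j <- as.matrix(Sigma_j)
  stopifnot(length(c_j) == nrow(Sigma_j), nrow(Sigma_j) == ncol(Sigma_j))
  eg <- eigen(0.5 * (Sigma_j + t(Sigma_j)), symmetric = TRUE)
  tol <- 1e-10 * max(abs(eg$values), 0)
  keep <- eg$values > tol
  df <- sum(keep)
  if (df == 0L) {
    if (any(c_j != 0)) stop("zero-rank covariance with nonzero coefficients")
    stat <- 0
  } else {
    proj <- drop(crossprod(eg$vectors[, keep, drop = FALSE], c_j))
    stat <- sum(proj^2 / eg$values[keep])
  }
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(name = name, statistic = stat, df = df, p_value = p),
            class = "wald_test")
}

#' @export
print.wald_test <- function(x, ...) {
  cat(sprintf("Wald chi-square%s: statistic %.4f, df %d, p = %.4g\n",
              if (!is.null(x$name)) paste0(" [", x$name, "]") else "",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Wald tests for every effect curve of a fit
#'
#' @param fit an [fit_em()] result with `compute_se = TRUE`.
#' @return data.frame with one row per effect: statistic, df, p-value.
#' @export
wald_tests <- function(fit) {
  enames <- colnames(fit$psi_hat$c_beta)
  rows <- lapply(enames, function(e) {
    blk <- effect_block(fit, e)
    wt <- wald_test(blk$coefs, blk$Sigma, name = e)
    data.frame(effect = e, statistic = wt$statistic, df = wt$df,
               p_value = wt$p_value)
  })
  do.call(rbind, rows)
}

#' Pointwise confidence bands for an effect curve
#'
#' Delta-method bands for \eqn{\beta(h) = \phi(h)'c}:
#' \eqn{\phi(h)'c \pm z_{1-\alpha/2} \sqrt{\phi(h)' \Sigma \phi(h)}}.
#' The basis is periodic so the band at `h = 0` equals the band at
#' `h = period`.
#'
#' @param c_j coefficient vector.
#' @param Sigma_j coefficient covariance.
#' @param basis the [fourier_basis()] of the curve.
#' @param hours evaluation grid (default fine grid over one period).
#' @param levels confidence levels in (0, 1).
#' @return data.frame with `hour`, `estimate`, and `lower_XX`/`upper_XX`
#'   columns per level.
#' @export
confidence_bands <- function(c_j, Sigma_j, basis,
                             hours = seq(0, basis$period, by = 0.25),
                             levels = c(0.90, 0.95, 0.99)) {
  stopifnot(all(levels > 0 & levels < 1))
  Phi <- eval_basis(basis, hours)
  est <- drop(Phi %*% as.numeric(c_j))
  sdv <- sqrt(pmax(rowSums((Phi %*% as.matrix(Sigma_j)) * Phi), 0))
  out <- data.frame(hour = hours, estimate = est)
  for (lv in levels) {
    z <- stats::qnorm(1 - (1 - lv) / 2)
    tag <- sprintf("%02d", round(100 * lv))
    out[[paste0("lower_", tag)]] <- est - z * sdv
    out[[paste0("upper_", tag)]] <- est + z * sdv
  }
  out
}
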