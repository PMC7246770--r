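#' Information criterion (larger is better)
#'
#' The model-comparison criterion used throughout: the observed-data
#' log-likelihood penalized by twice the parameter count,
#' `logL - 2 * npar`, with the best model attaining the maximum.
#'
#' @param loglik observed-data log-likelihood.
#' @param npar number of free parameters.
#' @return numeric criterion value.
#' @export
model_aic <- function(loglik, npar) {
  loglik - 2 * npar
}

#' Greedy forward selection of covariates
#'
#' Starting from the intercept-only specification, each iteration refits the
#' model once per remaining candidate and keeps the candidate giving the
#' largest information criterion.  By default the full path is returned; a
#' relative-improvement threshold stops early when the criterion gain drops
#' below it.
#'
#' @param cube a [panel_cube()].
#' @param candidates character vector of candidate covariates.
#' @param spec template [stfm_spec()] supplying basis sizes (its covariate
#'   list is ignored).
#' @param config an [em_config()] used for every fit.
#' @param threshold optional relative-improvement stop (e.g. `0.001`);
#'   `NULL` emits the full path.
#' @param max_steps cap on the number of covariates added.
#' @return object of class `forward_path`: a data.frame `path` (iteration,
#'   covariate added, criterion) plus `baseline_ic`.
#' @export
forward_select <- function(cube, candidates, spec, config = em_config(),
                           threshold = NULL, max_steps = length(candidates)) {
  fit_with <- function(covs) {
    sp <- stfm_spec(covariates = covs, p_z = spec$p_z, p_beta = spec$p_beta,
                    p_eps = spec$p_eps, intercept = spec$intercept)
    fit_em(cube, sp, config)
  }
  base <- fit_with(character())
  current <- character()
  ic_curr <- base$ic
  rows <- list()
  remaining <- candidates
  for (step in seq_len(min(max_steps, length(candidates)))) {
    ics <- rep(NA_real_, length(remaining))
    for (k in seq_along(remaining)) {
      ics[k] <- tryCatch(fit_with(c(current, remaining[k]))$ic,
                         error = function(e) {
                           warning("fit failed for candidate ", remaining[k],
                                   ": ", conditionMessage(e))
                           NA_real_
                         })
    }
    if (all(is.na(ics))) break
    best <- which.max(ics)
    if (!is.null(threshold)) {
      gain <- (ics[best] - ic_curr) / max(abs(ic_curr), 1e-12)
      if (is.finite(gain) && gain < threshold) break
    }
    current <- c(current, remaining[best])
    rows[[step]] <- data.frame(iteration = step - 1L,
                               covariate = remaining[best],
                               ic = ics[best])
    ic_curr <- ics[best]
    remaining <- remaining[-best]
    if (!length(remaining)) break
  }
  structure(list(path = if (length(rows)) do.call(rbind, rows) else
                   data.frame(iteration = integer(), covariate = character(),
                              ic = numeric()),
                 baseline_ic = base$ic),
            class = "forward_path")
}

#' @export
print.forward_path <- function(x, ...) {
  cat(sprintf("forward selection: baseline IC %.3f\n", x$baseline_ic))
  print(x$path)
  invisible(x)
}

#' Grid search over basis sizes
#'
#' Evaluates every `(p_z, p_beta, p_eps)` combination by
#' leave-one-station-out cross-validation (average MSE and R-squared) and a
#' full-data fit (information criterion).
#'
#' @param cube a [panel_cube()].
#' @param grid data.frame with columns `p_z`, `p_beta`, `p_eps` (odd sizes;
#'   `p_z` may be 0).
#' @param covariates covariates to include in every candidate model.
#' @param config an [em_config()] used for every fit.
#' @return data.frame: one row per combination with `mse_bar`, `r2_bar`,
#'   `ic`, plus attributes `best_mse`, `best_r2`, `best_ic` (row indices).
#' @export
basis_grid_search <- function(cube, grid, covariates = character(),
                              config = em_config()) {
  stopifnot(all(c("p_z", "p_beta", "p_eps") %in% names(grid)))
  out <- grid
  out$mse_bar <- out$r2_bar <- out$ic <- NA_real_
  for (r in seq_len(nrow(grid))) {
    sp <- stfm_spec(covariates = covariates, p_z = grid$p_z[r],
                    p_beta = grid$p_beta[r], p_eps = grid$p_eps[r])
    cv <- loso_cv(cube, sp, config)
    fit <- fit_em(cube, sp, config)
    out$mse_bar[r] <- cv$mse_bar
    out$r2_bar[r] <- cv$r2_bar
    out$ic[r] <- fit$ic
  }
  attr(out, "best_mse") <- which.min(out$mse_bar)
  attr(out, "best_r2") <- which.max(out$r2_bar)
  attr(out, "best_ic") <- which.max(out$ic)
  out
}
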