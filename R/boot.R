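#' Residual-bootstrap confidence intervals for an epimutation fit
#'
#' Bootstraps the model residuals: for each replicate a new response
#' `B_q = fitted_q + e*` is formed, with `e*` drawn with replacement from
#' the vector of fitted residuals, and the model is refitted.  Percentile
#' intervals are taken from the resulting bootstrap distribution of each
#' free parameter.  Refits are warm-started at the original point estimate
#' (plus `n_starts - 1` random restarts), which keeps replicate fits on the
#' same objective basin; results are reproducible under a fixed seed.
#'
#' @param fit an `"epifit"`.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95, i.e. 2.5/97.5 percentiles).
#' @param n_starts restarts per refit (default 2: warm start + 1 random).
#' @param max_iter Nelder-Mead iteration cap per refit.
#' @return An object of class `"epiboot"`: list with `estimates` (a
#'   `B x k` matrix of replicate parameter estimates), `ci` (per-parameter
#'   lower/upper bounds), `level`, `B`, `seed` and the original fit.
#' @export
epiboot <- function(fit, B = 1000, seed = 1L, level = 0.95,
                    n_starts = 2, max_iter = 500) {
  stopifnot(inherits(fit, "epifit"), B >= 1, level > 0, level < 1)
  free <- fit$free
  est <- matrix(NA_real_, B, length(free),
                dimnames = list(NULL, free))
  data <- fit$data
  set.seed(seed)
  rseeds <- sample.int(.Machine$integer.max - 1, B)
  for (b in seq_len(B)) {
    eps <- sample(fit$residuals, fit$M, replace = TRUE)
    newD <- pmin(pmax(fit$fitted + eps, 0), 1)
    bdata <- data
    bdata$pairs$D <- newD
    bfit <- epifit(bdata, form = fit$form, system = fit$system,
                   n_starts = n_starts - 1, seed = rseeds[b],
                   max_iter = max_iter, start = fit$par)
    est[b, ] <- bfit$par[free]
  }
  a <- (1 - level) / 2
  ci <- t(apply(est, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(ci) <- paste0(format(100 * c(a, 1 - a), trim = TRUE), " %")
  out <- list(estimates = est, ci = ci, level = level, B = B, seed = seed,
              fit = fit)
  class(out) <- "epiboot"
  out
}

#' @export
print.epiboot <- function(x, digits = 4, ...) {
  cat("Residual bootstrap: ", x$B, " replicates, ",
      format(100 * x$level), "% percentile intervals\n", sep = "")
  tab <- cbind(estimate = x$fit$par[x$fit$free], x$ci)
  print(signif(tab, digits))
  invisible(x)
}

#' @export
confint.epiboot <- function(object, parm, level = NULL, ...) {
  if (!is.null(level) && level != object$level)
    stop("bootstrap was run at level ", object$level,
         "; rerun epiboot() for a different level")
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Confidence intervals for an epimutation fit
#'
#' Runs (or reuses) a residual bootstrap and returns percentile intervals;
#' see [epiboot()] for the procedure.
#'
#' @param object an `"epifit"`.
#' @param parm parameters to report (default: all free parameters).
#' @param level confidence level.
#' @param B,seed bootstrap replicates and seed, passed to [epiboot()].
#' @param ... further arguments to [epiboot()].
#' @return Matrix of lower/upper bounds.
#' @export
confint.epifit <- function(object, parm, level = 0.95, B = 1000,
                           seed = 1L, ...) {
  bt <- epiboot(object, B = B, seed = seed, level = level, ...)
  confint(bt, parm)
}
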