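#' Nested F-test between two epimutation model fits
#'
#' Tests whether the full model (e.g. a selection form, `ABmm`/`ABuu`)
#' fits significantly better than a nested reduced model (e.g. the neutral
#' form, or `ABnull` against `ABneutral`).  With residual sums of squares
#' \eqn{RSS_R, RSS_F} and residual degrees of freedom
#' \eqn{df_R = M - k_R}, \eqn{df_F = M - k_F},
#' \deqn{F = \frac{(RSS_R - RSS_F)/(df_R - df_F)}{RSS_F / df_F},}
#' referred to the \eqn{F(df_R - df_F,\; df_F)} distribution.
#'
#' @param full,reduced `"epifit"` objects on the same data (same number of
#'   pairs, same system), with the reduced model's free parameters a subset
#'   of the full model's.
#' @return A list of class `"epi_ftest"` with `F`, `df_num`, `df_den`,
#'   `p_value`, and the two RSS values.  If the full model's RSS exceeds
#'   the reduced model's beyond numerical tolerance the optimizer has
#'   failed on one of the fits; a warning advises refitting (e.g. more
#'   restarts) and `F` is truncated at 0.
#' @seealso [anova.epifit()] for the conventional `anova()` interface.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "epifit"), inherits(reduced, "epifit"))
  if (full$M != reduced$M)
    stop("fits are not on the same data (different number of pairs)")
  if (full$system != reduced$system)
    stop("fits use different propagation systems")
  if (!all(reduced$free %in% full$free) ||
      length(reduced$free) >= length(full$free))
    stop("models are not nested (reduced free parameters must be a strict ",
         "subset of the full model's)")
  df_num <- reduced$df - full$df
  df_den <- full$df
  dss <- reduced$rss - full$rss
  if (dss < -1e-4 * max(full$rss, 1e-300))
    warning("full-model RSS exceeds reduced-model RSS: optimizer failure ",
            "likely; refit with more restarts")
  Fstat <- max(0, dss / df_num) / (full$rss / df_den)
  out <- list(F = Fstat, df_num = df_num, df_den = df_den,
              p_value = stats::pf(Fstat, df_num, df_den, lower.tail = FALSE),
              rss_full = full$rss, rss_reduced = reduced$rss,
              full = full$form, reduced = reduced$form)
  class(out) <- "epi_ftest"
  out
}

#' @export
print.epi_ftest <- function(x, ...) {
  cat("Nested F-test: ", x$reduced, " (reduced) vs ", x$full, " (full)\n",
      sep = "")
  cat(sprintf("  RSS_R = %.6g, RSS_F = %.6g\n", x$rss_reduced, x$rss_full))
  cat(sprintf("  F(%d, %d) = %.4g,  p = %.4g\n",
              x$df_num, x$df_den, x$F, x$p_value))
  invisible(x)
}

#' Fit a nested model pair with symmetric optimization effort
#'
#' A fair nested F-test requires both models to be minimized equally well:
#' if only the full model is optimized thoroughly, part of the apparent
#' RSS improvement is reduced-model optimizer slack and the test rejects
#' too often.  This helper fits the reduced model from random restarts,
#' warm-starts the full model at the reduced optimum (plus its own
#' restarts), then refits the reduced model warm-started at the full
#' model's shared parameters and keeps the better of the two reduced
#' fits.
#'
#' @param data a `"divergence_data"`.
#' @param reduced_form,full_form nested model forms (e.g. `"ABneutral"`
#'   and `"ABuu"`).
#' @param system `"selfing"` or `"clonal"`.
#' @param n_starts random restarts used for each model.
#' @param seed integer seed.
#' @param w_start near-boundary starting value of the selection
#'   coefficient for the full model's warm start.
#' @param ... further arguments passed to [epifit()].
#' @return List with `reduced`, `full` (both `"epifit"`) and `test`
#'   (the [compare_models()] result).
#' @export
fit_nested <- function(data, reduced_form = "ABneutral",
                       full_form = c("ABuu", "ABmm"),
                       system = c("selfing", "clonal"),
                       n_starts = 12, seed = 1L, w_start = 0.95, ...) {
  full_form <- match.arg(full_form)
  system <- match.arg(system)
  red <- epifit(data, reduced_form, system, n_starts = n_starts,
                seed = seed, ...)
  shared <- intersect(red$free, .free_params(full_form))
  ful <- epifit(data, full_form, system, n_starts = n_starts, seed = seed,
                start = c(red$par[shared], w = w_start), ...)
  red2 <- epifit(data, reduced_form, system, n_starts = 0, seed = seed,
                 start = ful$par[red$free], ...)
  if (red2$rss < red$rss) red <- red2
  if (red$rss < ful$rss) {
    # reduced fit overtook the full fit: polish the full model from the
    # reduced optimum with w just inside the boundary
    ful2 <- epifit(data, full_form, system, n_starts = 0, seed = seed,
                   start = c(red$par[shared], w = 0.999), ...)
    if (ful2$rss < ful$rss) ful <- ful2
  }
  list(reduced = red, full = ful, test = compare_models(ful, red))
}

#' Analysis-of-variance comparison of nested epimutation fits
#'
#' Conventional `anova()` interface to [compare_models()]: call with the
#' reduced fit first, e.g. `anova(fit_neutral, fit_selection)`.
#'
#' @param object the reduced `"epifit"`.
#' @param ... exactly one further `"epifit"`, the full model.
#' @return A classed `"anova"` data.frame with the F-statistic and p-value.
#' @export
anova.epifit <- function(object, ...) {
  dots <- list(...)
  fits <- c(list(object), dots[vapply(dots, inherits, logical(1), "epifit")])
  if (length(fits) != 2)
    stop("anova.epifit compares exactly two nested fits")
  fits <- fits[order(vapply(fits, function(f) length(f$free), integer(1)))]
  reduced <- fits[[1]]
  full <- fits[[2]]
  ft <- compare_models(full, reduced)
  tab <- data.frame(
    Res.Df = c(reduced$df, full$df),
    RSS = c(reduced$rss, full$rss),
    Df = c(NA, ft$df_num),
    `Sum of Sq` = c(NA, ft$rss_reduced - ft$rss_full),
    F = c(NA, ft$F),
    `Pr(>F)` = c(NA, ft$p_value),
    check.names = FALSE)
  rownames(tab) <- c(reduced$form, full$form)
  structure(tab, heading = c("Nested epimutation model comparison\n"),
            class = c("anova", "data.frame"))
}
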