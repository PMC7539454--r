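.sys_code <- function(system) {
  match(match.arg(system, c("selfing", "clonal")), c("selfing", "clonal"))
}
.form_code <- function(form) {
  match(match.arg(form, c("ABneutral", "ABmm", "ABuu", "ABnull")),
        c("ABneutral", "ABmm", "ABuu", "ABnull"))
}
.free_params <- function(form) {
  switch(form,
         ABneutral = c("alpha", "beta", "gamma", "c"),
         ABmm = c("alpha", "beta", "w", "gamma", "c"),
         ABuu = c("alpha", "beta", "w", "gamma", "c"),
         ABnull = "c")
}
.times_matrix <- function(data) {
  as.matrix(data$pairs[, c("t_ij", "t_i", "t_j")])
}

#' Constrained least-squares objective of an epimutation model
#'
#' The quantity minimized by [epifit()]: the residual sum of squares of the
#' observed divergences around `c + D*` plus a soft equilibrium constraint,
#' `M (p_bar_1 - p1_inf)^2`, where `p1_inf` is the model's equilibrium u/u
#' proportion (see [equilibrium_uu()]).  The constraint anchors the highly
#' nonlinear surface and stabilizes convergence.  For the `ABnull` form
#' (no accumulation) the equilibrium is undefined and the constraint term
#' is omitted.
#'
#' @param data a `"divergence_data"` object.
#' @param form,system model form and propagation system.
#' @param alpha,beta,w,gamma,c parameter values on the natural scale.
#' @return The objective value (non-negative scalar).
#' @export
epi_objective <- function(data, form, system, alpha, beta, w = 1,
                          gamma = 0, c = 0) {
  stopifnot(inherits(data, "divergence_data"))
  form <- match.arg(form, c("ABneutral", "ABmm", "ABuu", "ABnull"))
  system <- match.arg(system, c("selfing", "clonal"))
  pi <- founder_distribution(data$p1_obs, data$p3_obs, gamma)
  pred <- vapply(seq_len(data$M), function(q)
    expected_divergence(system, form, alpha, beta, w,
                        t_i = data$pairs$t_i[q], t_j = data$pairs$t_j[q],
                        t_ij = data$pairs$t_ij[q], pi = pi),
    numeric(1))
  obj <- sum((data$pairs$D - pred - c)^2)
  if (form != "ABnull")
    obj <- obj + data$M *
      (data$p_bar_1 - equilibrium_uu(system, form, alpha, beta, w))^2
  obj
}

#' Fit an epimutation model to pairwise methylome divergence data
#'
#' Estimates the epimutation gain rate `alpha`, loss rate `beta`, founder
#' epiheterozygosity split `gamma`, residual offset `c` and (for the
#' selection forms) the selection coefficient `w` by minimizing the
#' constrained least-squares objective (see [epi_objective()]) with
#' Nelder-Mead iterations from multiple random restarts.
#'
#' The four model forms are: `ABneutral` (neutral accumulation, `w = 1`),
#' `ABmm` (selection against the unmethylated epiallele), `ABuu`
#' (selection against the methylated epiallele) and `ABnull` (no
#' accumulation, `alpha = beta = 0`, `w = 1`).  `ABnull` with
#' `gamma_null = 0` is an intercept-only model and is solved in closed form
#' (`c_hat = mean(D)`); with `gamma_null > 0` on a selfing system it
#' retains the founder-heterozygote segregation transient.
#'
#' The bounded parameters are logit-transformed to the real line and `c` is
#' fitted on the log scale, so every Nelder-Mead iterate respects the
#' boxes; estimates are reported on the natural scale.  Random restarts
#' draw `alpha` and `beta` log-uniformly over `[1e-9, 0.1]`, `gamma` and
#' `w` uniformly, and `c` near the minimum observed divergence.  The fit is
#' deterministic given (`data`, `form`, `system`, `seed`).
#'
#' @param data a `"divergence_data"` object (from [divergence_dataset()],
#'   [read_divergence()] or [divergence_data()]).
#' @param form `"ABneutral"`, `"ABmm"`, `"ABuu"` or `"ABnull"`.
#' @param system `"selfing"` or `"clonal"`.
#' @param n_starts number of random restarts (default 50).
#' @param seed integer seed for the restart stream.
#' @param max_iter Nelder-Mead iteration cap per start.
#' @param reltol relative convergence tolerance passed to [stats::optim()].
#' @param start optional named vector of natural-scale starting values
#'   (`alpha`, `beta`, `w`, `gamma`, `c`) prepended to the random restarts
#'   (used e.g. to warm-start bootstrap refits).
#' @param gamma_null fixed `gamma` for the `ABnull` form (default 0).
#' @return An object of class `"epifit"` with components `par` (full
#'   natural-scale parameter vector), `free` (names of the free
#'   parameters), `rss`, `df` (`M - k`), `r_squared`, `sigma2` (residual
#'   variance `rss/df`), `fitted`, `residuals`, `value` (minimized
#'   objective including the constraint term), `eq_uu`, `converged`,
#'   `best_start` and the data.  Supports `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict`, `plot`, `simulate`, `confint` and
#'   `anova`.
#' @examples
#' ## noise-free clonal data generated from the model itself
#' tm <- data.frame(sample_i = "a", sample_j = letters[2:7],
#'                  t_i = 1, t_j = seq(6, 31, 5), t_ij = 1)
#' tm$delta_t <- (tm$t_i - tm$t_ij) + (tm$t_j - tm$t_ij)
#' pi <- founder_distribution(0.7, 0.3, 0)
#' tm$D <- 0.005 + vapply(seq_len(nrow(tm)), function(q)
#'   expected_divergence("clonal", "ABneutral", 2e-3, 8e-3, 1,
#'                       tm$t_i[q], tm$t_j[q], tm$t_ij[q], pi), 1)
#' dat <- divergence_data(tm, p1_obs = 0.7, p3_obs = 0.3,
#'                        p_bar_1 = equilibrium_uu("clonal", "ABneutral",
#'                                                 2e-3, 8e-3))
#' fit <- epifit(dat, "ABneutral", "clonal", n_starts = 10, seed = 1)
#' coef(fit)
#' @export
epifit <- function(data, form = c("ABneutral", "ABmm", "ABuu", "ABnull"),
                   system = c("selfing", "clonal"),
                   n_starts = 50, seed = 1L, max_iter = 1000,
                   reltol = 1e-10, start = NULL, gamma_null = 0) {
  stopifnot(inherits(data, "divergence_data"))
  form <- match.arg(form)
  system <- match.arg(system)
  sys <- .sys_code(system)
  frm <- .form_code(form)
  free <- .free_params(form)
  k <- length(free)
  M <- data$M
  if (M <= k)
    stop("need more sample pairs (", M, ") than free parameters (", k, ")")
  D <- data$pairs$D
  tmx <- .times_matrix(data)
  key <- paste(tmx[, 1], tmx[, 2], tmx[, 3])
  ukey <- unique(key)
  utmx <- tmx[match(ukey, key), , drop = FALSE]
  idx <- match(key, ukey)
  cl <- match.call()

  if (form == "ABnull") {
    pred <- as.numeric(cpp_pred_d(sys, frm, 0, 0, 1, gamma_null,
                                  data$p1_obs, data$p3_obs, utmx))[idx]
    chat <- mean(D - pred)
    par <- c(alpha = 0, beta = 0, w = 1, gamma = gamma_null, c = chat)
    fitted <- pred + chat
    res <- D - fitted
    rss <- sum(res^2)
    out <- list(call = cl, form = form, system = system, par = par,
                free = free, rss = rss, df = M - k,
                r_squared = 1 - rss / sum((D - mean(D))^2),
                sigma2 = rss / (M - k), fitted = fitted, residuals = res,
                value = rss, eq_uu = NA_real_, converged = TRUE,
                best_start = 0L, n_starts = 0L, seed = seed, data = data,
                M = M)
    class(out) <- "epifit"
    return(out)
  }

  has_w <- "w" %in% free
  ig <- if (has_w) 4L else 3L
  ic <- if (has_w) 5L else 4L
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  to_nat <- function(tp) {
    c(alpha = stats::plogis(tp[[1]]), beta = stats::plogis(tp[[2]]),
      w = if (has_w) stats::plogis(tp[[3]]) else 1,
      gamma = stats::plogis(tp[[ig]]), c = exp(tp[[ic]]))
  }
  p1o <- data$p1_obs; p3o <- data$p3_obs; pb1 <- data$p_bar_1
  plogis <- stats::plogis
  fn <- function(tp) {
    v <- cpp_objective(sys, frm, plogis(tp[1L]), plogis(tp[2L]),
                       if (has_w) plogis(tp[3L]) else 1, plogis(tp[ig]),
                       exp(tp[ic]), p1o, p3o, utmx, idx, D, pb1, TRUE)
    if (is.finite(v)) v else 1e10
  }

  set.seed(seed)
  c0 <- max(min(D), 1e-6)
  starts <- cbind(stats::qlogis(10^stats::runif(n_starts, -9, -1)),
                  stats::qlogis(10^stats::runif(n_starts, -9, -1)))
  if (has_w) starts <- cbind(starts,
                             stats::qlogis(clamp(stats::runif(n_starts))))
  starts <- cbind(starts, stats::qlogis(clamp(stats::runif(n_starts))),
                  log(c0) + stats::runif(n_starts, -0.7, 0.7))
  if (!is.null(start)) {
    sv <- c(alpha = 1e-4, beta = 1e-4, w = 0.9, gamma = 0.5, c = c0)
    sv[names(start)] <- start
    sv[c("alpha", "beta", "w", "gamma")] <-
      clamp(sv[c("alpha", "beta", "w", "gamma")])
    row <- c(stats::qlogis(sv[["alpha"]]), stats::qlogis(sv[["beta"]]))
    if (has_w) row <- c(row, stats::qlogis(sv[["w"]]))
    row <- c(row, stats::qlogis(sv[["gamma"]]), log(max(sv[["c"]], 1e-10)))
    starts <- rbind(row, starts)
  }

  best <- NULL
  best_i <- NA_integer_
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], fn, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = reltol))
    if (is.null(best) || o$value < best$value) {
      best <- o
      best_i <- i
    }
  }

  nat <- to_nat(best$par)
  pred <- as.numeric(cpp_pred_d(sys, frm, nat[["alpha"]], nat[["beta"]],
                                nat[["w"]], nat[["gamma"]],
                                data$p1_obs, data$p3_obs, utmx))[idx]
  fitted <- pred + nat[["c"]]
  res <- D - fitted
  rss <- sum(res^2)
  out <- list(call = cl, form = form, system = system, par = nat,
              free = free, rss = rss, df = M - k,
              r_squared = 1 - rss / sum((D - mean(D))^2),
              sigma2 = rss / (M - k), fitted = fitted, residuals = res,
              value = best$value,
              eq_uu = cpp_equilibrium_uu(sys, frm, nat[["alpha"]],
                                         nat[["beta"]], nat[["w"]]),
              converged = best$convergence == 0, best_start = best_i,
              n_starts = nrow(starts), seed = seed, data = data, M = M)
  class(out) <- "epifit"
  out
}

#' @export
print.epifit <- function(x, digits = 4, ...) {
  cat("Epimutation model fit: ", x$form, " (", x$system, " system)\n",
      sep = "")
  cat("  ", x$M, " sample pairs;  df = ", x$df, "\n", sep = "")
  print(signif(x$par[x$free], digits))
  cat(sprintf("  RSS = %.4g;  R-squared = %.4f%s\n", x$rss, x$r_squared,
              if (!x$converged) "  [not converged]" else ""))
  invisible(x)
}

#' @export
coef.epifit <- function(object, all = FALSE, ...) {
  if (all) object$par else object$par[object$free]
}

#' @export
fitted.epifit <- function(object, ...) object$fitted

#' @export
residuals.epifit <- function(object, ...) object$residuals

#' Predict expected divergence from a fitted epimutation model
#'
#' @param object an `"epifit"`.
#' @param newdata optional data.frame with columns `t_i`, `t_j`, `t_ij`
#'   (internal time scale, founder at 1); defaults to the fitted pairs.
#' @param ... unused.
#' @return Numeric vector of predicted divergences (`c + D*`).
#' @export
predict.epifit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  stopifnot(all(c("t_i", "t_j", "t_ij") %in% names(newdata)))
  tmx <- as.matrix(newdata[, c("t_ij", "t_i", "t_j")])
  p <- object$par
  as.numeric(cpp_pred_d(.sys_code(object$system), .form_code(object$form),
                        p[["alpha"]], p[["beta"]], p[["w"]], p[["gamma"]],
                        object$data$p1_obs, object$data$p3_obs, tmx)) +
    p[["c"]]
}

#' @export
summary.epifit <- function(object, ...) {
  out <- list(fit = object,
              coef = object$par[object$free],
              rss = object$rss, df = object$df,
              r_squared = object$r_squared,
              sigma = sqrt(object$sigma2), eq_uu = object$eq_uu,
              p_bar_1 = object$data$p_bar_1)
  class(out) <- "summary.epifit"
  out
}

#' @export
print.summary.epifit <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Epimutation model: ", f$form, " (", f$system, " system), ",
      f$M, " pairs\n\n", sep = "")
  cat("Parameter estimates:\n")
  print(signif(x$coef, digits))
  cat(sprintf("\nRSS = %.4g on %d df;  sigma = %.4g;  R-squared = %.4f\n",
              x$rss, x$df, x$sigma, x$r_squared))
  if (is.finite(x$eq_uu))
    cat(sprintf("Equilibrium u/u proportion = %.4f (pooled p_bar_1 = %.4f)\n",
                x$eq_uu, x$p_bar_1))
  if (!f$converged)
    cat("Warning: best Nelder-Mead start did not report convergence\n")
  invisible(x)
}

#' Plot observed and fitted divergence against divergence time
#'
#' @param x an `"epifit"`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.epifit <- function(x, ...) {
  dt <- x$data$pairs$delta_t
  graphics::plot(dt, x$data$pairs$D, xlab = expression(Delta * t),
                 ylab = "5mC divergence D",
                 main = paste(x$form, "fit"), ...)
  o <- order(dt)
  graphics::lines(dt[o], x$fitted[o], col = 2, lwd = 2)
  graphics::points(dt[o], x$fitted[o], col = 2, pch = 16, cex = 0.6)
  invisible(x)
}

#' Simulate divergence responses from a fitted model
#'
#' Draws new response vectors under the fitted regression model
#' `D = c + D* + e` with `e ~ N(0, sigma2)` (Gaussian residuals, the
#' model's error assumption).
#'
#' @param object an `"epifit"`.
#' @param nsim number of response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data.frame with `nsim` columns, each a simulated `D` vector.
#' @export
simulate.epifit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  M <- object$M
  out <- as.data.frame(matrix(
    rep(object$fitted, nsim) +
      stats::rnorm(M * nsim, 0, sqrt(object$sigma2)),
    nrow = M))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
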