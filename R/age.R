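#' Profile the unknown founder age of a somatic pedigree
#'
#' When the total age of a tree is unknown (coring of the oldest sector
#' failed or is imprecise), the divergence times of sample pairs spanning
#' different stems are undefined.  The age is then treated as an
#' additional unknown: for each candidate age the pedigree is rebuilt, the
#' pair times recomputed, the model refitted, and the minimized objective
#' (the model residual, LSQ) recorded.  The age estimate is the grid
#' argmin (ties broken to the smallest age).  The pairwise divergences
#' themselves do not depend on the candidate age and are computed once.
#'
#' @param ped_fun function mapping a candidate age to a `"pedigree"`
#'   (e.g. `function(a) tree_pedigree(a, branch_ages)`).
#' @param samples list of `"methylome"` objects matching the pedigree's
#'   samples.
#' @param ages numeric grid of candidate ages (e.g. `seq(250, 350, 5)`).
#' @param form,system model form and propagation system (somatic
#'   phylogenies use the clonal kernel).
#' @param founder_sample optional founder sample id, as in
#'   [divergence_dataset()].
#' @param n_starts,seed,max_iter fitting controls per candidate age; each
#'   age after the first is additionally warm-started at the previous
#'   age's estimate.
#' @return An object of class `"age_profile"`: list with `ages`, `lsq`
#'   (minimized objective per age), `age_hat`, `fits` (per-age
#'   `"epifit"`s) and `best_fit`.  Supports `print` and `plot` (the
#'   LSQ-vs-age profile).
#' @export
profile_founder_age <- function(ped_fun, samples, ages,
                                form = "ABneutral", system = "clonal",
                                founder_sample = NULL,
                                n_starts = 10, seed = 1L, max_iter = 1000) {
  stopifnot(is.function(ped_fun), length(ages) >= 1)
  ages <- sort(unique(as.numeric(ages)))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  names(samples) <- ids

  # pair divergences are age-invariant: compute once
  cmb <- utils::combn(sort(ids), 2)
  Dtab <- data.frame(sample_i = cmb[1, ], sample_j = cmb[2, ],
                     D = NA_real_, N_shared = NA_integer_,
                     stringsAsFactors = FALSE)
  for (k in seq_len(ncol(cmb))) {
    dv <- pair_divergence(samples[[cmb[1, k]]], samples[[cmb[2, k]]])
    Dtab$D[k] <- dv$D
    Dtab$N_shared[k] <- dv$N_shared
  }
  sp <- state_proportions(samples)
  if (!is.null(founder_sample)) {
    i <- match(founder_sample, sp$counts$sample_id)
    if (is.na(i)) stop("founder_sample not among the samples")
    p1 <- sp$counts$x1[i] / sp$counts$N[i]
    p3 <- sp$counts$x3[i] / sp$counts$N[i]
  } else {
    p1 <- mean(sp$counts$x1 / sp$counts$N)
    p3 <- mean(sp$counts$x3 / sp$counts$N)
  }

  fits <- vector("list", length(ages))
  lsq <- rep(NA_real_, length(ages))
  warm <- NULL
  for (a in seq_along(ages)) {
    ped <- ped_fun(ages[a])
    pt <- pair_times(ped, ids)
    key <- paste(pt$sample_i, pt$sample_j)
    m <- match(key, paste(Dtab$sample_i, Dtab$sample_j))
    pt$D <- Dtab$D[m]
    pt$N_shared <- Dtab$N_shared[m]
    dat <- divergence_data(pt, p1_obs = p1, p3_obs = p3,
                           p_bar_1 = sp$p_bar_1)
    fit <- epifit(dat, form = form, system = system, n_starts = n_starts,
                  seed = seed, max_iter = max_iter, start = warm)
    fits[[a]] <- fit
    lsq[a] <- fit$value
    warm <- fit$par
  }
  best <- which.min(lsq)  # first minimum = smallest age on ties
  out <- list(ages = ages, lsq = lsq, age_hat = ages[best],
              fits = fits, best_fit = fits[[best]],
              form = form, system = system)
  class(out) <- "age_profile"
  out
}

#' @export
print.age_profile <- function(x, ...) {
  cat("Founder-age profile (", x$form, ", ", x$system, " system)\n",
      sep = "")
  cat("  grid: ", length(x$ages), " ages in [", min(x$ages), ", ",
      max(x$ages), "]\n", sep = "")
  cat(sprintf("  estimated age = %g (LSQ = %.6g)\n", x$age_hat,
              min(x$lsq)))
  invisible(x)
}

#' Plot the LSQ-versus-age profile
#'
#' @param x an `"age_profile"`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.age_profile <- function(x, ...) {
  graphics::plot(x$ages, x$lsq, type = "b", xlab = "candidate founder age",
                 ylab = "model residual (LSQ)", ...)
  graphics::abline(v = x$age_hat, lty = 2, col = 2)
  invisible(x)
}
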