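#' Divergence indicator between two methylation states
#'
#' The per-locus contribution to the mean absolute methylome divergence:
#' 0 if the two states are equal, 1/2 if exactly one is the epiheterozygote
#' (0.5), and 1 for an opposite-homozygote pair (0 vs 1).  This equals
#' `abs(a - b)` on the state coding `{0, 0.5, 1}`.
#'
#' @param a,b numeric vectors of states in `{0, 0.5, 1}` (recycled).
#' @return Numeric vector of indicator values in `{0, 0.5, 1}`.
#' @export
state_indicator <- function(a, b) {
  if (!all(a %in% c(0, 0.5, 1)) || !all(b %in% c(0, 0.5, 1)))
    stop("states must be 0, 0.5 or 1")
  abs(a - b)
}

#' Mean absolute methylome divergence between two samples
#'
#' Computes \eqn{D = N^{-1} \sum_k I(s_{ak}, s_{bk})} over the \eqn{N}
#' loci measured in both samples (per-pair intersection; loci absent from
#' either sample are simply dropped and never imputed).
#'
#' @param a,b `"methylome"` objects.
#' @return A list with `D` (in `[0, 1]`) and `N_shared`.
#' @export
pair_divergence <- function(a, b) {
  stopifnot(inherits(a, "methylome"), inherits(b, "methylome"))
  i <- match(names(a$states), names(b$states))
  ok <- !is.na(i)
  n <- sum(ok)
  if (n == 0) stop("samples '", a$sample_id, "' and '", b$sample_id,
                   "' share no loci")
  list(D = mean(abs(a$states[ok] - b$states[i[ok]])), N_shared = n)
}

#' Assemble the model-ready divergence dataset
#'
#' Joins the pairwise divergence values to the pedigree's divergence times:
#' one record per unique sample pair with internal-scale times
#' (`t_i`, `t_j`, `t_ij`, founder at 1), the divergence time `delta_t`, the
#' divergence `D` and the shared-locus count.  Also records the founder
#' state proportions `p1_obs = x1/N`, `p3_obs = x3/N` (from
#' `founder_sample` if given, else averaged over all samples) and the
#' pooled mean u/u proportion `p_bar_1`, which the fit uses as its
#' equilibrium anchor.
#'
#' @param ped a `"pedigree"` object.
#' @param samples list of `"methylome"` objects whose `sample_id`s match
#'   the pedigree's `sample_ref`s.
#' @param founder_sample optional sample id whose state proportions are
#'   used for the founder distribution.
#' @param common_loci if `TRUE`, restrict every pair to the loci shared by
#'   *all* samples (global intersection) instead of the default per-pair
#'   intersection.
#' @return An object of class `"divergence_data"`: list with `pairs`
#'   (data.frame), `p1_obs`, `p3_obs`, `p_bar_1`, `M`.
#' @export
divergence_dataset <- function(ped, samples, founder_sample = NULL,
                               common_loci = FALSE) {
  stopifnot(inherits(ped, "pedigree"), is.list(samples))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  names(samples) <- ids
  if (common_loci) {
    keys <- Reduce(intersect, lapply(samples, function(s) names(s$states)))
    if (!length(keys)) stop("no loci shared by all samples")
    samples <- lapply(samples, function(s) {
      i <- match(keys, names(s$states))
      methylome(s$sample_id, s$loci[i, , drop = FALSE], unname(s$states[i]))
    })
    names(samples) <- ids
  }
  pt <- pair_times(ped, ids)
  pt$D <- NA_real_
  pt$N_shared <- NA_integer_
  for (k in seq_len(nrow(pt))) {
    dv <- pair_divergence(samples[[pt$sample_i[k]]],
                          samples[[pt$sample_j[k]]])
    pt$D[k] <- dv$D
    pt$N_shared[k] <- dv$N_shared
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
  divergence_data(pt, p1_obs = p1, p3_obs = p3, p_bar_1 = sp$p_bar_1)
}

#' Construct a divergence dataset from a precomputed pair table
#'
#' Lower-level constructor used by [divergence_dataset()] and by fits that
#' start from a previously written divergence table or from simulated
#' responses.
#'
#' @param pairs data.frame with columns `sample_i`, `sample_j`, `t_i`,
#'   `t_j`, `t_ij`, `delta_t`, `D` and optionally `N_shared` (times on the
#'   internal scale, founder at 1).
#' @param p1_obs,p3_obs founder proportions of u/u and m/m loci.
#' @param p_bar_1 pooled mean u/u proportion across samples.
#' @return A `"divergence_data"` object.
#' @export
divergence_data <- function(pairs, p1_obs, p3_obs, p_bar_1) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  need <- c("sample_i", "sample_j", "t_i", "t_j", "t_ij", "delta_t", "D")
  if (!all(need %in% names(pairs)))
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(pairs$D >= 0 & pairs$D <= 1),
            p1_obs >= 0, p1_obs <= 1, p3_obs >= 0, p3_obs <= 1,
            p1_obs + p3_obs <= 1 + 1e-9,
            p_bar_1 >= 0, p_bar_1 <= 1)
  if (any(pairs$t_ij < 1 - 1e-9))
    stop("pair times must be on the internal scale (founder at t = 1)")
  structure(list(pairs = pairs, p1_obs = p1_obs, p3_obs = p3_obs,
                 p_bar_1 = p_bar_1, M = nrow(pairs)),
            class = "divergence_data")
}

#' @export
print.divergence_data <- function(x, ...) {
  cat("Divergence dataset: ", x$M, " sample pairs\n", sep = "")
  cat(sprintf("  delta_t range [%g, %g];  D range [%.4g, %.4g]\n",
              min(x$pairs$delta_t), max(x$pairs$delta_t),
              min(x$pairs$D), max(x$pairs$D)))
  cat(sprintf("  founder p1 = %.4g, p3 = %.4g;  pooled p_bar_1 = %.4g\n",
              x$p1_obs, x$p3_obs, x$p_bar_1))
  invisible(x)
}

#' Write a divergence dataset to a tab-separated file
#'
#' The pair table is written with a short `#key=value` comment header
#' carrying the founder proportions and `p_bar_1`, so the file can be read
#' back with [read_divergence()] and fitted directly.
#'
#' @param x a `"divergence_data"` object.
#' @param path output path.
#' @return Invisibly, `x`.
#' @export
write_divergence <- function(x, path) {
  stopifnot(inherits(x, "divergence_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s=%.17g", c("p1_obs", "p3_obs", "p_bar_1"),
                     c(x$p1_obs, x$p3_obs, x$p_bar_1)), con)
  utils::write.table(x$pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a divergence dataset written by [write_divergence()]
#'
#' @param path file path.
#' @return A `"divergence_data"` object.
#' @export
read_divergence <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]),
                                 numeric(1)),
                          vapply(kv, `[`, character(1), 1))
  pairs <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  divergence_data(pairs, vals[["p1_obs"]], vals[["p3_obs"]],
                  vals[["p_bar_1"]])
}
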