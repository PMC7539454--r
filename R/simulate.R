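#' Draw founder epigenotype states
#'
#' I.i.d. draws of diploid epigenotypes (coded 0, 0.5, 1) from a founder
#' distribution over (u/u, m/u, m/m).
#'
#' @param n_loci number of loci.
#' @param founder_pi probability 3-vector.
#' @param seed optional seed.
#' @return Numeric state vector of length `n_loci`.
#' @export
sample_founder <- function(n_loci, founder_pi, seed = NULL) {
  stopifnot(n_loci >= 0, length(founder_pi) == 3, all(founder_pi >= 0),
            abs(sum(founder_pi) - 1) < 1e-9)
  if (!is.null(seed)) set.seed(seed)
  if (n_loci == 0) return(numeric(0))
  c(0, 0.5, 1)[sample.int(3, n_loci, replace = TRUE, prob = founder_pi)]
}

# one forward step of the epigenotype chain for an integer state vector
.evolve_step <- function(st, G) {
  new <- st
  for (s in 1:3) {
    idx <- which(st == s)
    if (length(idx))
      new[idx] <- sample.int(3, length(idx), replace = TRUE, prob = G[s, ])
  }
  new
}

.misclassify <- function(st, rate) {
  if (rate <= 0) return(st)
  flip <- stats::runif(length(st)) < rate
  n <- sum(flip)
  if (n)  # shift to one of the two wrong states, uniformly
    st[flip] <- ((st[flip] - 1L + sample.int(2, n, replace = TRUE)) %% 3L) + 1L
  st
}

#' Forward-simulate epigenotypes through a pedigree
#'
#' Evolves every locus independently down the pedigree: each child node's
#' per-locus state is drawn from the transition-kernel row of its parent's
#' state once per elapsed time unit along the edge.  An observation layer
#' then flips each observed state to one of the other two states (chosen
#' uniformly) with probability `misclass_rate`, emulating measurement
#' error; misclassification affects only the emitted methylomes, never the
#' transmitted states.  Edge durations must be integers unless
#' `fractional = TRUE`, in which case the state distribution after a
#' fractional duration `d` is obtained from `kernel_power(G, d)` and
#' sampled once per edge.
#'
#' @param ped a `"pedigree"` object.
#' @param system,form,alpha,beta,w kernel specification (see
#'   [epi_kernel()]).
#' @param n_loci number of independent loci.
#' @param founder_pi founder distribution over (u/u, m/u, m/m).
#' @param misclass_rate observation misclassification probability in
#'   `[0, 1)`.
#' @param seed optional seed; the full output is reproducible given the
#'   seed.
#' @param keep `"samples"` (default) returns methylomes for sampled nodes
#'   only; `"all"` for every node (keyed by node id).
#' @param fractional allow non-integer edge durations (see above).
#' @return Named list of `"methylome"` objects (loci `chr1:1..n_loci`,
#'   `+` strand, CG context).
#' @export
evolve_pedigree <- function(ped, system, form = "ABneutral",
                            alpha, beta, w = 1, n_loci, founder_pi,
                            misclass_rate = 0, seed = NULL,
                            keep = c("samples", "all"),
                            fractional = FALSE) {
  stopifnot(inherits(ped, "pedigree"), n_loci >= 0,
            misclass_rate >= 0, misclass_rate < 1)
  keep <- match.arg(keep)
  if (!is.null(seed)) set.seed(seed)
  G <- epi_kernel(system, form, alpha, beta, w)
  ids <- ped$nodes$node_id
  it <- stats::setNames(ped$nodes$itime, ids)
  states <- vector("list", length(ids))
  names(states) <- ids
  states[[ped$root]] <- sample.int(3, n_loci, replace = TRUE,
                                   prob = founder_pi)
  # parents precede children when sorted by internal time (ties resolved by
  # repeated sweeps; zero-length offshoots share their parent's time)
  todo <- setdiff(ids[order(it[ids])], ped$root)
  for (id in todo) {
    p <- ped$parent[[id]]
    d <- it[[id]] - it[[p]]
    if (abs(d - round(d)) < 1e-9) {
      st <- states[[p]]
      for (k in seq_len(round(d))) st <- .evolve_step(st, G)
    } else {
      if (!fractional)
        stop("non-integer edge duration ", d, " on edge ", p, " -> ", id,
             "; set fractional = TRUE to enable fractional stepping")
      P <- kernel_power(G, d)
      P <- pmax(P, 0)
      st <- states[[p]]
      for (s in 1:3) {
        idx <- which(states[[p]] == s)
        if (length(idx))
          st[idx] <- sample.int(3, length(idx), replace = TRUE,
                                prob = P[s, ])
      }
    }
    states[[id]] <- st
  }
  out_ids <- if (keep == "all") ids else
    ids[!is.na(ped$nodes$sample_ref)]
  loci <- data.frame(seqname = "chr1", position = seq_len(n_loci),
                     strand = "+", context = "CG",
                     stringsAsFactors = FALSE)
  out <- lapply(out_ids, function(id) {
    obs <- .misclassify(states[[id]], misclass_rate)
    sid <- ped$nodes$sample_ref[match(id, ids)]
    if (is.na(sid)) sid <- id
    methylome(sid, loci, c(0, 0.5, 1)[obs])
  })
  names(out) <- vapply(out, function(s) s$sample_id, character(1))
  out
}

#' Monte-Carlo oracle for the expected divergence
#'
#' Brute-force estimate of the model's expected divergence for one pair
#' configuration: `reps` independent loci are drawn for the most recent
#' common ancestor from `pi G'^(t_ij - 1)`, evolved down the two branches
#' by per-time-unit sampling from the kernel rows, and the state indicator
#' is averaged.  Serves as the independent check of
#' [expected_divergence()] (the analytic triple sum): the two must agree
#' within Monte-Carlo error.
#'
#' @inheritParams epi_kernel
#' @param t_i,t_j,t_ij pair times (internal scale, founder at 1); branch
#'   durations must be integers.
#' @param pi founder distribution.
#' @param reps number of simulated loci.
#' @param seed optional seed.
#' @return List with `estimate` and `se` (sample SD / sqrt(reps)).
#' @export
mc_divergence <- function(system, form = "ABneutral", alpha, beta, w = 1,
                          t_i, t_j, t_ij, pi, reps, seed = NULL) {
  stopifnot(reps >= 1, t_ij >= 1 - 1e-9, t_i >= t_ij, t_j >= t_ij)
  if (!is.null(seed)) set.seed(seed)
  G <- epi_kernel(system, form, alpha, beta, w)
  anc_dist <- as.numeric(pi %*% kernel_power(G, t_ij - 1))
  anc_dist <- pmax(anc_dist, 0)
  anc <- sample.int(3, reps, replace = TRUE, prob = anc_dist)
  branch <- function(st, d) {
    if (abs(d - round(d)) > 1e-9)
      stop("branch durations must be integers for the Monte-Carlo oracle")
    for (k in seq_len(round(d))) st <- .evolve_step(st, G)
    st
  }
  si <- branch(anc, t_i - t_ij)
  sj <- branch(anc, t_j - t_ij)
  ind <- abs(c(0, 0.5, 1)[si] - c(0, 0.5, 1)[sj])
  list(estimate = mean(ind), se = stats::sd(ind) / sqrt(reps))
}

#' Simulate a ready-to-fit divergence dataset from a pedigree
#'
#' Convenience wrapper: forward-simulates methylomes for all sampled nodes
#' with [evolve_pedigree()] and assembles the model-ready dataset with
#' [divergence_dataset()].
#'
#' @inheritParams evolve_pedigree
#' @param founder_sample optional sample id passed to
#'   [divergence_dataset()].
#' @param common_loci passed to [divergence_dataset()].
#' @return A `"divergence_data"` object.
#' @export
simulate_dataset <- function(ped, system, form = "ABneutral",
                             alpha, beta, w = 1, n_loci, founder_pi,
                             misclass_rate = 0, seed = NULL,
                             founder_sample = NULL, common_loci = FALSE,
                             fractional = FALSE) {
  samples <- evolve_pedigree(ped, system, form, alpha, beta, w,
                             n_loci, founder_pi, misclass_rate, seed,
                             keep = "samples", fractional = fractional)
  divergence_dataset(ped, samples, founder_sample = founder_sample,
                     common_loci = common_loci)
}
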