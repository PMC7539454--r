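#' Pedigree of a standard mutation-accumulation design
#'
#' Builds the pedigree of an MA experiment in which `n_lineages` replicate
#' lineages are propagated independently from a single founder and sampled
#' at given generations.  Each sampled generation of each lineage is a node
#' on that lineage's germline path; the founder itself can be sampled
#' (e.g. generation-0 methylomes).
#'
#' @param n_lineages number of replicate lineages.
#' @param sample_gens generations (per lineage) at which methylomes are
#'   collected, e.g. `c(10, 20, 30)`.
#' @param founder_sampled if `TRUE`, the founder carries a sample
#'   (`"S_F"`).
#' @return A `"pedigree"` with lineage nodes `L<i>_G<g>` and samples
#'   `S_L<i>_G<g>`.
#' @export
ma_pedigree <- function(n_lineages, sample_gens, founder_sampled = TRUE) {
  stopifnot(n_lineages >= 1, length(sample_gens) >= 1, all(sample_gens > 0))
  sample_gens <- sort(unique(sample_gens))
  nodes <- data.frame(node_id = "F", time = 0,
                      sample_ref = if (founder_sampled) "S_F"
                                   else NA_character_,
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent_id = character(0), child_id = character(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_lineages)) {
    prev <- "F"
    for (g in sample_gens) {
      id <- sprintf("L%d_G%d", i, g)
      nodes <- rbind(nodes, data.frame(node_id = id, time = g,
                                       sample_ref = paste0("S_", id)))
      edges <- rbind(edges, data.frame(parent_id = prev, child_id = id))
      prev <- id
    }
  }
  build_pedigree(nodes, edges)
}

#' Pedigree of a multi-stem tree (somatic phylogeny)
#'
#' Builds the intra-organismal phylogeny of a tree whose stems are clones
#' of a common (possibly dead) bole: every stem diverges from the founder
#' at time 0, carries a chain of coring-dated branch points, and each
#' branch point spawns one leaf sampled at the present (`total_age`).
#' Branch-point positions are given as ages before present (the quantity
#' coring measures), so the same `branch_ages` can be combined with a
#' candidate `total_age` when the founder age itself is unknown --- this is
#' the parameterized builder that [profile_founder_age()] expects.
#'
#' @param total_age total age of the tree (time units, e.g. years).
#' @param branch_ages list with one numeric vector per stem: the ages
#'   before present of that stem's branch points, in decreasing order;
#'   all must be smaller than `total_age`.
#' @return A `"pedigree"` with root `root` (time 0) and sampled leaves
#'   `S_T<s>_B<k>` at time `total_age`.
#' @export
tree_pedigree <- function(total_age, branch_ages) {
  stopifnot(is.list(branch_ages), length(branch_ages) >= 1)
  if (any(unlist(branch_ages) >= total_age))
    stop("candidate total_age (", total_age, ") not larger than every ",
         "branch-point age before present")
  nodes <- data.frame(node_id = "root", time = 0,
                      sample_ref = NA_character_, stringsAsFactors = FALSE)
  edges <- data.frame(parent_id = character(0), child_id = character(0),
                      stringsAsFactors = FALSE)
  for (s in seq_along(branch_ages)) {
    ages <- sort(branch_ages[[s]], decreasing = TRUE)
    prev <- "root"
    for (k in seq_along(ages)) {
      bp <- sprintf("T%d_BP%d", s, k)
      leaf <- sprintf("T%d_B%d", s, k)
      nodes <- rbind(nodes,
                     data.frame(node_id = bp, time = total_age - ages[k],
                                sample_ref = NA_character_),
                     data.frame(node_id = leaf, time = total_age,
                                sample_ref = paste0("S_", leaf)))
      edges <- rbind(edges,
                     data.frame(parent_id = prev, child_id = bp),
                     data.frame(parent_id = bp, child_id = leaf))
      prev <- bp
    }
  }
  build_pedigree(nodes, edges)
}
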