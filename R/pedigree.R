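#' Build a pedigree from node and edge tables
#'
#' A pedigree describes the lineage topology of a mutation-accumulation (MA)
#' experiment or of an intra-organismal somatic phylogeny (e.g. the branches
#' of a tree dated by coring).  It is a rooted, time-annotated graph: every
#' node carries an absolute time (generations for MA lines, years for trees),
#' the unique root is the founder, and node times never decrease along any
#' root-to-leaf path.  Internally all times are shifted so that the founder
#' sits at time 1; model exponents are taken on that internal scale.
#'
#' Sampled individuals are attached to nodes through `sample_ref`.  Siblings
#' of a germline progenitor can be represented as zero-length (or short)
#' offshoot edges from the germline node of their generation, so both
#' progenitor and sibling sampling schemes are expressible in one format.
#'
#' @param nodes data.frame with columns `node_id`, `time` and optionally
#'   `sample_ref` (NA or `""` for unsampled nodes).  Times may be
#'   non-integer (e.g. coring ages in years); no rounding is performed.
#' @param edges data.frame with columns `parent_id`, `child_id`.
#' @return An object of class `"pedigree"`: a list with the validated node
#'   table (including the internal time column `itime`, founder at 1), the
#'   parent map, the root id and the founder time offset.
#' @examples
#' ped <- build_pedigree(
#'   nodes = data.frame(node_id = c("F", "A", "B"), time = c(0, 3, 31),
#'                      sample_ref = c(NA, "S_A", "S_B")),
#'   edges = data.frame(parent_id = c("F", "A"), child_id = c("A", "B")))
#' pair_times(ped)
#' @seealso [pair_times()], [mrca_time()], [read_pedigree()]
#' @export
build_pedigree <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("node_id", "time") %in% names(nodes)),
            all(c("parent_id", "child_id") %in% names(edges)))
  nodes$node_id <- as.character(nodes$node_id)
  nodes$time <- as.numeric(nodes$time)
  if (anyNA(nodes$time) || any(!is.finite(nodes$time)))
    stop("node times must be finite numbers")
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node_id in node table")
  if (is.null(nodes$sample_ref)) nodes$sample_ref <- NA_character_
  nodes$sample_ref <- as.character(nodes$sample_ref)
  nodes$sample_ref[!is.na(nodes$sample_ref) & nodes$sample_ref == ""] <-
    NA_character_
  sr <- nodes$sample_ref[!is.na(nodes$sample_ref)]
  if (anyDuplicated(sr)) stop("duplicate sample_ref in node table")

  ids <- nodes$node_id
  if (nrow(edges) > 0) {
    edges$parent_id <- as.character(edges$parent_id)
    edges$child_id <- as.character(edges$child_id)
    unknown <- setdiff(c(edges$parent_id, edges$child_id), ids)
    if (length(unknown))
      stop("edge table refers to unknown node(s): ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(edges$child_id))
      stop("node with multiple parents: ",
           paste(unique(edges$child_id[duplicated(edges$child_id)]),
                 collapse = ", "))
  }
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (nrow(edges) > 0) parent[edges$child_id] <- edges$parent_id

  roots <- ids[is.na(parent)]
  if (length(roots) != 1)
    stop("pedigree must have exactly one root (found ",
         length(roots), ": ", paste(roots, collapse = ", "), ")")
  root <- roots

  # walk to the root from every node: detects cycles and disconnection
  time <- stats::setNames(nodes$time, ids)
  n <- length(ids)
  for (id in ids) {
    seen <- character(0)
    cur <- id
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) stop("cycle detected in pedigree at node ", cur)
      seen <- c(seen, cur)
      p <- parent[[cur]]
      if (time[[cur]] < time[[p]] - 1e-9)
        stop("child time < parent time on edge ", p, " -> ", cur)
      cur <- p
      if (length(seen) > n) stop("cycle detected in pedigree")
    }
    if (cur != root)
      stop("node ", id, " is not reachable from the root ", root)
  }

  nodes$itime <- nodes$time - time[[root]] + 1
  structure(list(nodes = nodes, parent = parent, root = root,
                 founder_time_offset = 1 - time[[root]]),
            class = "pedigree")
}

#' Read a pedigree from tab-separated node and edge files
#'
#' The node file must have a header row with columns `node_id`, `time` and
#' optionally `sample_ref`; the edge file columns `parent_id`, `child_id`.
#' Times are read as decimal numbers.  Gzip-compressed files are read
#' transparently.
#'
#' @param nodes_file,edges_file paths to the tab-separated tables.
#' @return A `"pedigree"` object (see [build_pedigree()]).
#' @export
read_pedigree <- function(nodes_file, edges_file) {
  nodes <- utils::read.delim(nodes_file, stringsAsFactors = FALSE,
                             colClasses = NA)
  edges <- utils::read.delim(edges_file, stringsAsFactors = FALSE)
  build_pedigree(nodes, edges)
}

#' Write a pedigree to tab-separated node and edge files
#'
#' @param ped a `"pedigree"` object.
#' @param nodes_file,edges_file output paths.
#' @return Invisibly, `ped`.
#' @export
write_pedigree <- function(ped, nodes_file, edges_file) {
  stopifnot(inherits(ped, "pedigree"))
  nd <- ped$nodes[, c("node_id", "time", "sample_ref")]
  utils::write.table(nd, nodes_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ch <- names(ped$parent)[!is.na(ped$parent)]
  ed <- data.frame(parent_id = unname(ped$parent[ch]), child_id = ch)
  utils::write.table(ed, edges_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ped)
}

.ancestor_chain <- function(ped, id) {
  chain <- id
  while (!is.na(ped$parent[[id]])) {
    id <- ped$parent[[id]]
    chain <- c(chain, id)
  }
  chain
}

.node_of_sample <- function(ped, sample_id) {
  i <- match(sample_id, ped$nodes$sample_ref)
  if (is.na(i)) {
    i <- match(sample_id, ped$nodes$node_id)
    if (is.na(i)) stop("sample or node not found in pedigree: ", sample_id)
  }
  ped$nodes$node_id[i]
}

#' Time of the most recent common ancestor of two nodes
#'
#' A node counts as its own ancestor, so for two samples on the same lineage
#' the MRCA is the earlier of the two.  The returned time is on the original
#' (input) time scale of the node table.
#'
#' @param ped a `"pedigree"` object.
#' @param a,b node ids (or sample ids attached via `sample_ref`).
#' @return The MRCA time (numeric, original scale).
#' @export
mrca_time <- function(ped, a, b) {
  stopifnot(inherits(ped, "pedigree"))
  na <- .node_of_sample(ped, a)
  nb <- .node_of_sample(ped, b)
  ca <- .ancestor_chain(ped, na)
  common <- ca[ca %in% .ancestor_chain(ped, nb)]
  mrca <- common[1]  # chains are ordered leaf -> root; first hit is deepest
  ped$nodes$time[match(mrca, ped$nodes$node_id)]
}

#' Divergence times for all unique sample pairs
#'
#' For samples i and j with times \eqn{t_i, t_j} and MRCA time
#' \eqn{t_{ij}}, the divergence time is
#' \eqn{\Delta t = (t_i - t_{ij}) + (t_j - t_{ij})}.  Times in the returned
#' table are on the internal scale on which the founder sits at time 1 (the
#' scale the epimutation models expect); `delta_t` is identical on both
#' scales.  Pairs are ordered lexicographically by sample id.
#'
#' @param ped a `"pedigree"` object.
#' @param samples character vector of sample ids; defaults to every sample
#'   attached to the pedigree.
#' @return data.frame with columns `sample_i`, `sample_j`, `t_i`, `t_j`,
#'   `t_ij`, `delta_t`, one row per unordered pair.
#' @export
pair_times <- function(ped, samples = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(samples))
    samples <- ped$nodes$sample_ref[!is.na(ped$nodes$sample_ref)]
  samples <- sort(unique(as.character(samples)))
  if (length(samples) < 2)
    stop("need at least two samples to form pairs")
  node <- vapply(samples, .node_of_sample, character(1), ped = ped)
  it <- stats::setNames(ped$nodes$itime, ped$nodes$node_id)
  chains <- lapply(node, .ancestor_chain, ped = ped)
  cmb <- utils::combn(seq_along(samples), 2)
  out <- data.frame(
    sample_i = samples[cmb[1, ]],
    sample_j = samples[cmb[2, ]],
    t_i = unname(it[node[cmb[1, ]]]),
    t_j = unname(it[node[cmb[2, ]]]),
    t_ij = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(cmb))) {
    ca <- chains[[cmb[1, k]]]
    mrca <- ca[ca %in% chains[[cmb[2, k]]]][1]
    out$t_ij[k] <- it[[mrca]]
  }
  out$delta_t <- (out$t_i - out$t_ij) + (out$t_j - out$t_ij)
  out
}

#' @export
print.pedigree <- function(x, ...) {
  ns <- sum(!is.na(x$nodes$sample_ref))
  cat("Pedigree: ", nrow(x$nodes), " nodes, root '", x$root, "', ",
      ns, " sampled node(s)\n", sep = "")
  cat("  time span (original scale): [",
      min(x$nodes$time), ", ", max(x$nodes$time), "]\n", sep = "")
  invisible(x)
}
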