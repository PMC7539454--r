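#' Construct a methylome sample
#'
#' A methylome sample is one individual's map from cytosine loci to diploid
#' methylation states, coded 0 (u/u, both alleles unmethylated), 0.5 (m/u,
#' epiheterozygote) and 1 (m/m).  A locus is identified by the exact tuple
#' (seqname, position, strand, context): cytosine calls from bisulphite
#' callers are strand-specific, so cross-sample matching requires equality
#' of all four fields.
#'
#' @param sample_id character scalar.
#' @param loci data.frame with columns `seqname`, `position` (1-based
#'   integer), `strand` (`+`/`-`) and `context` (`CG`, `CHG` or `CHH`).
#' @param states numeric vector of states in `{0, 0.5, 1}`, one per locus.
#' @return An object of class `"methylome"`.
#' @export
methylome <- function(sample_id, loci, states) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  stopifnot(all(c("seqname", "position", "strand", "context") %in%
                  names(loci)),
            nrow(loci) == length(states))
  states <- as.numeric(states)
  if (length(states) && !all(states %in% c(0, 0.5, 1)))
    stop("states must be 0, 0.5 or 1")
  pos <- suppressWarnings(as.numeric(loci$position))
  if (length(pos) && (anyNA(pos) || any(pos < 1) || any(pos != round(pos))))
    stop("malformed position: need 1-based integers")
  loci$position <- as.integer(pos)
  bad <- setdiff(unique(loci$context), c("CG", "CHG", "CHH"))
  if (length(bad))
    stop("unknown context: ", paste(bad, collapse = ", "))
  key <- paste(loci$seqname, loci$position, loci$strand, loci$context,
               sep = "\r")
  if (anyDuplicated(key)) stop("duplicate locus in methylome")
  structure(list(sample_id = as.character(sample_id), loci = loci,
                 states = stats::setNames(states, key)),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  n <- length(x$states)
  cat("Methylome sample '", x$sample_id, "': ", n, " loci\n", sep = "")
  if (n) {
    tb <- table(factor(x$states, levels = c(0, 0.5, 1)))
    cat("  u/u: ", tb[[1]], "  m/u: ", tb[[2]], "  m/m: ", tb[[3]], "\n",
        sep = "")
  }
  invisible(x)
}

#' Read methylation status calls from a tab-separated file
#'
#' Expects a header row with columns `seqname`, `position`, `strand`,
#' `context` and `status`, where status is `U` (unmethylated, state 0),
#' `I` (intermediate/epiheterozygote, state 0.5) or `M` (methylated,
#' state 1).  Gzip-compressed files are read transparently.
#'
#' @param path file path.
#' @param sample_id sample name; defaults to the file base name.
#' @param context optional character vector: keep only loci in these
#'   contexts (subset of `CG`, `CHG`, `CHH`).
#' @return A `"methylome"` object.
#' @export
read_methylome <- function(path, sample_id = NULL, context = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seqname", "position", "strand", "context", "status")
  if (!all(need %in% names(tab)))
    stop("methylome file must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$status), c("U", "I", "M"))
  if (length(bad))
    stop("unknown status token: ", paste(bad, collapse = ", "))
  if (!is.null(context)) tab <- tab[tab$context %in% context, , drop = FALSE]
  if (is.null(sample_id))
    sample_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  st <- c(U = 0, I = 0.5, M = 1)[tab$status]
  methylome(sample_id, tab[, need[1:4], drop = FALSE], unname(st))
}

#' Write a methylome sample to a tab-separated file
#'
#' Inverse of [read_methylome()]: the read-write round trip preserves the
#' state map exactly.
#'
#' @param x a `"methylome"` object.
#' @param path output path (a `.gz` suffix writes gzip).
#' @return Invisibly, `x`.
#' @export
write_methylome <- function(x, path) {
  stopifnot(inherits(x, "methylome"))
  tab <- x$loci
  tab$status <- c("U", "I", "M")[match(x$states, c(0, 0.5, 1))]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Call binary methylation states from read counts
#'
#' Per locus, an upper-tail binomial test of the methylated read count given
#' total coverage and a success probability equal to `error_rate` (the
#' bisulphite non-conversion/error rate).  P-values are adjusted across loci
#' with the Benjamini-Yekutieli procedure; loci with adjusted p at or below
#' `fdr` are called methylated (state 1), all others unmethylated (state 0).
#' No intermediate (0.5) states are produced: hidden epiheterozygosity is
#' absorbed by the founder-heterozygosity parameter `gamma` of the models.
#' Loci with zero coverage are dropped with a warning.
#'
#' @param counts data.frame with columns `seqname`, `position`, `strand`,
#'   `context`, `meth_reads`, `total_reads`.
#' @param error_rate probability in (0, 1); no default is guessed --- supply
#'   the rate estimated for the experiment (e.g. from a chloroplast or
#'   lambda spike-in).
#' @param fdr false discovery rate level (default 0.05).
#' @param sample_id sample name for the returned object.
#' @return A `"methylome"` object with states in `{0, 1}`.
#' @export
call_states_binomial <- function(counts, error_rate, fdr = 0.05,
                                 sample_id = "sample") {
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  stopifnot(all(c("meth_reads", "total_reads") %in% names(counts)),
            error_rate > 0, error_rate < 1)
  if (any(counts$meth_reads < 0) ||
      any(counts$meth_reads > counts$total_reads))
    stop("need 0 <= meth_reads <= total_reads")
  zero <- counts$total_reads == 0
  if (any(zero)) {
    warning(sum(zero), " locus/loci with zero coverage dropped")
    counts <- counts[!zero, , drop = FALSE]
  }
  p <- stats::pbinom(counts$meth_reads - 1, counts$total_reads, error_rate,
                     lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BY")
  methylome(sample_id,
            counts[, c("seqname", "position", "strand", "context")],
            as.numeric(padj <= fdr))
}

#' Restrict a methylome to genomic regions
#'
#' Retains the loci whose position falls inside any region of a BED or GFF3
#' annotation (e.g. exons, promoters, transposable elements), enabling
#' feature-specific epimutation rate estimates.  BED input is interpreted as
#' 0-based half-open `[start, end)`, GFF3 as 1-based closed; both are
#' normalized internally to 1-based closed coordinates (this is what
#' `rtracklayer::import` produces).  Overlap ignores strand.
#'
#' @param x a `"methylome"` object.
#' @param regions a `GRanges`, or a path to a BED or GFF3 file (format
#'   detected from the extension).
#' @return A `"methylome"` with the retained subset of loci.
#' @export
filter_by_regions <- function(x, regions) {
  stopifnot(inherits(x, "methylome"))
  if (is.character(regions)) {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", regions)))
    if (ext == "bed") {
      regions <- rtracklayer::import(regions, format = "BED")
    } else if (ext %in% c("gff", "gff3", "gtf")) {
      regions <- rtracklayer::import(regions, format = "GFF")
    } else {
      stop("unknown region file format: .", ext, " (need BED or GFF3)")
    }
  }
  if (!methods::is(regions, "GRanges"))
    stop("regions must be a GRanges or a BED/GFF3 file path")
  if (length(regions) == 0 || length(x$states) == 0) {
    keep <- logical(length(x$states))
  } else {
    gr <- GenomicRanges::GRanges(
      x$loci$seqname,
      IRanges::IRanges(x$loci$position, x$loci$position))
    keep <- IRanges::overlapsAny(gr, regions, ignore.strand = TRUE)
  }
  methylome(x$sample_id, x$loci[keep, , drop = FALSE],
            unname(x$states[keep]))
}

#' Per-sample state counts and the pooled u/u proportion
#'
#' Counts, for each sample, the loci in states u/u, m/u and m/m
#' (\eqn{x_1, x_2, x_3}, with \eqn{x_1+x_2+x_3=N}) and computes
#' \eqn{\bar p_1}, the mean over samples of \eqn{x_1/N}.  \eqn{\bar p_1}
#' serves as the empirical guess at the equilibrium u/u proportion that
#' anchors the model fit.
#'
#' @param samples a `"methylome"` or a list of them.
#' @return A list with `counts` (data.frame `sample_id`, `x1`, `x2`, `x3`,
#'   `N`) and `p_bar_1`.
#' @export
state_proportions <- function(samples) {
  if (inherits(samples, "methylome")) samples <- list(samples)
  if (!length(samples)) stop("need at least one sample")
  rows <- lapply(samples, function(s) {
    stopifnot(inherits(s, "methylome"))
    if (!length(s$states)) stop("empty sample: ", s$sample_id)
    data.frame(sample_id = s$sample_id,
               x1 = sum(s$states == 0),
               x2 = sum(s$states == 0.5),
               x3 = sum(s$states == 1),
               N = length(s$states), stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)
  list(counts = counts, p_bar_1 = mean(counts$x1 / counts$N))
}
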