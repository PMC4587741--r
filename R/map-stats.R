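# Contiguity and alignment-coverage summaries: the bnx_stats / cmap_stats /
# xmap_stats / BNGCompare family.

#' N50 of a multiset of lengths
#'
#' The largest length L such that elements of length >= L together contain
#' at least half the cumulative length (sort descending, accumulate, first
#' element where the running sum reaches total/2).
#'
#' @param lengths numeric vector of lengths (non-empty).
#' @return the N50 (numeric scalar).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("N50 of an empty set is undefined")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

# Batch-report variant: empty sets yield 0 with a warning instead of
# erroring inside a table build.
n50_or_zero <- function(lengths) {
  if (length(lengths) == 0L) {
    warning("N50 of an empty set reported as 0")
    return(0)
  }
  n50(lengths)
}

map_set_stats <- function(lengths) {
  data.frame(n_maps = length(lengths),
             cumulative_length = sum(lengths),
             n50 = if (length(lengths)) n50(lengths) else 0)
}

#' Molecule-map contiguity statistics per length filter
#'
#' @param molecules a [bnx_set()].
#' @param min_length_filters length thresholds (bp); one output row each,
#'   applied with [filter_by_min_length()]. Defaults to the standard
#'   100/150/180 kb trio.
#' @return data.frame with columns `min_length`, `n_maps`,
#'   `cumulative_length`, `n50`.
#' @export
bnx_stats <- function(molecules, min_length_filters = c(1e5, 1.5e5, 1.8e5)) {
  lens <- molecule_lengths(molecules)
  do.call(rbind, lapply(min_length_filters, function(f) {
    kept <- lens[lens >= f]
    cbind(data.frame(min_length = f),
          data.frame(n_maps = length(kept), cumulative_length = sum(kept),
                     n50 = if (length(kept)) n50(kept) else {
                       warning("N50 of an empty set reported as 0"); 0
                     }))
  }))
}

#' Consensus-map contiguity statistics
#'
#' @param maps a [cmap_set()].
#' @return one-row data.frame (`n_maps`, `cumulative_length`, `n50`); an
#'   empty set yields zeros with a warning for the N50.
#' @export
cmap_stats <- function(maps) {
  lens <- cmap_lengths(maps)
  data.frame(n_maps = length(lens), cumulative_length = sum(lens),
             n50 = n50_or_zero(lens))
}

#' Sequence contiguity statistics
#'
#' @param sequences a [Biostrings::DNAStringSet].
#' @return one-row data.frame (`n_maps`, `cumulative_length`, `n50`).
#' @export
seq_stats <- function(sequences) {
  map_set_stats(as.numeric(Biostrings::width(sequences)))
}

#' Alignment coverage on one side of an XMAP
#'
#' Breadth is the length of the interval union of aligned spans on the
#' chosen side (non-redundant coverage); total is the plain sum of span
#' lengths (with redundancy); percent is breadth over the cumulative map
#' length of that side.
#'
#' @param alignments an `xmap` data.frame.
#' @param maps a [cmap_set()] for the chosen side (all ids must resolve).
#' @param side `"reference"` or `"query"`.
#' @return list of class `alignment_coverage`: `breadth`, `total_aligned`,
#'   `percent_aligned`, `redundancy`, `side`.
#' @export
xmap_stats <- function(alignments, maps, side = c("reference", "query")) {
  side <- match.arg(side)
  ids <- if (side == "reference") alignments$ref_id else alignments$qry_id
  starts <- if (side == "reference") alignments$ref_start else
    alignments$qry_start
  ends <- if (side == "reference") alignments$ref_end else alignments$qry_end
  known <- as.integer(names(cmap_lengths(maps)))
  dangling <- setdiff(unique(ids), known)
  if (length(dangling))
    stop(sprintf("alignment references unknown %s map id(s): %s", side,
                 paste(dangling, collapse = ", ")))
  total_len <- sum(cmap_lengths(maps))
  breadth <- if (length(ids)) sum(vapply(unique(ids), function(id) {
    sel <- ids == id
    interval_union_length(starts[sel], ends[sel])
  }, numeric(1))) else 0
  total_aligned <- sum(ends - starts)
  out <- list(breadth = breadth, total_aligned = total_aligned,
              percent_aligned = if (total_len > 0)
                100 * breadth / total_len else 0,
              redundancy = total_aligned - breadth, side = side)
  class(out) <- "alignment_coverage"
  out
}

#' @export
print.alignment_coverage <- function(x, ...) {
  cat(sprintf(
    "<alignment_coverage (%s): breadth %.0f bp, total %.0f bp, %.2f%% covered, redundancy %.0f bp>\n",
    x$side, x$breadth, x$total_aligned, x$percent_aligned, x$redundancy))
  invisible(x)
}

#' Joint assembly/map comparison report
#'
#' Joins contiguity statistics for the sequence assembly, its in silico
#' maps and the consensus genome maps with alignment coverage measured on
#' both sides, in a fixed block order.
#'
#' @param fasta_stats one-row data.frame from [seq_stats()].
#' @param insilico_stats one-row data.frame from [cmap_stats()].
#' @param consensus_stats one-row data.frame from [cmap_stats()].
#' @param coverage_ref an `alignment_coverage` measured on the reference
#'   side.
#' @param coverage_qry an `alignment_coverage` measured on the query side.
#' @return data.frame with columns `block`, `metric`, `value`, in
#'   deterministic order; class `bng_compare`.
#' @export
compare_summary <- function(fasta_stats, insilico_stats, consensus_stats,
                            coverage_ref, coverage_qry) {
  stat_block <- function(block, s)
    data.frame(block = block,
               metric = c("n_maps", "cumulative_length", "n50"),
               value = c(s$n_maps, s$cumulative_length, s$n50))
  cov_block <- function(block, cv)
    data.frame(block = block,
               metric = c("breadth", "total_aligned", "percent_aligned",
                          "redundancy"),
               value = c(cv$breadth, cv$total_aligned, cv$percent_aligned,
                         cv$redundancy))
  out <- rbind(stat_block("sequence_assembly", fasta_stats),
               stat_block("insilico_maps", insilico_stats),
               stat_block("consensus_maps", consensus_stats),
               cov_block("coverage_reference_side", coverage_ref),
               cov_block("coverage_query_side", coverage_qry))
  rownames(out) <- NULL
  class(out) <- c("bng_compare", "data.frame")
  out
}
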