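#' Single-molecule label map
#'
#' One imaged DNA molecule: its length in bp and the ascending positions of
#' detected nick labels, plus scan/flowcell provenance. Any quality rows
#' (QX lines and other channels) found in a BNX block are retained verbatim
#' in `extra_rows` and written back unchanged.
#'
#' @param molecule_id integer id.
#' @param length molecule length in bp (may be fractional).
#' @param label_positions strictly ascending label positions (bp, channel 1).
#' @param scan_id integer scan number within the flowcell.
#' @param flowcell_id flowcell identifier (text).
#' @param extra_rows character vector of retained raw lines.
#' @return an object of class `molecule_map`.
#' @export
molecule_map <- function(molecule_id, length, label_positions = numeric(),
                         scan_id = 1L, flowcell_id = "1",
                         extra_rows = character()) {
  m <- structure(
    list(molecule_id = as.integer(molecule_id),
         length = as.numeric(length),
         label_positions = as.numeric(label_positions),
         scan_id = as.integer(scan_id),
         flowcell_id = as.character(flowcell_id),
         extra_rows = as.character(extra_rows)),
    class = "molecule_map")
  validate_molecule_map(m)
  m
}

#' @export
print.molecule_map <- function(x, ...) {
  cat(sprintf("<molecule_map %d: %.1f bp, %d labels, flowcell %s scan %d>\n",
              x$molecule_id, x$length, length(x$label_positions),
              x$flowcell_id, x$scan_id))
  invisible(x)
}

validate_molecule_map <- function(m) {
  if (!is.finite(m$length) || m$length <= 0)
    stop(sprintf("molecule %d: length must be > 0", m$molecule_id))
  p <- m$label_positions
  if (length(p)) {
    if (any(diff(p) <= 0))
      stop(sprintf("molecule %d: label positions not strictly ascending",
                   m$molecule_id))
    if (p[1L] <= 0 || p[length(p)] > m$length)
      stop(sprintf("molecule %d: label position outside (0, length]",
                   m$molecule_id))
  }
  invisible(m)
}

#' Collection of single-molecule maps
#'
#' @param molecules list of [molecule_map()] objects.
#' @return an object of class `bnx_set` (a list of `molecule_map`).
#' @export
bnx_set <- function(molecules = list()) {
  stopifnot(all(vapply(molecules, inherits, logical(1), "molecule_map")))
  structure(molecules, class = "bnx_set")
}

#' @export
print.bnx_set <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<bnx_set: %d molecules", n))
  if (n) cat(sprintf(", total %.1f Mb",
                     sum(vapply(x, `[[`, numeric(1), "length")) / 1e6))
  cat(">\n")
  invisible(x)
}

#' @export
`[.bnx_set` <- function(x, i) bnx_set(unclass(x)[i])

#' Lengths of the molecules in a bnx_set
#' @param x a `bnx_set`.
#' @return numeric vector of molecule lengths (bp).
#' @export
molecule_lengths <- function(x) vapply(x, `[[`, numeric(1), "length")

#' Consensus map record
#'
#' One CMAP record: either a consensus genome map (assembled from single
#' molecules by an external assembler) or an in silico map (digested from a
#' sequence scaffold). Sites are stored without the trailing channel-0 end
#' marker; the writer appends it and the reader strips it.
#'
#' @param cmap_id integer map id.
#' @param contig_length map length (bp).
#' @param sites data.frame with columns `site_id`, `channel`, `position`,
#'   `stddev`, `coverage`, `occurrence` (end marker excluded).
#' @return an object of class `consensus_map`.
#' @export
consensus_map <- function(cmap_id, contig_length, sites = empty_sites()) {
  sites <- as.data.frame(sites)
  need <- c("site_id", "channel", "position", "stddev", "coverage",
            "occurrence")
  stopifnot(all(need %in% names(sites)))
  m <- structure(
    list(cmap_id = as.integer(cmap_id),
         contig_length = as.numeric(contig_length),
         num_sites = nrow(sites),
         sites = sites[, need, drop = FALSE]),
    class = "consensus_map")
  validate_consensus_map(m)
  m
}

empty_sites <- function() {
  data.frame(site_id = integer(), channel = integer(), position = numeric(),
             stddev = numeric(), coverage = numeric(), occurrence = numeric())
}

#' Build a consensus map from bare label positions
#' @param cmap_id integer id.
#' @param contig_length map length (bp).
#' @param positions non-decreasing label positions (bp).
#' @param channel label channel (recycled).
#' @return a `consensus_map`.
#' @export
consensus_map_from_positions <- function(cmap_id, contig_length, positions,
                                         channel = 1L) {
  n <- length(positions)
  consensus_map(cmap_id, contig_length, data.frame(
    site_id = seq_len(n), channel = rep_len(as.integer(channel), n),
    position = as.numeric(positions), stddev = rep(0, n),
    coverage = rep(1, n), occurrence = rep(1, n)))
}

validate_consensus_map <- function(m) {
  if (!is.finite(m$contig_length) || m$contig_length <= 0)
    stop(sprintf("cmap %d: contig length must be > 0", m$cmap_id))
  p <- m$sites$position
  if (length(p)) {
    if (any(diff(p) < 0))
      stop(sprintf("cmap %d: site positions decrease", m$cmap_id))
    if (p[length(p)] > m$contig_length)
      stop(sprintf("cmap %d: site position beyond contig length", m$cmap_id))
  }
  invisible(m)
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("<consensus_map %d: %.1f bp, %d sites>\n",
              x$cmap_id, x$contig_length, x$num_sites))
  invisible(x)
}

#' Collection of consensus maps
#' @param maps list of [consensus_map()] objects.
#' @return an object of class `cmap_set`.
#' @export
cmap_set <- function(maps = list()) {
  stopifnot(all(vapply(maps, inherits, logical(1), "consensus_map")))
  ids <- vapply(maps, `[[`, integer(1), "cmap_id")
  if (anyDuplicated(ids)) stop("duplicate cmap ids")
  structure(stats::setNames(maps, ids), class = "cmap_set")
}

#' @export
print.cmap_set <- function(x, ...) {
  cat(sprintf("<cmap_set: %d maps, total %.2f Mb>\n", length(x),
              sum(cmap_lengths(x)) / 1e6))
  invisible(x)
}

#' @export
`[.cmap_set` <- function(x, i) cmap_set(unclass(x)[i])

#' Map lengths of a cmap_set
#' @param x a `cmap_set`.
#' @return named numeric vector of map lengths (bp), names are cmap ids.
#' @export
cmap_lengths <- function(x) {
  vapply(x, `[[`, numeric(1), "contig_length")
}

#' Empty XMAP alignment table
#'
#' Alignments are held as a data.frame (class `xmap`) in a *normalized*
#' in-memory convention: `qry_start < qry_end` always, with the strand in
#' `orientation`. The on-disk XMAP convention (negative-strand records store
#' `qry_start > qry_end`) is restored by [write_xmap()].
#'
#' @return zero-row `xmap` data.frame.
#' @export
empty_xmap <- function() {
  structure(
    data.frame(entry_id = integer(), qry_id = integer(), ref_id = integer(),
               qry_start = numeric(), qry_end = numeric(),
               ref_start = numeric(), ref_end = numeric(),
               orientation = character(), confidence = numeric(),
               hit_enum = character(), qry_len = numeric(),
               ref_len = numeric(), label_channel = integer(),
               alignment = character(), stringsAsFactors = FALSE),
    class = c("xmap", "data.frame"))
}

as_xmap <- function(df) {
  tpl <- empty_xmap()
  defaults <- list(hit_enum = "", label_channel = 1L, alignment = "",
                   qry_len = NA_real_, ref_len = NA_real_)
  for (nm in names(tpl)) {
    if (is.null(df[[nm]])) {
      fill <- defaults[[nm]]
      if (is.null(fill)) stop(sprintf("xmap column '%s' is required", nm))
      df[[nm]] <- rep(fill, nrow(df))
    }
  }
  df <- df[, names(tpl), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("xmap", "data.frame")
  validate_xmap(df)
  df
}

validate_xmap <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (!all(x$orientation %in% c("+", "-")))
    stop("orientation must be '+' or '-'")
  if (any(x$ref_end < x$ref_start)) stop("ref_end < ref_start")
  if (any(x$qry_end < x$qry_start))
    stop("normalized xmap requires qry_start < qry_end")
  invisible(x)
}

#' Thresholds governing one run of the stitching algorithm
#'
#' @param filter_sets list of two-element numeric vectors
#'   `c(min_confidence, min_pat)`. An alignment is kept when it passes at
#'   least one set (both boundaries inclusive). Defaults to the pair of sets
#'   `(13, 30)` and `(8, 90)`: one for high-confidence local-ish alignments,
#'   one for long overlaps in label-poor regions.
#' @param partial_pat_threshold percent-aligned below which a passing
#'   alignment is flagged as partial (default 60).
#' @param negative_gap_flag_limit gaps estimated below this (bp, negative)
#'   are flagged as potential mis-assemblies (default -20000).
#' @param min_negative_gap_exclusion optional bp limit; when set, both maps
#'   flanking a gap below it are excluded from joining in that iteration.
#'   Off (`NULL`) by default.
#' @param spacer_length length of the unknown-gap spacer (fixed at 100 bp).
#' @return an object of class `stitch_config`.
#' @export
stitch_config <- function(filter_sets = list(c(13, 30), c(8, 90)),
                          partial_pat_threshold = 60,
                          negative_gap_flag_limit = -20000,
                          min_negative_gap_exclusion = NULL,
                          spacer_length = 100) {
  stopifnot(length(filter_sets) >= 1L)
  for (fs in filter_sets) {
    stopifnot(length(fs) == 2L, fs[1L] >= 0, fs[2L] >= 0, fs[2L] <= 100)
  }
  if (spacer_length != 100) stop("spacer_length is fixed at 100 bp")
  if (partial_pat_threshold <= 0 || partial_pat_threshold >= 100)
    stop("partial_pat_threshold must lie in (0, 100)")
  structure(list(filter_sets = filter_sets,
                 partial_pat_threshold = partial_pat_threshold,
                 negative_gap_flag_limit = negative_gap_flag_limit,
                 min_negative_gap_exclusion = min_negative_gap_exclusion,
                 spacer_length = spacer_length),
            class = "stitch_config")
}

#' In silico digestion settings
#'
#' Defaults follow the dual-nicking design used for label densities below
#' the ideal band: nt.BspQI (GCTCTTC) plus nt.BbvCI (CCTCAGC), with
#' inclusion rules "longer than 20 kb" and "more than 5 labels" (both
#' strict inequalities).
#'
#' @param motifs named character vector of recognition sequences.
#' @param min_scaffold_length scaffolds must be strictly longer than this.
#' @param min_labels scaffolds must carry strictly more labels than this.
#' @param channel_mode `"merged"` (all motifs on channel 1) or
#'   `"per-enzyme"` (one channel per motif).
#' @return an object of class `digest_config`.
#' @export
digest_config <- function(motifs = c(BspQI = "GCTCTTC", BbvCI = "CCTCAGC"),
                          min_scaffold_length = 20000,
                          min_labels = 5,
                          channel_mode = c("merged", "per-enzyme")) {
  channel_mode <- match.arg(channel_mode)
  motifs <- toupper(motifs)
  if (length(motifs) == 0L || any(nchar(motifs) == 0L))
    stop("motifs must be non-empty")
  if (any(grepl("[^ACGT]", motifs)))
    stop("motifs must contain only A/C/G/T")
  stopifnot(min_scaffold_length > 0)
  structure(list(motifs = motifs,
                 min_scaffold_length = min_scaffold_length,
                 min_labels = min_labels,
                 channel_mode = channel_mode),
            class = "digest_config")
}
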