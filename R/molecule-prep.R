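# Molecule preparation: split BNX molecules by scan, estimate per-scan
# stretch (bases per pixel) from alignments to in silico maps, rescale
# label positions to nominal 500 bpp, QC, and merge.

NOMINAL_BPP <- 500

#' Partition molecules by (flowcell, scan)
#'
#' @param molecules a [bnx_set()].
#' @return named list of `bnx_set` partitions, key `"<flowcell>:<scan>"`,
#'   molecule order preserved within each partition.
#' @export
split_by_scan <- function(molecules) {
  if (length(molecules) == 0L) return(stats::setNames(list(), character()))
  keys <- vapply(molecules, function(m)
    paste(m$flowcell_id, m$scan_id, sep = ":"), "")
  idx <- split(seq_along(molecules), factor(keys, levels = unique(keys)))
  lapply(idx, function(i) bnx_set(unclass(molecules)[i]))
}

#' Estimate a scan's stretch from its molecules' alignments
#'
#' The scale is the length-weighted average ratio of reference (in silico)
#' to query (molecule) aligned span: `sum(ref spans) / sum(qry spans)`.
#' Bases-per-pixel is `500 * scale`. With no alignments the scan is
#' flagged, the estimate is absent (`bpp = NA`) and the scale defaults to 1
#' so rescaling is a no-op.
#'
#' @param alignments `xmap` of this scan's molecules (query) against in
#'   silico maps (reference).
#' @param flowcell_id,scan_id provenance labels for the report row.
#' @param qc_band acceptable bpp band; outside it the scan is flagged.
#'   Default `c(475, 525)` (nominal 500 +/- 5 percent).
#' @return an object of class `scan_stretch`: list with `flowcell_id`,
#'   `scan_id`, `bpp`, `scale`, `n_alignments`, `flagged`.
#' @export
estimate_scan_bpp <- function(alignments, flowcell_id = "1", scan_id = 1L,
                              qc_band = c(475, 525)) {
  n <- nrow(alignments)
  if (n == 0L) {
    est <- list(flowcell_id = flowcell_id, scan_id = as.integer(scan_id),
                bpp = NA_real_, scale = 1, n_alignments = 0L, flagged = TRUE)
    class(est) <- "scan_stretch"
    return(est)
  }
  ref_span <- sum(alignments$ref_end - alignments$ref_start)
  qry_span <- sum(alignments$qry_end - alignments$qry_start)
  if (qry_span <= 0) stop("zero total query span")
  scale <- ref_span / qry_span
  bpp <- NOMINAL_BPP * scale
  est <- list(flowcell_id = flowcell_id, scan_id = as.integer(scan_id),
              bpp = bpp, scale = scale, n_alignments = n,
              flagged = bpp < qc_band[1L] || bpp > qc_band[2L])
  class(est) <- "scan_stretch"
  est
}

#' @export
print.scan_stretch <- function(x, ...) {
  cat(sprintf("<scan_stretch %s:%d bpp=%s n=%d%s>\n", x$flowcell_id,
              x$scan_id, if (is.na(x$bpp)) "NA" else sprintf("%.2f", x$bpp),
              x$n_alignments, if (x$flagged) " FLAGGED" else ""))
  invisible(x)
}

#' Rescale a scan's molecules to nominal stretch
#'
#' Multiplies every label position and molecule length by the estimated
#' scale, bringing the scan to 500 bases per pixel.
#'
#' @param molecules a [bnx_set()] (one scan's molecules).
#' @param estimate a `scan_stretch` from [estimate_scan_bpp()] (or a bare
#'   numeric scale).
#' @return rescaled `bnx_set`.
#' @export
rescale_scan <- function(molecules, estimate) {
  scale <- if (inherits(estimate, "scan_stretch")) estimate$scale
           else as.numeric(estimate)
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  bnx_set(lapply(molecules, function(m) {
    m$length <- m$length * scale
    m$label_positions <- m$label_positions * scale
    m
  }))
}

#' Merge scan partitions back into one molecule collection
#'
#' Concatenates partitions; colliding molecule ids are renumbered
#' sequentially and the renumbering is recorded in attribute `id_map`.
#'
#' @param partitions list of `bnx_set` (as from [split_by_scan()]).
#' @return a single `bnx_set`; attribute `id_map` is a data.frame
#'   (`old_id`, `new_id`, `flowcell_id`, `scan_id`) of renumbered molecules.
#' @export
merge_scans <- function(partitions) {
  mols <- unlist(lapply(partitions, unclass), recursive = FALSE)
  if (length(mols) == 0L) {
    out <- bnx_set()
    attr(out, "id_map") <- data.frame(old_id = integer(), new_id = integer(),
                                      flowcell_id = character(),
                                      scan_id = integer())
    return(out)
  }
  ids <- vapply(mols, `[[`, integer(1), "molecule_id")
  remap <- list()
  if (anyDuplicated(ids)) {
    next_id <- max(ids) + 1L
    for (i in seq_along(mols)[duplicated(ids)]) {
      old <- mols[[i]]$molecule_id
      mols[[i]]$molecule_id <- next_id
      remap[[length(remap) + 1L]] <- data.frame(
        old_id = old, new_id = next_id, flowcell_id = mols[[i]]$flowcell_id,
        scan_id = mols[[i]]$scan_id, stringsAsFactors = FALSE)
      next_id <- next_id + 1L
    }
    message(sprintf("merge_scans: renumbered %d colliding molecule ids",
                    length(remap)))
  }
  out <- bnx_set(mols)
  attr(out, "id_map") <- if (length(remap)) do.call(rbind, remap) else
    data.frame(old_id = integer(), new_id = integer(),
               flowcell_id = character(), scan_id = integer())
  out
}

#' Per-scan stretch QC table
#'
#' @param estimates list of `scan_stretch` objects.
#' @return data.frame with one row per scan (`flowcell_id`, `scan_id`,
#'   `bpp`, `scale`, `n_alignments`, `flagged`), ordered by flowcell then
#'   scan.
#' @export
qc_report <- function(estimates) {
  if (length(estimates) == 0L)
    return(data.frame(flowcell_id = character(), scan_id = integer(),
                      bpp = numeric(), scale = numeric(),
                      n_alignments = integer(), flagged = logical()))
  tab <- do.call(rbind, lapply(estimates, function(e)
    data.frame(flowcell_id = e$flowcell_id, scan_id = e$scan_id,
               bpp = e$bpp, scale = e$scale, n_alignments = e$n_alignments,
               flagged = e$flagged, stringsAsFactors = FALSE)))
  tab <- tab[order(tab$flowcell_id, tab$scan_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Plot per-scan bpp for each flowcell
#'
#' One panel-less base-graphics plot: bpp against scan index, one line per
#' flowcell, with the nominal 500 bpp and the QC band marked.
#'
#' @param report data.frame from [qc_report()].
#' @param qc_band bpp band to draw.
#' @return the report, invisibly.
#' @export
plot_qc <- function(report, qc_band = c(475, 525)) {
  if (nrow(report) == 0L) {
    graphics::plot.new()
    return(invisible(report))
  }
  graphics::plot(report$scan_id, report$bpp, type = "n",
                 xlab = "scan", ylab = "bases per pixel",
                 ylim = range(c(report$bpp, qc_band, NOMINAL_BPP),
                              na.rm = TRUE))
  graphics::abline(h = NOMINAL_BPP, lty = 1, col = "grey40")
  graphics::abline(h = qc_band, lty = 2, col = "grey70")
  fcs <- unique(report$flowcell_id)
  for (i in seq_along(fcs)) {
    g <- report[report$flowcell_id == fcs[i], ]
    graphics::lines(g$scan_id, g$bpp, col = i)
    graphics::points(g$scan_id, g$bpp, col = i,
                     pch = ifelse(g$flagged, 4, 19))
  }
  invisible(report)
}

#' Filter molecules by minimum length
#'
#' Keeps molecules with `length >= min_length` (inclusive boundary).
#'
#' @param molecules a [bnx_set()].
#' @param min_length minimum molecule length in bp (>= 0).
#' @return filtered `bnx_set`.
#' @export
filter_by_min_length <- function(molecules, min_length) {
  stopifnot(min_length >= 0)
  keep <- molecule_lengths(molecules) >= min_length
  bnx_set(unclass(molecules)[keep])
}

#' Full molecule-preparation stage
#'
#' Splits by scan, estimates per-scan stretch from the given molecule-to-
#' in-silico-map alignments, rescales each scan, merges, and applies the
#' minimum-length filter. Alignment is an input (produced externally or by
#' the naive stand-in aligner); this stage never aligns.
#'
#' @param molecules a [bnx_set()].
#' @param alignments `xmap` of molecules (query) vs in silico maps
#'   (reference); query ids are molecule ids.
#' @param min_length minimum molecule length (bp) applied after merging.
#' @param qc_band acceptable bpp band.
#' @return list with `molecules` (adjusted, merged, filtered `bnx_set`),
#'   `qc` (the [qc_report()] table) and `estimates`.
#' @export
prep_molecules <- function(molecules, alignments, min_length = 150000,
                           qc_band = c(475, 525)) {
  parts <- split_by_scan(molecules)
  estimates <- vector("list", length(parts))
  adjusted <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    part <- parts[[i]]
    key <- strsplit(names(parts)[i], ":", fixed = TRUE)[[1L]]
    ids <- vapply(part, `[[`, integer(1), "molecule_id")
    aln <- alignments[alignments$qry_id %in% ids, , drop = FALSE]
    est <- estimate_scan_bpp(aln, flowcell_id = key[1L],
                             scan_id = as.integer(key[2L]),
                             qc_band = qc_band)
    estimates[[i]] <- est
    adjusted[[i]] <- rescale_scan(part, est)
  }
  merged <- merge_scans(adjusted)
  list(molecules = filter_by_min_length(merged, min_length),
       qc = qc_report(estimates), estimates = estimates)
}
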