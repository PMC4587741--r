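# BNX 1.x: one block per imaged molecule. A "0" line carries the molecule
# header (id, length, scan/flowcell provenance), a "1" line the channel-1
# label positions terminated by the molecule length, and any further lines
# in the block (QX quality rows, extra channels) are opaque and preserved.

#' Read a BNX 1.x single-molecule map file
#'
#' Liberal parser for the BNX 1.2 column layout: unknown header keys are
#' tolerated, quality rows and extra channels are retained verbatim per
#' molecule, and scan/flowcell provenance is taken from the 0-line columns
#' when present (defaulting to 1 otherwise).
#'
#' @param path path to a BNX text file.
#' @return a [bnx_set()] with the file's header lines in attribute `header`.
#' @export
read_bnx <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  version <- grep("BNX File Version", header, value = TRUE)
  if (length(version) == 0L || !grepl("1\\.", version[1L]))
    stop(sprintf("%s: header does not declare a BNX 1.x version", path))
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  mols <- list()
  cur <- NULL
  flush <- function(cur) {
    molecule_map(cur$id, cur$len, cur$pos, cur$scan, cur$flowcell, cur$extra)
  }
  for (i in body_idx) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    tag <- tok[1L]
    if (tag == "0") {
      if (!is.null(cur)) mols[[length(mols) + 1L]] <- flush(cur)
      if (length(tok) < 3L)
        stop_parse(path, i, "0 line needs at least id and length")
      len <- suppressWarnings(as.numeric(tok[3L]))
      if (is.na(len)) stop_parse(path, i, "non-numeric molecule length")
      cur <- list(id = as.integer(tok[2L]), len = len, pos = numeric(),
                  scan = if (length(tok) >= 8L && !is.na(tok[8L]))
                    as.integer(tok[8L]) else 1L,
                  flowcell = if (length(tok) >= 11L) tok[11L] else "1",
                  extra = character())
    } else if (tag == "1") {
      if (is.null(cur))
        stop_parse(path, i, "1 line before any 0 header line")
      vals <- suppressWarnings(as.numeric(tok[-1L]))
      if (anyNA(vals)) stop_parse(path, i, "non-numeric label position")
      # final value on the 1 line is the molecule length, not a label
      if (length(vals)) vals <- vals[-length(vals)]
      cur$pos <- vals
    } else {
      if (is.null(cur))
        stop_parse(path, i, "data line before any 0 header line")
      cur$extra <- c(cur$extra, lines[i])
    }
  }
  if (!is.null(cur)) mols[[length(mols) + 1L]] <- flush(cur)
  out <- bnx_set(mols)
  attr(out, "header") <- header
  out
}

#' Write a collection of molecule maps as BNX 1.2
#'
#' @param molecules a [bnx_set()] (or list of [molecule_map()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bnx <- function(molecules, path) {
  for (m in molecules) {
    tryCatch(validate_molecule_map(m), error = function(e)
      stop(sprintf("refusing to write molecule %d: %s",
                   m$molecule_id, conditionMessage(e))))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# BNX File Version:\t1.2",
    "# Label Channels:\t1",
    "# Nanochannel  START",
    paste("#0h", "LabelChannel", "MoleculeId", "Length", "AvgIntensity",
          "SNR", "NumberofLabels", "OriginalMoleculeId", "ScanNumber",
          "ScanDirection", "ChipId", "Flowcell", "RunId", sep = "\t"),
    paste("#0f", "int", "int", "float", "float", "float", "int", "int",
          "int", "int", "string", "int", "int", sep = "\t"),
    "#1h\tLabelChannel\tLabelPositions[N]",
    "#1f\tint\tfloat"), con)
  for (m in molecules) {
    writeLines(paste("0", m$molecule_id, fmt_bp(m$length), "0.0", "0.0",
                     length(m$label_positions), m$molecule_id, m$scan_id,
                     "-1", "chip", m$flowcell_id, "1", sep = "\t"), con)
    writeLines(paste(c("1", fmt_bp(c(m$label_positions, m$length))),
                     collapse = "\t"), con)
    if (length(m$extra_rows)) writeLines(m$extra_rows, con)
  }
  invisible(path)
}
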