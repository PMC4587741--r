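# XMAP 0.2: one alignment per row. Mandatory columns 1-9; QryLen, RefLen,
# LabelChannel and the label-pair Alignment string are optional. On disk a
# negative-strand record stores QryStartPos > QryEndPos; in memory spans are
# normalized to start < end with the strand kept in `orientation`.

xmap_columns <- c("XmapEntryID", "QryContigID", "RefContigID", "QryStartPos",
                  "QryEndPos", "RefStartPos", "RefEndPos", "Orientation",
                  "Confidence", "HitEnum", "QryLen", "RefLen", "LabelChannel",
                  "Alignment")

#' Read an XMAP 0.2 alignment file
#'
#' @param path path to an XMAP text file.
#' @return an `xmap` data.frame in the normalized in-memory convention
#'   (`qry_start < qry_end`, strand in `orientation`).
#' @export
read_xmap <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) return(empty_xmap())
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9L)) {
    bad <- which(lengths(fields) < 9L)[1L]
    stop(sprintf(
      "%s: XMAP row %d has %d columns; 9 are mandatory (through Confidence)",
      path, bad, length(fields[[bad]])))
  }
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  num <- function(i, default = NA_character_) {
    v <- suppressWarnings(as.numeric(get(i, default)))
    v
  }
  ori <- get(8L)
  if (!all(ori %in% c("+", "-")))
    stop(sprintf("%s: unknown orientation token '%s'",
                 path, setdiff(ori, c("+", "-"))[1L]))
  conf <- num(9L)
  if (anyNA(conf)) stop(sprintf("%s: non-numeric Confidence column", path))
  qs <- num(4L); qe <- num(5L)
  df <- data.frame(
    entry_id = as.integer(get(1L)), qry_id = as.integer(get(2L)),
    ref_id = as.integer(get(3L)),
    qry_start = pmin(qs, qe), qry_end = pmax(qs, qe),
    ref_start = num(6L), ref_end = num(7L),
    orientation = ori, confidence = conf, hit_enum = get(10L, ""),
    qry_len = num(11L), ref_len = num(12L),
    label_channel = {
      lc <- suppressWarnings(as.integer(get(13L, "1")))
      ifelse(is.na(lc), 1L, lc)
    },
    alignment = {
      a <- get(14L, "")
      ifelse(is.na(a), "", a)
    },
    stringsAsFactors = FALSE)
  as_xmap(df)
}

#' Write alignments as XMAP 0.2
#'
#' Restores the on-disk negative-strand convention (`QryStartPos >
#' QryEndPos` for orientation `-`).
#'
#' @param alignments an `xmap` data.frame (normalized convention).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xmap <- function(alignments, path) {
  x <- as_xmap(as.data.frame(alignments))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# XMAP File Version:\t0.2",
    "# Label Channels:\t1",
    paste0("#h ", paste(xmap_columns, collapse = "\t")),
    paste0("#f ", paste(c("int", "int", "int", "float", "float", "float",
                          "float", "string", "float", "string", "float",
                          "float", "int", "string"), collapse = "\t"))), con)
  if (nrow(x)) {
    neg <- x$orientation == "-"
    qs <- ifelse(neg, x$qry_end, x$qry_start)
    qe <- ifelse(neg, x$qry_start, x$qry_end)
    fmt_opt <- function(v) ifelse(is.na(v), "", fmt_bp(v))
    rows <- paste(x$entry_id, x$qry_id, x$ref_id, fmt_bp(qs), fmt_bp(qe),
                  fmt_bp(x$ref_start), fmt_bp(x$ref_end), x$orientation,
                  formatC(x$confidence, format = "f", digits = 2),
                  ifelse(is.na(x$hit_enum), "", x$hit_enum),
                  fmt_opt(x$qry_len), fmt_opt(x$ref_len), x$label_channel,
                  ifelse(is.na(x$alignment), "", x$alignment), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}
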