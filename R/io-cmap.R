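# CMAP 0.1: tab-separated site rows, one file holding many maps. Each map
# ends with a channel-0 marker row at position == contig length whose
# SiteID is NumSites + 1.

cmap_columns <- c("CMapId", "ContigLength", "NumSites", "SiteID",
                  "LabelChannel", "Position", "StdDev", "Coverage",
                  "Occurrence")

#' Read a CMAP 0.1 consensus-map file
#'
#' @param path path to a CMAP text file.
#' @return a [cmap_set()]. A missing channel-0 end marker is tolerated with
#'   a warning; a `NumSites` value disagreeing with the site rows is an
#'   error.
#' @export
read_cmap <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) return(cmap_set())
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 9L))
    stop(sprintf("%s: CMAP rows need 9 columns, found %d", path, min(ncol)))
  tab <- as.data.frame(do.call(rbind, lapply(fields, `[`, 1:9)),
                       stringsAsFactors = FALSE)
  names(tab) <- cmap_columns
  for (nm in cmap_columns) {
    v <- suppressWarnings(as.numeric(tab[[nm]]))
    if (anyNA(v)) stop(sprintf("%s: non-numeric value in column %s", path, nm))
    tab[[nm]] <- v
  }
  maps <- lapply(split(tab, factor(tab$CMapId, levels = unique(tab$CMapId))),
                 function(g) {
    marker <- g$LabelChannel == 0
    if (!any(marker)) {
      warning(sprintf("cmap %d: missing channel-0 end marker; reconstructed",
                      g$CMapId[1L]))
    }
    sites <- g[!marker, , drop = FALSE]
    if (nrow(sites) != g$NumSites[1L])
      stop(sprintf("cmap %d: NumSites %d disagrees with %d site rows",
                   g$CMapId[1L], g$NumSites[1L], nrow(sites)))
    consensus_map(g$CMapId[1L], g$ContigLength[1L], data.frame(
      site_id = as.integer(sites$SiteID), channel = as.integer(sites$LabelChannel),
      position = sites$Position, stddev = sites$StdDev,
      coverage = sites$Coverage, occurrence = sites$Occurrence))
  })
  cmap_set(unname(maps))
}

#' Write consensus maps as CMAP 0.1
#'
#' Appends the channel-0 end marker row for each map.
#'
#' @param maps a [cmap_set()] (or list of [consensus_map()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cmap <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# CMAP File Version:\t0.1",
    "# Label Channels:\t1",
    paste0("#h ", paste(cmap_columns, collapse = "\t")),
    paste0("#f ", paste(c("int", "float", "int", "int", "int", "float",
                          "float", "int", "int"), collapse = "\t"))), con)
  for (m in maps) {
    validate_consensus_map(m)
    s <- m$sites
    n <- nrow(s)
    rows <- character(n + 1L)
    for (i in seq_len(n)) {
      rows[i] <- paste(m$cmap_id, fmt_bp(m$contig_length), n, s$site_id[i],
                       s$channel[i], fmt_bp(s$position[i]),
                       fmt_bp(s$stddev[i]), s$coverage[i], s$occurrence[i],
                       sep = "\t")
    }
    rows[n + 1L] <- paste(m$cmap_id, fmt_bp(m$contig_length), n, n + 1L, 0L,
                          fmt_bp(m$contig_length), "0.0", 1, 1, sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read/write the digestion key file
#'
#' The key file links in silico map ids to the FASTA headers and lengths of
#' the scaffolds they were digested from (tab-separated: CompntId,
#' CompntName, CompntLength).
#'
#' @param key data.frame with columns `CompntId`, `CompntName`,
#'   `CompntLength`.
#' @param path file path.
#' @return `read_key` returns the key data.frame; `write_key` returns
#'   `path` invisibly.
#' @export
write_key <- function(key, path) {
  stopifnot(all(c("CompntId", "CompntName", "CompntLength") %in% names(key)))
  utils::write.table(key[, c("CompntId", "CompntName", "CompntLength")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_key
#' @export
read_key <- function(path) {
  k <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("CompntId", "CompntName", "CompntLength") %in% names(k)))
  k
}
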