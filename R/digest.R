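# In silico digestion: locate nicking-enzyme recognition motifs in sequence
# scaffolds and emit the label maps an optical-map aligner can consume.

#' Find nicking-enzyme label sites in a sequence
#'
#' Reports every occurrence of `motif` on the forward strand and every
#' occurrence of its reverse complement (i.e. motif hits on the reverse
#' strand), each as the 1-based coordinate of the leftmost base of the
#' match on the forward strand. Overlapping occurrences are all reported.
#' A motif equal to its own reverse complement is counted once per
#' genomic occurrence. Ambiguity codes (N etc.) never match.
#'
#' @param sequence character string or [Biostrings::DNAString].
#' @param motif recognition sequence (A/C/G/T).
#' @return ascending integer vector of 1-based site positions.
#' @export
find_label_sites <- function(sequence, motif) {
  if (!nzchar(motif)) stop("empty motif")
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A/C/G/T")
  subject <- if (inherits(sequence, "DNAString")) sequence
             else Biostrings::DNAString(toupper(as.character(sequence)))
  fwd <- Biostrings::start(
    Biostrings::matchPattern(motif, subject, fixed = TRUE))
  rc <- revcomp_chr(motif)
  if (rc == motif) return(sort(fwd))
  rev <- Biostrings::start(
    Biostrings::matchPattern(rc, subject, fixed = TRUE))
  sort(c(fwd, rev))
}

#' Digest FASTA scaffolds into in silico maps
#'
#' Scaffolds qualify when strictly longer than `min_scaffold_length` with
#' strictly more than `min_labels` label sites; the rest are listed in
#' `excluded` with the rule they failed. In merged-channel mode the site
#' list is the sorted union over motifs on channel 1; in per-enzyme mode
#' each motif gets its own channel.
#'
#' @param scaffolds a [Biostrings::DNAStringSet] (or named character vector)
#'   with unique names.
#' @param config a [digest_config()].
#' @return list with elements `maps` (a [cmap_set()]), `key` (data.frame
#'   `CompntId`, `CompntName`, `CompntLength`), and `excluded` (data.frame
#'   `CompntName`, `CompntLength`, `n_labels`, `reason`).
#' @export
digest_fasta <- function(scaffolds, config = digest_config()) {
  if (!inherits(scaffolds, "DNAStringSet"))
    scaffolds <- Biostrings::DNAStringSet(scaffolds)
  ids <- names(scaffolds)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("scaffold ids must be present and unique")
  maps <- list()
  key <- list()
  excluded <- list()
  next_id <- 1L
  for (i in seq_along(scaffolds)) {
    seqlen <- Biostrings::width(scaffolds)[i]
    per_motif <- lapply(config$motifs, function(m)
      find_label_sites(scaffolds[[i]], m))
    n_labels <- length(unique(unlist(per_motif)))
    ok_len <- seqlen > config$min_scaffold_length
    ok_lab <- n_labels > config$min_labels
    if (ok_len && ok_lab) {
      sites <- if (config$channel_mode == "merged") {
        pos <- sort(unique(unlist(per_motif)))
        data.frame(site_id = seq_along(pos), channel = 1L, position = pos,
                   stddev = 0, coverage = 1, occurrence = 1)
      } else {
        pos <- unlist(per_motif)
        ch <- rep(seq_along(per_motif), lengths(per_motif))
        o <- order(pos, ch)
        data.frame(site_id = seq_along(pos), channel = ch[o],
                   position = pos[o], stddev = 0, coverage = 1,
                   occurrence = 1)
      }
      maps[[length(maps) + 1L]] <- consensus_map(next_id, seqlen, sites)
      key[[length(key) + 1L]] <- data.frame(
        CompntId = next_id, CompntName = ids[i], CompntLength = seqlen,
        stringsAsFactors = FALSE)
      next_id <- next_id + 1L
    } else {
      reason <- paste(c(
        if (!ok_len) sprintf("length %d <= %d", seqlen,
                             config$min_scaffold_length),
        if (!ok_lab) sprintf("labels %d <= %d", n_labels,
                             config$min_labels)), collapse = "; ")
      excluded[[length(excluded) + 1L]] <- data.frame(
        CompntName = ids[i], CompntLength = seqlen, n_labels = n_labels,
        reason = reason, stringsAsFactors = FALSE)
    }
  }
  list(maps = cmap_set(maps),
       key = if (length(key)) do.call(rbind, key) else
         data.frame(CompntId = integer(), CompntName = character(),
                    CompntLength = integer()),
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         data.frame(CompntName = character(), CompntLength = integer(),
                    n_labels = integer(), reason = character()))
}

#' Label density of a map set, in labels per 100 kb
#'
#' Computes `1e5 * total sites / total length` overall and per label
#' channel, and reports whether the overall density lies inside the ideal
#' band for optical mapping, taken as the closed interval \[10, 15\].
#'
#' @param maps a [cmap_set()].
#' @param band ideal density band (closed), default `c(10, 15)`.
#' @return list with `overall`, `per_channel` (named numeric),
#'   `in_ideal_band` (logical), `band`, `total_length`, `total_sites`.
#' @export
label_density <- function(maps, band = c(10, 15)) {
  if (length(maps) == 0L) stop("no maps")
  total_len <- sum(cmap_lengths(maps))
  if (total_len <= 0) stop("zero total map length")
  channels <- unlist(lapply(maps, function(m) m$sites$channel))
  total_sites <- length(channels)
  per_channel <- if (total_sites) {
    tab <- table(channels)
    stats::setNames(1e5 * as.numeric(tab) / total_len, names(tab))
  } else numeric()
  overall <- 1e5 * total_sites / total_len
  list(overall = overall, per_channel = per_channel,
       in_ideal_band = overall >= band[1L] && overall <= band[2L],
       band = band, total_length = total_len, total_sites = total_sites)
}
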