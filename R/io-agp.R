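#' Ordered plan for one super scaffold
#'
#' Components are sequence scaffolds (by FASTA header) with an orientation,
#' separated by signed estimated gaps. A negative or zero gap is realised
#' as the fixed 100 bp unknown spacer when the plan is serialized.
#'
#' @param name object name (`Super_scaffold_<k>`).
#' @param components data.frame with columns `component_id` (character) and
#'   `orientation` (`"+"`/`"-"`).
#' @param gaps numeric vector of signed gap estimates (bp), length
#'   `nrow(components) - 1`.
#' @param provenance optional list (consensus map id, iteration, ...).
#' @return an object of class `super_scaffold_plan`.
#' @export
super_scaffold_plan <- function(name, components, gaps = numeric(),
                                provenance = list()) {
  components <- as.data.frame(components)
  stopifnot(all(c("component_id", "orientation") %in% names(components)),
            all(components$orientation %in% c("+", "-")))
  if (length(gaps) != max(nrow(components) - 1L, 0L))
    stop("need exactly one gap between each pair of consecutive components")
  if (anyDuplicated(components$component_id))
    stop("a component may appear only once in a plan")
  structure(list(name = name,
                 components = components[, c("component_id", "orientation")],
                 gaps = as.numeric(gaps), provenance = provenance),
            class = "super_scaffold_plan")
}

#' @export
print.super_scaffold_plan <- function(x, ...) {
  cat(sprintf("<super_scaffold_plan %s: %d components, gaps [%s]>\n",
              x$name, nrow(x$components),
              paste(round(x$gaps), collapse = ", ")))
  invisible(x)
}

# A signed gap estimate becomes either an N gap of its (rounded) length or,
# when non-positive (unknown/overlapping), the fixed 100 bp U spacer.
gap_run <- function(gap, spacer_length = 100) {
  len <- round(gap)
  if (len >= 1) list(type = "N", length = as.integer(len))
  else list(type = "U", length = as.integer(spacer_length))
}

agp_template <- function(n = 0L) {
  data.frame(object_id = character(n), object_start = integer(n),
             object_end = integer(n), part_number = integer(n),
             component_type = character(n), component_id = character(n),
             component_start = integer(n), component_end = integer(n),
             orientation = character(n), gap_length = integer(n),
             gap_type = character(n), linkage = character(n),
             evidence = character(n), stringsAsFactors = FALSE)
}

agp_rows_for_plan <- function(plan, lengths, spacer_length = 100) {
  comp <- plan$components
  n <- nrow(comp)
  rows <- vector("list", 2L * n - 1L)
  pos <- 0L
  part <- 0L
  for (i in seq_len(n)) {
    id <- comp$component_id[i]
    if (is.na(lengths[id]))
      stop(sprintf("component '%s' missing from registry", id))
    clen <- as.integer(lengths[id])
    part <- part + 1L
    rows[[2L * i - 1L]] <- data.frame(
      object_id = plan$name, object_start = pos + 1L,
      object_end = pos + clen, part_number = part, component_type = "W",
      component_id = id, component_start = 1L, component_end = clen,
      orientation = comp$orientation[i], gap_length = NA_integer_,
      gap_type = NA_character_, linkage = NA_character_,
      evidence = NA_character_, stringsAsFactors = FALSE)
    pos <- pos + clen
    if (i < n) {
      g <- gap_run(plan$gaps[i], spacer_length)
      part <- part + 1L
      rows[[2L * i]] <- data.frame(
        object_id = plan$name, object_start = pos + 1L,
        object_end = pos + g$length, part_number = part,
        component_type = g$type, component_id = NA_character_,
        component_start = NA_integer_, component_end = NA_integer_,
        orientation = NA_character_, gap_length = g$length,
        gap_type = "scaffold", linkage = "yes", evidence = "map",
        stringsAsFactors = FALSE)
      pos <- pos + g$length
    }
  }
  do.call(rbind, rows)
}

#' Build an AGP 2.0 table from super-scaffold plans
#'
#' Components referenced by the plans must be registered with their lengths;
#' registered components not used by any plan are emitted as single-component
#' objects (unplaced scaffolds pass through under their own name).
#'
#' @param plans list of [super_scaffold_plan()].
#' @param registry named numeric vector of component lengths (names are
#'   FASTA headers), or a data.frame with `CompntName` and `CompntLength`.
#' @param spacer_length unknown-gap spacer length (100 bp).
#' @return an `agp` data.frame (AGP v2.0 columns).
#' @export
agp_from_plans <- function(plans, registry, spacer_length = 100) {
  if (is.data.frame(registry))
    registry <- stats::setNames(registry$CompntLength, registry$CompntName)
  used <- unlist(lapply(plans, function(p) p$components$component_id))
  if (anyDuplicated(used))
    stop("a component may appear in only one plan")
  blocks <- lapply(plans, agp_rows_for_plan, lengths = registry,
                   spacer_length = spacer_length)
  unplaced <- setdiff(names(registry), used)
  for (id in unplaced) {
    blocks[[length(blocks) + 1L]] <- agp_rows_for_plan(
      super_scaffold_plan(id, data.frame(component_id = id,
                                         orientation = "+")),
      lengths = registry)
  }
  agp <- if (length(blocks)) do.call(rbind, blocks) else agp_template()
  rownames(agp) <- NULL
  validate_agp(agp)
  class(agp) <- c("agp", "data.frame")
  agp
}

# Every object must tile [1, object_end of last part] contiguously.
validate_agp <- function(agp) {
  for (obj in unique(agp$object_id)) {
    g <- agp[agp$object_id == obj, , drop = FALSE]
    g <- g[order(g$part_number), , drop = FALSE]
    if (g$object_start[1L] != 1L)
      stop(sprintf("AGP object %s does not start at 1", obj))
    if (nrow(g) > 1L &&
        any(g$object_start[-1L] != g$object_end[-nrow(g)] + 1L))
      stop(sprintf("AGP object %s parts do not tile contiguously", obj))
    spans <- g$object_end - g$object_start + 1L
    w <- g$component_type == "W"
    if (any(spans[w] != g$component_end[w] - g$component_start[w] + 1L))
      stop(sprintf("AGP object %s: component span mismatch", obj))
    if (any(spans[!w] != g$gap_length[!w]))
      stop(sprintf("AGP object %s: gap span mismatch", obj))
    if (any(g$component_type == "U" & g$gap_length != 100L))
      stop(sprintf("AGP object %s: U gaps must be exactly 100 bp", obj))
  }
  invisible(agp)
}

#' Write an AGP 2.0 file
#' @param agp an `agp` data.frame (from [agp_from_plans()] or assembled).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  validate_agp(agp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  if (nrow(agp)) {
    w <- agp$component_type == "W"
    col6 <- ifelse(w, agp$component_id, agp$gap_length)
    col7 <- ifelse(w, agp$component_start, agp$gap_type)
    col8 <- ifelse(w, agp$component_end, agp$linkage)
    col9 <- ifelse(w, agp$orientation, agp$evidence)
    writeLines(paste(agp$object_id, agp$object_start, agp$object_end,
                     agp$part_number, agp$component_type, col6, col7, col8,
                     col9, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an AGP 2.0 file
#' @param path path to an AGP file.
#' @return an `agp` data.frame.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) {
    agp <- agp_template()
    class(agp) <- c("agp", "data.frame")
    return(agp)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 9L)) stop(sprintf("%s: AGP rows need 9 columns", path))
  m <- do.call(rbind, lapply(f, `[`, 1:9))
  w <- m[, 5L] == "W"
  agp <- data.frame(
    object_id = m[, 1L], object_start = as.integer(m[, 2L]),
    object_end = as.integer(m[, 3L]), part_number = as.integer(m[, 4L]),
    component_type = m[, 5L],
    component_id = ifelse(w, m[, 6L], NA_character_),
    component_start = ifelse(w, suppressWarnings(as.integer(m[, 7L])), NA),
    component_end = ifelse(w, suppressWarnings(as.integer(m[, 8L])), NA),
    orientation = ifelse(w, m[, 9L], NA_character_),
    gap_length = ifelse(w, NA, suppressWarnings(as.integer(m[, 6L]))),
    gap_type = ifelse(w, NA_character_, m[, 7L]),
    linkage = ifelse(w, NA_character_, m[, 8L]),
    evidence = ifelse(w, NA_character_, m[, 9L]),
    stringsAsFactors = FALSE)
  validate_agp(agp)
  class(agp) <- c("agp", "data.frame")
  agp
}

#' Rebuild object sequences from an AGP and its component sequences
#'
#' The reconstruction oracle for the AGP/FASTA consistency invariant:
#' components are sliced from `components`, reverse-complemented where
#' placed `-`, and gaps become runs of `N`.
#'
#' @param agp an `agp` data.frame.
#' @param components a [Biostrings::DNAStringSet] of component sequences.
#' @return a [Biostrings::DNAStringSet] of object sequences, in first
#'   appearance order.
#' @export
agp_to_fasta <- function(agp, components) {
  objs <- unique(agp$object_id)
  seqs <- vapply(objs, function(obj) {
    g <- agp[agp$object_id == obj, , drop = FALSE]
    g <- g[order(g$part_number), , drop = FALSE]
    parts <- vapply(seq_len(nrow(g)), function(i) {
      if (g$component_type[i] == "W") {
        if (!g$component_id[i] %in% names(components))
          stop(sprintf("component '%s' missing from sequence set",
                       g$component_id[i]))
        s <- Biostrings::subseq(components[[g$component_id[i]]],
                                g$component_start[i], g$component_end[i])
        if (g$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
        as.character(s)
      } else {
        strrep("N", g$gap_length[i])
      }
    }, "")
    paste(parts, collapse = "")
  }, "")
  Biostrings::DNAStringSet(stats::setNames(seqs, objs))
}
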