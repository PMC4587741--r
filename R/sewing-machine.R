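# Iteration driver: re-digest the stitched FASTA, re-align, re-stitch,
# until no new super scaffolds are produced. Iteration matters because an
# in silico map can span two consensus maps: once its neighbours on one
# map are merged, the merged super scaffold's map can reach a second
# consensus map and recruit further scaffolds there.

# Expand one AGP W part into rows over original components, flipping the
# child part list when the part is placed "-" (orientation composition:
# "-" of "-" is "+").
expand_agp_part <- function(row, registry, visiting = character()) {
  if (row$component_type != "W") return(row)
  id <- row$component_id
  if (id %in% visiting)
    stop(sprintf("cycle in AGP registry at object '%s'", id))
  child <- registry[[id]]
  if (is.null(child)) return(row)
  rows <- do.call(rbind, lapply(seq_len(nrow(child)), function(i)
    expand_agp_part(child[i, , drop = FALSE], registry, c(visiting, id))))
  if (row$orientation == "-") {
    rows <- rows[rev(seq_len(nrow(rows))), , drop = FALSE]
    w <- rows$component_type == "W"
    rows$orientation[w] <- ifelse(rows$orientation[w] == "+", "-", "+")
  }
  rows
}

recoordinate_agp <- function(rows, object_id) {
  pos <- 0L
  for (i in seq_len(nrow(rows))) {
    span <- if (rows$component_type[i] == "W")
      rows$component_end[i] - rows$component_start[i] + 1L
    else rows$gap_length[i]
    rows$object_id[i] <- object_id
    rows$object_start[i] <- pos + 1L
    rows$object_end[i] <- pos + span
    rows$part_number[i] <- i
    pos <- pos + span
  }
  rownames(rows) <- NULL
  rows
}

#' Flatten nested super-scaffold AGP to original components
#'
#' Rewrites an AGP whose W lines may reference previously built objects so
#' that every W line references an original input scaffold, composing
#' orientations and recomputing object coordinates. Gap lines are
#' preserved.
#'
#' @param agp an `agp` data.frame.
#' @param registry named list mapping object names to their (already
#'   flattened) AGP rows; names absent from the registry are treated as
#'   original components.
#' @return flattened `agp` data.frame.
#' @export
flatten_agp <- function(agp, registry) {
  out <- lapply(unique(agp$object_id), function(obj) {
    g <- agp[agp$object_id == obj, , drop = FALSE]
    g <- g[order(g$part_number), , drop = FALSE]
    rows <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
      expand_agp_part(g[i, , drop = FALSE], registry)))
    recoordinate_agp(rows, obj)
  })
  flat <- do.call(rbind, out)
  validate_agp(flat)
  class(flat) <- c("agp", "data.frame")
  flat
}

#' Iterative super-scaffolding (the sewing-machine loop)
#'
#' Repeats digest -> align -> invert -> stitch on the working FASTA until a
#' pass creates no new joins or `max_iter` passes have run. The final AGP
#' is flattened so every component line references an original input
#' scaffold.
#'
#' @param scaffolds a [Biostrings::DNAStringSet] of draft scaffolds.
#' @param consensus_maps a [cmap_set()] of consensus genome maps.
#' @param aligner function `(insilico_maps, consensus_maps) -> xmap` with
#'   the in silico maps as reference (e.g. [naive_aligner()], or a wrapper
#'   around an external alignment tool).
#' @param digest_cfg a [digest_config()].
#' @param stitch_cfg a [stitch_config()].
#' @param max_iter maximum number of passes (default 5).
#' @return list with `fasta`, `agp` (flattened), `report` (per-iteration
#'   data.frame: `iteration`, `n_new_joins`, `n_records`, `n50`), `joins`,
#'   `flags`, `n_iterations`.
#' @export
run_iterations <- function(scaffolds, consensus_maps, aligner,
                           digest_cfg = digest_config(),
                           stitch_cfg = stitch_config(), max_iter = 5L) {
  stopifnot(!is.null(names(scaffolds)), !anyDuplicated(names(scaffolds)))
  current <- scaffolds
  registry <- list()
  counter <- 1L
  report <- list()
  joins <- list()
  flags <- list()
  for (iter in seq_len(max_iter)) {
    dig <- digest_fasta(current, digest_cfg)
    aln <- tryCatch(aligner(dig$maps, consensus_maps), error = function(e)
      stop(sprintf("aligner failed at iteration %d: %s", iter,
                   conditionMessage(e)), call. = FALSE))
    res <- stitch_once(current, invert_xmap(aln), dig$key, stitch_cfg,
                       counter_start = counter, iteration = iter)
    counter <- res$counter_end
    # register each newly built object's composition over originals
    for (p in res$plans) {
      obj_rows <- res$agp[res$agp$object_id == p$name, , drop = FALSE]
      flat <- flatten_agp(obj_rows, registry)
      registry[[p$name]] <- flat
    }
    current <- res$fasta
    if (nrow(res$joins)) joins[[length(joins) + 1L]] <- res$joins
    if (nrow(res$flags)) flags[[length(flags) + 1L]] <- res$flags
    report[[iter]] <- data.frame(
      iteration = iter, n_new_joins = res$n_new_joins,
      n_records = length(current),
      n50 = n50(as.numeric(Biostrings::width(current))))
    if (res$n_new_joins == 0L) break
  }
  final_agp <- flatten_agp(
    agp_from_plans(list(),
                   stats::setNames(as.numeric(Biostrings::width(current)),
                                   names(current)),
                   stitch_cfg$spacer_length),
    registry)
  list(fasta = current, agp = final_agp,
       report = do.call(rbind, report),
       joins = if (length(joins)) do.call(rbind, joins) else NULL,
       flags = if (length(flags)) do.call(rbind, flags) else NULL,
       n_iterations = length(report))
}
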