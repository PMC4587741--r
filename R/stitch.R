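# The stitching algorithm: invert consensus-vs-in-silico alignments, filter
# by confidence and percent-aligned, pick one alignment per in silico map,
# infer signed gaps from projected positions on the consensus map, build
# super scaffolds (FASTA + AGP), and flag likely mis-assemblies.

#' Swap query and reference roles of an alignment table
#'
#' The external aligner reports consensus genome maps aligned against in
#' silico maps (reference). Stitching works in consensus-map coordinates,
#' so the alignment is inverted: ids, spans and lengths swap sides,
#' orientation is preserved, label pairs are reversed pairwise, and the
#' result is sorted (stably) by the new reference id and start.
#'
#' @param alignments an `xmap` data.frame with `qry_len` and `ref_len` set.
#' @return inverted `xmap`, sorted by `ref_id` then `ref_start`.
#' @export
invert_xmap <- function(alignments) {
  x <- as_xmap(as.data.frame(alignments))
  if (nrow(x) == 0L) return(x)
  if (anyNA(x$qry_len) || anyNA(x$ref_len))
    stop("invert_xmap requires qry_len and ref_len on every record")
  inv <- x
  inv$qry_id <- x$ref_id;       inv$ref_id <- x$qry_id
  inv$qry_start <- x$ref_start; inv$ref_start <- x$qry_start
  inv$qry_end <- x$ref_end;     inv$ref_end <- x$qry_end
  inv$qry_len <- x$ref_len;     inv$ref_len <- x$qry_len
  inv$alignment <- vapply(x$alignment, swap_label_pairs, "")
  inv <- inv[order(inv$ref_id, inv$ref_start), , drop = FALSE]
  rownames(inv) <- NULL
  as_xmap(inv)
}

# "(r,q)(r,q)..." -> "(q,r)(q,r)..."
swap_label_pairs <- function(s) {
  if (is.na(s) || !nzchar(s)) return(s %||% "")
  gsub("\\(([0-9]+),([0-9]+)\\)", "(\\2,\\1)", s)
}

#' Percent of the total possible alignment length that is aligned
#'
#' For each alignment the total possible (overlap-limited) length extends
#' the aligned reference span by the smaller of the two maps' unaligned
#' overhangs on each side, taking query overhangs in alignment orientation.
#' End-overlapping or contained alignments score 100; interior local hits
#' score low. Used to filter out local alignments that a global or overlap
#' scoring scheme would not have produced.
#'
#' @param alignments an `xmap` data.frame with `qry_len` and `ref_len` set.
#' @return numeric vector of percents in (0, 100].
#' @export
percent_aligned <- function(alignments) {
  x <- alignments
  if (nrow(x) == 0L) return(numeric())
  if (anyNA(x$qry_len) || anyNA(x$ref_len))
    stop("percent_aligned requires qry_len and ref_len")
  aligned <- x$ref_end - x$ref_start
  if (any(aligned <= 0)) stop("zero-length aligned span")
  r_l <- x$ref_start
  r_r <- x$ref_len - x$ref_end
  neg <- x$orientation == "-"
  q_lead <- ifelse(neg, x$qry_len - x$qry_end, x$qry_start)
  q_trail <- ifelse(neg, x$qry_start, x$qry_len - x$qry_end)
  total <- aligned + pmin(r_l, q_lead) + pmin(r_r, q_trail)
  100 * aligned / total
}

# Query overhangs (in alignment orientation) and the reference interval
# obtained by extending the aligned span with them: where the whole
# scaffold would sit on the consensus map.
with_projection <- function(x) {
  neg <- x$orientation == "-"
  x$q_lead <- ifelse(neg, x$qry_len - x$qry_end, x$qry_start)
  x$q_trail <- ifelse(neg, x$qry_start, x$qry_len - x$qry_end)
  x$proj_start <- x$ref_start - x$q_lead
  x$proj_end <- x$ref_end + x$q_trail
  x
}

#' Filter alignments by confidence and percent-aligned
#'
#' An alignment passes when, for at least one filter set, its confidence
#' is at least the set's minimum confidence AND its percent-aligned is at
#' least the set's minimum PAT (both boundaries inclusive). The computed
#' percent is attached as column `pat`.
#'
#' @param alignments an `xmap` data.frame.
#' @param filter_sets list of `c(min_confidence, min_pat)` pairs (see
#'   [stitch_config()]).
#' @return the passing subset, with column `pat` attached.
#' @export
filter_alignments <- function(alignments,
                              filter_sets = stitch_config()$filter_sets) {
  stopifnot(length(filter_sets) >= 1L)
  x <- as.data.frame(alignments)
  if (nrow(x) == 0L) { x$pat <- numeric(); return(x) }
  x$pat <- percent_aligned(alignments)
  keep <- Reduce(`|`, lapply(filter_sets, function(fs)
    x$confidence >= fs[1L] & x$pat >= fs[2L]))
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Choose at most one scaffolding alignment per in silico map
#'
#' Scaffolding candidates are alignments on consensus maps to which at
#' least two distinct in silico maps align; others cannot produce a join.
#' Within the candidate pool each in silico map keeps its longest aligned
#' consensus-map span; ties go to the highest confidence, then (as a
#' deterministic stand-in for an arbitrary choice) to the smallest
#' consensus map id and smallest entry id. Consensus maps left with fewer
#' than two chosen maps produce no joins this iteration.
#'
#' @param passing output of [filter_alignments()] (inverted alignments:
#'   reference = consensus map, query = in silico map).
#' @return data.frame of chosen alignments with projection columns,
#'   ordered by `ref_id` then `proj_start`.
#' @export
select_scaffolding_alignments <- function(passing) {
  x <- as.data.frame(passing)
  if (nrow(x) == 0L) return(x)
  per_ref <- tapply(x$qry_id, x$ref_id, function(q) length(unique(q)))
  candidate_refs <- as.integer(names(per_ref)[per_ref >= 2L])
  x <- x[x$ref_id %in% candidate_refs, , drop = FALSE]
  if (nrow(x) == 0L) return(x)
  x$span <- x$ref_end - x$ref_start
  o <- order(x$qry_id, -x$span, -x$confidence, x$ref_id, x$entry_id)
  x <- x[o, , drop = FALSE]
  chosen <- x[!duplicated(x$qry_id), , drop = FALSE]
  keep_refs <- names(which(table(chosen$ref_id) >= 2L))
  chosen <- chosen[chosen$ref_id %in% as.integer(keep_refs), , drop = FALSE]
  chosen <- with_projection(chosen)
  chosen <- chosen[order(chosen$ref_id, chosen$proj_start,
                         chosen$proj_end), , drop = FALSE]
  rownames(chosen) <- NULL
  chosen
}

#' Order components and infer signed gaps on one consensus map
#'
#' Components are ordered by projected start (ties broken by projected
#' end, with a log message). The gap between consecutive components is the
#' distance between the first's projected end and the second's projected
#' start; overlapping projections give negative gaps.
#'
#' @param chosen data.frame of chosen alignments for a single consensus
#'   map (projection columns attached).
#' @return list with `components` (ordered data.frame) and `gaps`
#'   (signed numeric, length `nrow - 1`).
#' @export
infer_gaps <- function(chosen) {
  stopifnot(nrow(chosen) >= 2L, length(unique(chosen$ref_id)) == 1L)
  if (anyDuplicated(chosen$proj_start))
    message(sprintf(
      "consensus map %d: identical projected starts; ordered by projected end",
      chosen$ref_id[1L]))
  o <- order(chosen$proj_start, chosen$proj_end)
  comp <- chosen[o, , drop = FALSE]
  rownames(comp) <- NULL
  gaps <- comp$proj_start[-1L] - comp$proj_end[-nrow(comp)]
  list(components = comp, gaps = gaps)
}

# v1.4.5 behaviour: both in silico maps flanking a gap below the exclusion
# limit are removed from the join; gaps are re-inferred from the survivors,
# repeating until no sub-limit gap remains.
apply_negative_gap_exclusion <- function(parts, limit) {
  excluded <- parts$components[0, , drop = FALSE]
  repeat {
    bad <- which(parts$gaps < limit)
    if (length(bad) == 0L || nrow(parts$components) < 2L) break
    drop <- unique(c(bad[1L], bad[1L] + 1L))
    excluded <- rbind(excluded, parts$components[drop, , drop = FALSE])
    comp <- parts$components[-drop, , drop = FALSE]
    if (nrow(comp) < 2L) {
      parts <- list(components = comp, gaps = numeric())
      break
    }
    parts <- infer_gaps(comp)
  }
  list(parts = parts, excluded = excluded)
}

#' Flag potential mis-assemblies
#'
#' Reports a partial-alignment flag for every passing alignment whose
#' percent-aligned is below the partial threshold, and an extreme negative
#' gap flag for every inferred gap below the flag limit. These point at
#' chimeric scaffolds or consensus-map assembly errors for sequence-level
#' follow-up; flagged joins still proceed unless the optional exclusion
#' limit is configured.
#'
#' @param passing output of [filter_alignments()].
#' @param plan_parts list of per-consensus-map `list(components, gaps)`.
#' @param config a [stitch_config()].
#' @return data.frame flag log (`flag`, `consensus_id`, `qry_id`,
#'   `partner_qry_id`, `value`).
#' @export
flag_issues <- function(passing, plan_parts, config = stitch_config()) {
  flags <- list()
  if (nrow(passing)) {
    part <- passing[passing$pat < config$partial_pat_threshold, ,
                    drop = FALSE]
    if (nrow(part))
      flags[[length(flags) + 1L]] <- data.frame(
        flag = "partial_alignment", consensus_id = part$ref_id,
        qry_id = part$qry_id, partner_qry_id = NA_integer_,
        value = part$pat, stringsAsFactors = FALSE)
  }
  for (parts in plan_parts) {
    bad <- which(parts$gaps < config$negative_gap_flag_limit)
    if (length(bad))
      flags[[length(flags) + 1L]] <- data.frame(
        flag = "extreme_negative_gap",
        consensus_id = parts$components$ref_id[1L],
        qry_id = parts$components$qry_id[bad],
        partner_qry_id = parts$components$qry_id[bad + 1L],
        value = parts$gaps[bad], stringsAsFactors = FALSE)
  }
  if (length(flags)) do.call(rbind, flags) else
    data.frame(flag = character(), consensus_id = integer(),
               qry_id = integer(), partner_qry_id = integer(),
               value = numeric())
}

#' Build super-scaffold sequences and AGP from join plans
#'
#' Components are concatenated in order, reverse-complemented where placed
#' `-`; a positive gap becomes a run of `N` of the estimated (rounded)
#' length, a non-positive gap the fixed 100 bp spacer with an AGP U line.
#' Scaffolds not referenced by any plan pass through unchanged.
#'
#' @param plans list of [super_scaffold_plan()] (components named by FASTA
#'   header).
#' @param scaffolds a [Biostrings::DNAStringSet] of all input scaffolds.
#' @param config a [stitch_config()].
#' @return list with `fasta` (DNAStringSet: super scaffolds then unplaced
#'   scaffolds in input order), `agp`, and `joins` (per-gap log).
#' @export
build_super_scaffolds <- function(plans, scaffolds,
                                  config = stitch_config()) {
  lens <- stats::setNames(as.numeric(Biostrings::width(scaffolds)),
                          names(scaffolds))
  for (p in plans) {
    missing <- setdiff(p$components$component_id, names(scaffolds))
    if (length(missing))
      stop(sprintf("plan %s references missing scaffold(s): %s", p$name,
                   paste(missing, collapse = ", ")))
  }
  joins <- list()
  built <- vapply(plans, function(p) {
    n <- nrow(p$components)
    pieces <- character(2L * n - 1L)
    for (i in seq_len(n)) {
      s <- scaffolds[[p$components$component_id[i]]]
      if (p$components$orientation[i] == "-")
        s <- Biostrings::reverseComplement(s)
      pieces[2L * i - 1L] <- as.character(s)
      if (i < n) {
        g <- gap_run(p$gaps[i], config$spacer_length)
        pieces[2L * i] <- strrep("N", g$length)
        joins[[length(joins) + 1L]] <<- data.frame(
          super_scaffold = p$name,
          consensus_id = p$provenance$consensus_id %||% NA_integer_,
          left = p$components$component_id[i],
          left_orientation = p$components$orientation[i],
          right = p$components$component_id[i + 1L],
          right_orientation = p$components$orientation[i + 1L],
          gap_estimate = p$gaps[i], gap_type = g$type,
          gap_in_sequence = g$length, stringsAsFactors = FALSE)
      }
    }
    paste(pieces, collapse = "")
  }, "")
  names(built) <- vapply(plans, `[[`, "", "name")
  used <- unlist(lapply(plans, function(p) p$components$component_id))
  unplaced <- setdiff(names(scaffolds), used)
  fasta <- Biostrings::DNAStringSet(c(
    built, stats::setNames(as.character(scaffolds[unplaced]), unplaced)))
  agp <- agp_from_plans(plans, lens, config$spacer_length)
  joins <- if (length(joins)) do.call(rbind, joins) else
    data.frame(super_scaffold = character(), consensus_id = integer(),
               left = character(), left_orientation = character(),
               right = character(), right_orientation = character(),
               gap_estimate = numeric(), gap_type = character(),
               gap_in_sequence = integer())
  list(fasta = fasta, agp = agp, joins = joins)
}

#' One stitching pass
#'
#' Composition filter -> select -> infer gaps -> flag -> build over a draft
#' FASTA and its (inverted) consensus-map alignments. Alignment query ids
#' must resolve to in silico map ids in the digestion key.
#'
#' @param scaffolds a [Biostrings::DNAStringSet] of draft scaffolds.
#' @param alignments inverted `xmap` (reference = consensus map, query =
#'   in silico map), e.g. from [invert_xmap()].
#' @param key digestion key data.frame mapping `CompntId` to `CompntName`
#'   (from [digest_fasta()]).
#' @param config a [stitch_config()].
#' @param counter_start first integer for `Super_scaffold_<k>` names.
#' @param iteration iteration number recorded in plan provenance.
#' @return list with `fasta`, `agp`, `joins`, `flags`, `plans`,
#'   `n_new_joins`, `counter_end`.
#' @export
stitch_once <- function(scaffolds, alignments, key,
                        config = stitch_config(), counter_start = 1L,
                        iteration = 1L) {
  unresolved <- setdiff(unique(alignments$qry_id), key$CompntId)
  if (length(unresolved))
    stop(sprintf("alignment query ids not in digestion key: %s",
                 paste(unresolved, collapse = ", ")))
  passing <- filter_alignments(alignments, config$filter_sets)
  chosen <- select_scaffolding_alignments(passing)
  plan_parts <- if (nrow(chosen)) {
    lapply(split(chosen, chosen$ref_id), infer_gaps)
  } else list()
  flags <- flag_issues(passing, plan_parts, config)
  if (!is.null(config$min_negative_gap_exclusion)) {
    plan_parts <- lapply(plan_parts, function(parts) {
      res <- apply_negative_gap_exclusion(
        parts, config$min_negative_gap_exclusion)
      if (nrow(res$excluded))
        flags <<- rbind(flags, data.frame(
          flag = "negative_gap_exclusion",
          consensus_id = res$excluded$ref_id,
          qry_id = res$excluded$qry_id, partner_qry_id = NA_integer_,
          value = NA_real_))
      res$parts
    })
    plan_parts <- Filter(function(p) nrow(p$components) >= 2L, plan_parts)
  }
  name_of <- stats::setNames(key$CompntName, key$CompntId)
  k <- counter_start
  plans <- list()
  for (parts in plan_parts) {
    plans[[length(plans) + 1L]] <- super_scaffold_plan(
      name = sprintf("Super_scaffold_%d", k),
      components = data.frame(
        component_id = unname(name_of[as.character(parts$components$qry_id)]),
        orientation = parts$components$orientation,
        stringsAsFactors = FALSE),
      gaps = parts$gaps,
      provenance = list(consensus_id = parts$components$ref_id[1L],
                        iteration = iteration))
    k <- k + 1L
  }
  built <- build_super_scaffolds(plans, scaffolds, config)
  c(built, list(flags = flags, plans = plans,
                n_new_joins = nrow(built$joins), counter_end = k))
}
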