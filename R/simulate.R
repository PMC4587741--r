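# Synthetic data: a random genome, a fragmented scaffold set with known
# layout, consensus maps with optical-map noise (interval sizing error,
# label dropout, false labels, per-scan stretch), ground-truth alignments,
# and a naive overlap aligner. Everything is reproducible from (parameters,
# seed), and the truth tables suffice to compute every expected downstream
# answer exactly.

#' Generate a random genome sequence
#'
#' I.i.d. bases at the requested GC content, so motif occurrences appear
#' at roughly the density implied by base composition.
#'
#' @param length genome length (bp, > 0).
#' @param gc GC fraction in \[0, 1\].
#' @param seed RNG seed (optional).
#' @return a [Biostrings::DNAString].
#' @export
make_genome <- function(length, gc = 0.35, seed = NULL) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  Biostrings::DNAString(paste(
    sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
}

#' Fragment a genome into shuffled, re-oriented scaffolds
#'
#' Scaffolds tile the genome minus inter-scaffold gaps; a random subset is
#' reverse-complemented and the output order is shuffled, so downstream
#' stitching must recover both order and orientation. The truth layout
#' (genome order) makes every expected join computable.
#'
#' @param genome a [Biostrings::DNAString].
#' @param n_scaffolds number of scaffolds (>= 1).
#' @param gap_range integer range for true inter-scaffold gap lengths
#'   (zero-length gaps are allowed and exercise negative-gap handling
#'   downstream).
#' @param min_scaffold minimum scaffold length (bp).
#' @param revcomp_prob probability a scaffold is stored reverse-
#'   complemented.
#' @param seed RNG seed (optional).
#' @return list with `scaffolds` (shuffled [Biostrings::DNAStringSet]),
#'   `layout` (data.frame in genome order: `name`, `genome_start`,
#'   `genome_end`, `length`, `orientation`, `gap_after`), and
#'   `adjacencies` (data.frame `left`, `right`, `gap`).
#' @export
fragment_genome <- function(genome, n_scaffolds, gap_range = c(0, 3000),
                            min_scaffold = 30000, revcomp_prob = 0.5,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(genome)
  n <- as.integer(n_scaffolds)
  stopifnot(n >= 1L)
  gaps <- if (n > 1L)
    sample(seq(gap_range[1L], gap_range[2L]), n - 1L, replace = TRUE)
  else integer()
  total_scaffold <- L - sum(gaps)
  if (total_scaffold < n * min_scaffold)
    stop("genome too short for requested scaffold count and minimum length")
  extra <- total_scaffold - n * min_scaffold
  w <- as.vector(stats::rmultinom(1L, extra, rep(1 / n, n)))
  lens <- min_scaffold + w
  starts <- cumsum(c(1, head(lens, -1L) + gaps))
  ends <- starts + lens - 1L
  ori <- ifelse(runif(n) < revcomp_prob, "-", "+")
  name <- sprintf("scaffold_%03d", seq_len(n))
  layout <- data.frame(name = name, genome_start = starts,
                       genome_end = ends, length = lens, orientation = ori,
                       gap_after = c(gaps, NA), stringsAsFactors = FALSE)
  seqs <- lapply(seq_len(n), function(i) {
    s <- Biostrings::subseq(genome, starts[i], ends[i])
    if (ori[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  })
  ord <- sample(n)
  scaffolds <- Biostrings::DNAStringSet(
    stats::setNames(unlist(seqs)[ord], name[ord]))
  adjacencies <- if (n > 1L)
    data.frame(left = name[-n], right = name[-1L], gap = gaps,
               stringsAsFactors = FALSE)
  else data.frame(left = character(), right = character(), gap = integer())
  list(scaffolds = scaffolds, layout = layout, adjacencies = adjacencies)
}

# Optical-map noise on one window's label list: multiplicative interval
# sizing error, binomial dropout, Poisson false labels. Positions are
# reported to 0.1 bp like the native formats.
perturb_labels <- function(rel_pos, window_length, sizing_sd = 0,
                           dropout = 0, false_per_100kb = 0) {
  pos <- rel_pos
  if (sizing_sd > 0 && length(pos)) {
    d <- diff(c(0, pos))
    d <- d * pmax(0.1, 1 + rnorm(length(d), 0, sizing_sd))
    pos <- cumsum(d)
  }
  if (dropout > 0 && length(pos))
    pos <- pos[runif(length(pos)) >= dropout]
  if (false_per_100kb > 0) {
    n_false <- rpois(1L, false_per_100kb * window_length / 1e5)
    pos <- c(pos, runif(n_false, 1, window_length))
  }
  pos <- sort(round(pos, 1))
  pos[pos >= 0.1 & pos <= window_length]
}

#' Simulate consensus genome maps over a fragmented genome
#'
#' Windows tile the genome; each becomes one consensus map whose labels
#' are the true digestion of the covered interval perturbed by sizing
#' noise, dropout and false labels. Window boundaries are placed *inside*
#' scaffolds (at `cut_frac` of the containing scaffold) so that every
#' true adjacency is interior to a window and boundary scaffolds straddle
#' two maps -- the geometry that makes iterative stitching informative.
#'
#' @param genome a [Biostrings::DNAString].
#' @param layout truth layout from [fragment_genome()].
#' @param motifs recognition motifs (as in [digest_config()]).
#' @param n_maps number of consensus maps (windows).
#' @param sizing_sd multiplicative interval noise sd (e.g. 0.02).
#' @param dropout per-label dropout probability (e.g. 0.10).
#' @param false_per_100kb false-label rate per 100 kb (e.g. 1).
#' @param cut_frac fraction of the boundary scaffold's *label sites* left
#'   of the cut. Cutting at a label-count quantile (rather than a bp
#'   fraction) guarantees both map portions of the straddling scaffold
#'   carry enough labels to be alignable.
#' @param seed RNG seed (optional).
#' @return list with `maps` (a [cmap_set()]) and `truth` (data.frame
#'   `cmap_id`, `genome_start`, `genome_end`).
#' @export
simulate_consensus_maps <- function(genome, layout,
                                    motifs = digest_config()$motifs,
                                    n_maps = 2, sizing_sd = 0, dropout = 0,
                                    false_per_100kb = 0, cut_frac = 0.6,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(genome)
  sites <- sort(unique(unlist(lapply(motifs, function(m)
    find_label_sites(genome, m)))))
  cuts <- integer()
  if (n_maps > 1L) {
    targets <- round(seq_len(n_maps - 1L) * L / n_maps)
    big <- layout[layout$length >= 50000, , drop = FALSE]
    # the straddling scaffold must be alignable on both sides of the cut,
    # so prefer scaffolds carrying at least 20 label sites
    nlab <- vapply(seq_len(nrow(big)), function(i)
      sum(sites > big$genome_start[i] & sites < big$genome_end[i]),
      integer(1))
    if (any(nlab >= 20L)) big <- big[nlab >= 20L, , drop = FALSE]
    cuts <- vapply(targets, function(t) {
      mid <- (big$genome_start + big$genome_end) / 2
      s <- big[which.min(abs(mid - t)), ]
      inside <- sites[sites > s$genome_start & sites < s$genome_end]
      if (length(inside) >= 4L) {
        # cut between labels at the cut_frac quantile of the site list
        k <- max(1L, min(length(inside) - 1L,
                         round(cut_frac * length(inside))))
        as.integer(round((inside[k] + inside[k + 1L]) / 2))
      } else {
        as.integer(s$genome_start + round(cut_frac * s$length))
      }
    }, integer(1))
    cuts <- sort(unique(cuts))
  }
  bounds <- c(0L, cuts, L)
  maps <- list()
  truth <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    ws <- bounds[k] + 1L
    we <- bounds[k + 1L]
    wlen <- we - ws + 1L
    rel <- sites[sites >= ws & sites <= we] - ws + 1L
    pos <- perturb_labels(rel, wlen, sizing_sd, dropout, false_per_100kb)
    maps[[k]] <- consensus_map_from_positions(k, wlen, pos)
    truth[[k]] <- data.frame(cmap_id = k, genome_start = ws,
                             genome_end = we)
  }
  list(maps = cmap_set(maps), truth = do.call(rbind, truth))
}

#' Ground-truth alignments of consensus maps to in silico maps
#'
#' Emits the exact alignments implied by provenance: one record per
#' (consensus window, scaffold) pair whose genome intervals overlap with
#' at least `min_labels` in silico label sites in the overlap. Reference
#' is the in silico map, query the consensus map, matching the external
#' aligner's convention. The confidence is the matched-label count -- a
#' documented stand-in proxy, not an aligner's -log10 p-value.
#'
#' @param consensus consensus-map simulation result from
#'   [simulate_consensus_maps()] (`maps` + `truth`).
#' @param insilico in silico digestion of the scaffold set (list with
#'   `maps` and `key`, from [digest_fasta()]).
#' @param layout truth layout from [fragment_genome()].
#' @param min_labels minimum in silico sites in the overlap.
#' @return an `xmap` (normalized in-memory convention).
#' @export
truth_xmap <- function(consensus, insilico, layout, min_labels = 2L) {
  key <- insilico$key
  id_of <- stats::setNames(key$CompntId, key$CompntName)
  rows <- list()
  for (w in seq_len(nrow(consensus$truth))) {
    tw <- consensus$truth[w, ]
    wlen <- cmap_lengths(consensus$maps)[[as.character(tw$cmap_id)]]
    for (s in seq_len(nrow(layout))) {
      sc <- layout[s, ]
      if (!sc$name %in% names(id_of)) next
      a <- max(tw$genome_start, sc$genome_start)
      b <- min(tw$genome_end, sc$genome_end)
      if (b <= a) next
      rid <- id_of[[sc$name]]
      if (sc$orientation == "+") {
        rs <- a - sc$genome_start + 1; re <- b - sc$genome_start + 1
      } else {
        rs <- sc$genome_end - b + 1; re <- sc$genome_end - a + 1
      }
      imap <- insilico$maps[[as.character(rid)]]
      conf <- sum(imap$sites$position >= rs & imap$sites$position <= re)
      if (conf < min_labels) next
      rows[[length(rows) + 1L]] <- data.frame(
        entry_id = 0L, qry_id = tw$cmap_id, ref_id = rid,
        qry_start = a - tw$genome_start + 1,
        qry_end = b - tw$genome_start + 1,
        ref_start = rs, ref_end = re, orientation = sc$orientation,
        confidence = conf, qry_len = wlen, ref_len = sc$length,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_xmap())
  x <- do.call(rbind, rows)
  x <- x[order(x$qry_id, x$ref_id), , drop = FALSE]
  x$entry_id <- seq_len(nrow(x))
  as_xmap(x)
}

#' Simulate BNX molecules with per-scan stretch
#'
#' Molecules are sampled from within scaffolds, their label positions
#' taken from the in silico sites, perturbed by interval sizing noise and
#' multiplied by the scan's stretch factor (bpp / 500). A ground-truth
#' molecule-to-in-silico-map XMAP accompanies the BNX so the stretch
#' estimator can be exercised without an external aligner.
#'
#' @param insilico in silico digestion of the scaffold set (`maps` +
#'   `key`).
#' @param scans data.frame with columns `flowcell_id`, `scan_id`,
#'   `stretch`, `n_molecules`.
#' @param mol_length_range molecule length range (bp).
#' @param sizing_sd multiplicative interval noise sd.
#' @param seed RNG seed (optional).
#' @return list with `molecules` (a [bnx_set()]) and `alignments`
#'   (`xmap`, molecules as query vs in silico maps as reference).
#' @export
simulate_molecules <- function(insilico, scans,
                               mol_length_range = c(150000, 250000),
                               sizing_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  key <- insilico$key
  mols <- list()
  rows <- list()
  mol_id <- 0L
  for (i in seq_len(nrow(scans))) {
    sc <- scans[i, ]
    for (j in seq_len(sc$n_molecules)) {
      len <- runif(1, mol_length_range[1L], mol_length_range[2L])
      ok <- key[key$CompntLength > len + 2, , drop = FALSE]
      if (nrow(ok) == 0L) stop("no scaffold long enough for a molecule")
      pick <- ok[sample.int(nrow(ok), 1L, prob = ok$CompntLength), ]
      start <- runif(1, 1, pick$CompntLength - len)
      imap <- insilico$maps[[as.character(pick$CompntId)]]
      inside <- imap$sites$position[imap$sites$position >= start &
                                      imap$sites$position <= start + len]
      true_rel <- inside - start
      noisy <- true_rel
      if (sizing_sd > 0 && length(noisy)) {
        d <- diff(c(0, noisy))
        d <- d * pmax(0.1, 1 + rnorm(length(d), 0, sizing_sd))
        noisy <- cumsum(d)
      }
      stretched <- round(noisy * sc$stretch, 1)
      mol_len <- round(len * sc$stretch, 1)
      # a label pushed outside the molecule by noise disappears on both
      # the molecule and the truth-alignment side
      keep <- which(stretched >= 0.1 & stretched <= mol_len &
                      !duplicated(stretched))
      stretched <- stretched[keep]
      true_kept <- true_rel[keep]
      mol_id <- mol_id + 1L
      mols[[mol_id]] <- molecule_map(mol_id, mol_len, stretched,
                                     scan_id = sc$scan_id,
                                     flowcell_id = sc$flowcell_id)
      if (length(stretched) >= 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          entry_id = 0L, qry_id = mol_id, ref_id = pick$CompntId,
          qry_start = stretched[1L], qry_end = stretched[length(stretched)],
          ref_start = round(true_kept[1L] + start, 1),
          ref_end = round(true_kept[length(true_kept)] + start, 1),
          orientation = "+", confidence = length(stretched),
          qry_len = mol_len, ref_len = pick$CompntLength,
          stringsAsFactors = FALSE)
      }
    }
  }
  aln <- if (length(rows)) {
    x <- do.call(rbind, rows)
    x$entry_id <- seq_len(nrow(x))
    as_xmap(x)
  } else empty_xmap()
  list(molecules = bnx_set(mols), alignments = aln)
}

#' Naive overlap alignment of two label maps
#'
#' Desk-scale stand-in for an external map aligner, intended for tests and
#' demonstrations only. Candidate offsets are voted by binned pairwise
#' label differences; for each leading offset the labels are paired
#' greedily within `tol`, in both orientations, and the maximal-match
#' alignment is reported with the matched-label count as its confidence
#' proxy.
#'
#' @param ref_map,qry_map [consensus_map()] objects (>= 2 labels each).
#' @param tol label pairing tolerance (bp); of the order of the expected
#'   sizing error, and much smaller than the typical label spacing so that
#'   chance pairings stay rare.
#' @param min_matches minimum matched labels to report an alignment.
#' @param min_density minimum fraction of each map's labels inside the
#'   aligned span that must be matched. A genuine overlap pairs nearly all
#'   spanned labels, whereas chance chains pair roughly `2 * tol /
#'   spacing` of them, so this rejects sparse spurious chains.
#' @return one-row `xmap` data.frame, or `NULL` if no alignment reaches
#'   the thresholds.
#' @export
naive_overlap_align <- function(ref_map, qry_map, tol = 50,
                                min_matches = 8L, min_density = 0.5) {
  rpos <- ref_map$sites$position
  qpos <- qry_map$sites$position
  if (length(rpos) < 2L || length(qpos) < 2L) return(NULL)
  greedy <- function(rp, qp, off) {
    i <- 1L; j <- 1L
    mi <- integer(); mj <- integer()
    while (i <= length(rp) && j <= length(qp)) {
      d <- rp[i] - (qp[j] + off)
      if (abs(d) <= tol) {
        mi <- c(mi, i); mj <- c(mj, j); i <- i + 1L; j <- j + 1L
      } else if (d > 0) j <- j + 1L else i <- i + 1L
    }
    list(mi = mi, mj = mj)
  }
  best <- NULL
  for (ori in c("+", "-")) {
    qp <- if (ori == "+") qpos else
      sort(qry_map$contig_length - qpos)
    nr <- length(rpos)
    d <- as.vector(outer(rpos, qp, "-"))
    bins <- round(d / (2 * tol))
    idx_by_bin <- split(seq_along(d), bins)
    cnt <- lengths(idx_by_bin)
    vals <- as.integer(names(idx_by_bin))
    # matches reachable from a bin's offset are bounded by the count in
    # the bin and its neighbours; screen candidates best-bound first and
    # reject sparse chains from label indices before running the greedy
    # pairing (pairs in a dense chain occupy consecutive sorted labels)
    nb <- function(v) { x <- cnt[match(v, vals)]; x[is.na(x)] <- 0L; x }
    bound <- nb(vals - 1L) + cnt + nb(vals + 1L)
    for (k in order(bound, decreasing = TRUE)) {
      if (bound[k] < min_matches) break
      if (!is.null(best) && bound[k] <= best$n) break
      own <- idx_by_bin[[k]]
      cand <- c(idx_by_bin[[as.character(vals[k] - 1L)]], own,
                idx_by_bin[[as.character(vals[k] + 1L)]])
      sel <- cand[abs(d[cand] - vals[k] * 2 * tol) <= 2 * tol]
      ri <- unique((sel - 1L) %% nr + 1L)
      qi <- unique((sel - 1L) %/% nr + 1L)
      ub <- min(length(ri), length(qi))
      if (ub < min_matches) next
      if (!is.null(best) && ub <= best$n) next
      if (ub / max(diff(range(ri)) + 1L, diff(range(qi)) + 1L) <
          min_density) next
      g <- greedy(rpos, qp, stats::median(d[own]))
      n <- length(g$mi)
      if (n < min_matches) next
      span_r <- sum(rpos >= rpos[g$mi[1L]] & rpos <= rpos[g$mi[n]])
      span_q <- sum(qp >= qp[g$mj[1L]] & qp <= qp[g$mj[n]])
      if (n / max(span_r, span_q) < min_density) next
      if (is.null(best) || n > best$n)
        best <- list(n = n, ori = ori, mi = g$mi, mj = g$mj, qp = qp)
    }
  }
  if (is.null(best)) return(NULL)
  q_matched <- if (best$ori == "+") best$qp[best$mj] else
    qry_map$contig_length - best$qp[best$mj]
  as_xmap(data.frame(
    entry_id = 1L, qry_id = qry_map$cmap_id, ref_id = ref_map$cmap_id,
    qry_start = min(q_matched), qry_end = max(q_matched),
    ref_start = rpos[min(best$mi)], ref_end = rpos[max(best$mi)],
    orientation = best$ori, confidence = best$n,
    qry_len = qry_map$contig_length, ref_len = ref_map$contig_length,
    stringsAsFactors = FALSE))
}

#' Build an aligner function from the naive overlap aligner
#'
#' Returns a function with the `(insilico_maps, consensus_maps) -> xmap`
#' signature expected by [run_iterations()], aligning every consensus map
#' against every in silico map and keeping the per-pair best alignments.
#'
#' @param tol label pairing tolerance (bp).
#' @param min_matches minimum matched labels per reported alignment.
#' @param min_density minimum matched fraction of spanned labels (see
#'   [naive_overlap_align()]).
#' @return an aligner function.
#' @export
naive_aligner <- function(tol = 50, min_matches = 8L, min_density = 0.5) {
  function(insilico_maps, consensus_maps) {
    rows <- list()
    for (r in insilico_maps) {
      for (q in consensus_maps) {
        a <- naive_overlap_align(r, q, tol = tol,
                                 min_matches = min_matches,
                                 min_density = min_density)
        if (!is.null(a)) rows[[length(rows) + 1L]] <- as.data.frame(a)
      }
    }
    if (!length(rows)) return(empty_xmap())
    x <- do.call(rbind, rows)
    x <- x[order(x$qry_id, x$ref_id), , drop = FALSE]
    x$entry_id <- seq_len(nrow(x))
    as_xmap(x)
  }
}

#' Fraction of true adjacencies recovered by a stitched assembly
#'
#' A true adjacency (consecutive scaffolds in the genome) is recovered
#' when its two scaffolds are adjacent components of one AGP object, in
#' either object orientation, with the correct relative orientation after
#' composing each component's placement with its stored orientation.
#'
#' @param agp flattened `agp` over original scaffolds.
#' @param layout truth layout from [fragment_genome()].
#' @return list with `recovered`, `total`, `fraction`, and per-adjacency
#'   `details`.
#' @export
adjacency_recovery <- function(agp, layout) {
  ori_of <- stats::setNames(layout$orientation, layout$name)
  genome_strand <- function(name, placed) {
    if (placed == ori_of[[name]]) "+" else "-"
  }
  pairs <- list()
  for (obj in unique(agp$object_id)) {
    g <- agp[agp$object_id == obj & agp$component_type == "W", ,
             drop = FALSE]
    g <- g[order(g$part_number), , drop = FALSE]
    if (nrow(g) < 2L) next
    for (i in seq_len(nrow(g) - 1L)) {
      pairs[[length(pairs) + 1L]] <- c(
        g$component_id[i], g$component_id[i + 1L],
        genome_strand(g$component_id[i], g$orientation[i]),
        genome_strand(g$component_id[i + 1L], g$orientation[i + 1L]))
    }
  }
  n <- nrow(layout)
  if (n < 2L)
    return(list(recovered = 0L, total = 0L, fraction = NA_real_,
                details = NULL))
  details <- data.frame(left = layout$name[-n], right = layout$name[-1L],
                        recovered = FALSE, stringsAsFactors = FALSE)
  for (p in pairs) {
    fwd <- details$left == p[1L] & details$right == p[2L] &
      p[3L] == "+" & p[4L] == "+"
    rev <- details$left == p[2L] & details$right == p[1L] &
      p[3L] == "-" & p[4L] == "-"
    details$recovered <- details$recovered | fwd | rev
  }
  list(recovered = sum(details$recovered), total = nrow(details),
       fraction = mean(details$recovered), details = details)
}
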