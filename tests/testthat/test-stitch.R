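# A hand-built scaffolding scenario: three consensus maps, seven scaffolds.
# On consensus map 1, A and B join with a +4500 bp gap and E only has an
# interior local hit; on map 2, C (reverse) and D join with a -500 bp gap;
# on map 3, F and G overlap by 24 kb (an extreme negative gap).
stitch_fixture <- function() {
  set.seed(801)
  lens <- c(A = 20000, B = 15000, C = 12000, D = 10000, E = 8000,
            F = 30000, G = 28000)
  scaffolds <- Biostrings::DNAStringSet(vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    ""))
  key <- data.frame(CompntId = seq_along(lens), CompntName = names(lens),
                    CompntLength = unname(lens), stringsAsFactors = FALSE)
  aln <- stitchmap:::as_xmap(data.frame(
    entry_id = 1:7,
    ref_id  = c(1L, 2L, 2L, 3L, 4L, 6L, 7L),      # in silico map (scaffold)
    qry_id  = c(1L, 1L, 2L, 2L, 2L, 3L, 3L),      # consensus map
    ref_start = c(0, 0, 0, 0, 0, 0, 0),
    ref_end = c(20000, 15000, 8000, 12000, 10000, 30000, 28000),
    qry_start = c(0, 24500, 100, 20000, 31500, 0, 6000),
    qry_end = c(20000, 39500, 8100, 32000, 41500, 30000, 34000),
    orientation = c("+", "+", "+", "-", "+", "+", "+"),
    confidence = c(20, 18, 13, 15, 9, 20, 20),
    qry_len = c(60000, 60000, 50000, 50000, 50000, 40000, 40000),
    ref_len = c(20000, 15000, 15000, 12000, 10000, 30000, 28000),
    stringsAsFactors = FALSE))
  list(scaffolds = scaffolds, key = key, alignments = aln)
}

test_that("invert_xmap swaps roles, keeps strand and is an involution", {
  x <- make_xmap_fixture()
  inv <- invert_xmap(x)
  expect_equal(inv$qry_id, x$ref_id)
  expect_equal(inv$ref_id[order(inv$entry_id)], x$qry_id)
  expect_equal(inv$ref_start[inv$entry_id == 1L], x$qry_start[1L])
  expect_equal(inv$qry_len, x$ref_len)
  expect_equal(inv$orientation[order(inv$entry_id)], x$orientation)
  expect_equal(inv$alignment[inv$entry_id == 2L], "(4,3)(3,4)")

  twice <- invert_xmap(inv)
  twice <- twice[order(twice$entry_id), ]
  rownames(twice) <- NULL
  expect_equal(as.data.frame(twice), as.data.frame(x))

  # the on-disk "-" convention reappears on the new query side after write
  path <- withr::local_tempfile(fileext = ".xmap")
  write_xmap(inv, path)
  f <- strsplit(grep("^#", readLines(path), invert = TRUE,
                     value = TRUE), "\t")
  neg <- f[[which(vapply(f, `[`, "", 8L) == "-")]]
  expect_gt(as.numeric(neg[4L]), as.numeric(neg[5L]))

  x$ref_len <- NA_real_
  expect_error(invert_xmap(x), "ref_len")
})

test_that("percent_aligned implements overlap-limited geometry", {
  row <- function(rs, re, qs, qe, ql, rl, ori = "+") stitchmap:::as_xmap(
    data.frame(entry_id = 1L, qry_id = 1L, ref_id = 1L, qry_start = qs,
               qry_end = qe, ref_start = rs, ref_end = re,
               orientation = ori, confidence = 1, qry_len = ql,
               ref_len = rl, stringsAsFactors = FALSE))
  # end overlap: no opposing overhangs on either side
  expect_equal(percent_aligned(row(800, 1000, 0, 200, 500, 1000)), 100)
  # query contained in reference
  expect_equal(percent_aligned(row(400, 900, 0, 500, 500, 1000)), 100)
  # interior local hit: 200 / (200 + 400 + 400)
  expect_equal(percent_aligned(row(400, 600, 400, 600, 1000, 1000)), 20)
  expect_error(percent_aligned(row(400, 400, 400, 600, 1000, 1000)),
               "zero-length")
})

test_that("PAT stays in (0, 100] over simulated alignments", {
  sc <- make_scenario(81, genome_length = 8e5, n_scaffolds = 6)
  pat <- percent_aligned(invert_xmap(sc$truth))
  expect_true(all(pat > 0 & pat <= 100))
})

test_that("alignment filtering is an inclusive union over filter sets", {
  mk <- function(conf, pat_target) {
    # containment span scaled to yield the requested PAT exactly
    aligned <- 1000
    over <- aligned * (100 - pat_target) / pat_target / 2
    stitchmap:::as_xmap(data.frame(
      entry_id = 1L, qry_id = 1L, ref_id = 1L,
      qry_start = over, qry_end = over + aligned,
      ref_start = over, ref_end = over + aligned, orientation = "+",
      confidence = conf, qry_len = 2 * over + aligned,
      ref_len = 2 * over + aligned, stringsAsFactors = FALSE))
  }
  sets <- stitch_config()$filter_sets
  expect_equal(nrow(filter_alignments(mk(10, 95), sets)), 1L)  # set 2 only
  expect_equal(nrow(filter_alignments(mk(14, 25), sets)), 0L)  # fails both
  expect_equal(nrow(filter_alignments(mk(13, 30), sets)), 1L)  # boundaries
  expect_equal(nrow(filter_alignments(mk(8, 90), sets)), 1L)

  # keeping either set alone yields a subset of the union
  both <- fx_aln <- stitch_fixture()$alignments
  inv <- invert_xmap(fx_aln)
  u <- filter_alignments(inv, sets)
  for (s in sets) {
    alone <- filter_alignments(inv, list(s))
    expect_true(all(alone$entry_id %in% u$entry_id))
  }
})

test_that("selection keeps one alignment per in silico map, deterministically", {
  fx <- stitch_fixture()
  passing <- filter_alignments(invert_xmap(fx$alignments))
  chosen <- select_scaffolding_alignments(passing)
  # scaffold B aligns to consensus 1 (15 kb) and 2 (8 kb): longest wins
  expect_equal(chosen$ref_id[chosen$qry_id == 2L], 1L)
  expect_equal(sum(chosen$qry_id == 2L), 1L)

  # equal spans: highest confidence wins
  tie <- stitchmap:::as_xmap(data.frame(
    entry_id = 1:4, qry_id = c(1L, 1L, 2L, 2L), ref_id = c(1L, 2L, 1L, 2L),
    qry_start = 0, qry_end = 1000, ref_start = 0, ref_end = 1000,
    orientation = "+", confidence = c(15, 12, 11, 11), qry_len = 1000,
    ref_len = 1000, stringsAsFactors = FALSE))
  tie$pat <- percent_aligned(tie)
  ch <- select_scaffolding_alignments(tie)
  expect_equal(ch$ref_id[ch$qry_id == 1L], 1L)
  # equal spans and confidences: smallest consensus id (repeatable)
  expect_equal(ch$ref_id[ch$qry_id == 2L], 1L)
  expect_identical(ch$entry_id, select_scaffolding_alignments(tie)$entry_id)

  # a consensus map attracting a single in silico map yields no candidates
  solo <- tie[tie$entry_id == 1L, ]
  expect_equal(nrow(select_scaffolding_alignments(solo)), 0L)
})

test_that("gap inference orders by projected span and signs gaps", {
  comp <- data.frame(
    entry_id = 1:2, qry_id = 1:2, ref_id = 7L,
    ref_start = c(100, 300), ref_end = c(240, 490),
    orientation = "+", confidence = 10,
    qry_start = c(0, 10), qry_end = c(140, 200),
    qry_len = c(150, 200), ref_len = 1000)
  comp <- stitchmap:::with_projection(comp)
  parts <- infer_gaps(comp)
  expect_equal(parts$components$qry_id, 1:2)
  expect_equal(parts$gaps, 40)   # proj end 250, proj start 290

  touching <- comp
  touching$proj_start[2L] <- touching$proj_end[1L]
  expect_equal(infer_gaps(touching)$gaps, 0)

  overlapping <- comp
  overlapping$proj_start[2L] <- 200
  expect_lt(infer_gaps(overlapping)$gaps, 0)
})

test_that("stitch_once reproduces the drawn join geometry", {
  fx <- stitch_fixture()
  res <- stitch_once(fx$scaffolds, invert_xmap(fx$alignments), fx$key,
                     stitch_config())
  expect_equal(res$n_new_joins, 3L)
  expect_length(res$plans, 3L)

  # consensus 1: A + 4500 N + B
  s1 <- res$fasta[["Super_scaffold_1"]]
  expect_equal(length(s1), 20000 + 4500 + 15000)
  expect_equal(as.character(Biostrings::subseq(s1, 20001, 24500)),
               strrep("N", 4500))
  expect_equal(as.character(Biostrings::subseq(s1, 1, 20000)),
               as.character(fx$scaffolds[["A"]]))

  # consensus 2: revcomp(C) + 100 N spacer + D (negative gap)
  s2 <- res$fasta[["Super_scaffold_2"]]
  expect_equal(length(s2), 12000 + 100 + 10000)
  expect_equal(as.character(Biostrings::subseq(s2, 1, 12000)),
               as.character(Biostrings::reverseComplement(
                 fx$scaffolds[["C"]])))
  u <- res$agp[res$agp$object_id == "Super_scaffold_2" &
                 res$agp$component_type != "W", ]
  expect_equal(u$component_type, "U")
  expect_equal(u$gap_length, 100L)

  # E passed filtering nowhere; it flows through unchanged
  expect_equal(as.character(res$fasta[["E"]]),
               as.character(fx$scaffolds[["E"]]))

  # flags: the 53% partial alignment and the -24 kb gap
  expect_equal(res$flags$qry_id[res$flags$flag == "partial_alignment"], 2L)
  neg <- res$flags[res$flags$flag == "extreme_negative_gap", ]
  expect_equal(neg$value, -24000)
  expect_setequal(c(neg$qry_id, neg$partner_qry_id), c(6L, 7L))
  # ... but the flagged join still proceeds by default
  expect_true("Super_scaffold_3" %in% names(res$fasta))

  # joins log records the consensus map and the gap estimate
  expect_equal(sort(res$joins$gap_estimate), c(-24000, -500, 4500))

  # joins add only N's: the non-N base count is conserved
  nonN <- function(x)
    sum(Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T")])
  expect_equal(nonN(res$fasta), nonN(fx$scaffolds))

  # AGP + input scaffolds reconstruct the emitted FASTA byte for byte
  rebuilt <- agp_to_fasta(res$agp, fx$scaffolds)
  expect_identical(as.character(rebuilt[names(res$fasta)]),
                   as.character(res$fasta))

  # no in silico map is used twice
  used <- unlist(lapply(res$plans, function(p) p$components$component_id))
  expect_false(anyDuplicated(used) > 0L)
})

test_that("minimum negative gap exclusion drops both flanking maps", {
  fx <- stitch_fixture()
  cfg <- stitch_config(min_negative_gap_exclusion = -20000)
  res <- stitch_once(fx$scaffolds, invert_xmap(fx$alignments), fx$key, cfg)
  # the F/G join (gap -24 kb) is excluded; A/B and C/D survive
  expect_equal(res$n_new_joins, 2L)
  expect_true(all(c("F", "G") %in% names(res$fasta)))
  excl <- res$flags[res$flags$flag == "negative_gap_exclusion", ]
  expect_setequal(excl$qry_id, c(6L, 7L))
  # a -5 kb gap is neither flagged nor excluded
  expect_false(any(res$flags$value[res$flags$flag ==
                                     "extreme_negative_gap"] %in% -500))
})

test_that("stitch_once degenerate and error paths", {
  fx <- stitch_fixture()
  res <- stitch_once(fx$scaffolds, empty_xmap(), fx$key, stitch_config())
  expect_equal(res$n_new_joins, 0L)
  expect_identical(as.character(res$fasta), as.character(fx$scaffolds))
  expect_equal(names(res$fasta), names(fx$scaffolds))

  bad <- fx$alignments
  bad$ref_id[1L] <- 99L
  expect_error(stitch_once(fx$scaffolds, invert_xmap(bad), fx$key,
                           stitch_config()), "99")
})
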