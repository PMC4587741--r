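test_that("genome generation is seeded and composition-faithful", {
  expect_identical(as.character(make_genome(5000, 0.4, seed = 1001)),
                   as.character(make_genome(5000, 0.4, seed = 1001)))
  at_only <- make_genome(2000, 0, seed = 1002)
  expect_equal(sum(Biostrings::alphabetFrequency(at_only)[c("C", "G")]), 0)

  # BspQI motif density within +/- 30 % of the i.i.d. two-strand
  # expectation 2 * L * p(motif) at gc = 0.5
  g <- make_genome(3e6, 0.5, seed = 1003)
  expected <- 2 * length(g) * (1 / 4)^7
  observed <- length(find_label_sites(g, "GCTCTTC"))
  expect_gt(observed, 0.7 * expected)
  expect_lt(observed, 1.3 * expected)
})

test_that("fragmentation tiles the genome and records a usable truth", {
  g <- make_genome(5e5, 0.5, seed = 1011)
  one <- fragment_genome(g, 1, seed = 1012, revcomp_prob = 0)
  expect_identical(as.character(one$scaffolds[[1L]]), as.character(g))
  expect_equal(nrow(one$adjacencies), 0L)

  fr <- fragment_genome(g, 8, seed = 1013)
  expect_length(fr$scaffolds, 8L)
  expect_equal(nrow(fr$adjacencies), 7L)
  lay <- fr$layout
  expect_equal(lay$genome_start[1L], 1)
  expect_equal(lay$genome_end[nrow(lay)], length(g))
  expect_equal(lay$genome_start[-1L],
               head(lay$genome_end, -1L) + head(lay$gap_after, -1L) + 1)
  # each stored scaffold is the (oriented) genome interval
  for (i in seq_len(nrow(lay))) {
    s <- Biostrings::subseq(g, lay$genome_start[i], lay$genome_end[i])
    if (lay$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
    expect_identical(as.character(fr$scaffolds[[lay$name[i]]]),
                     as.character(s))
  }
  # zero-length true gaps are allowed
  fr0 <- fragment_genome(g, 5, gap_range = c(0, 0), seed = 1014)
  expect_true(all(fr0$adjacencies$gap == 0))
})

test_that("noise-free consensus maps equal the digestion of their window", {
  g <- make_genome(6e5, 0.5, seed = 1021)
  fr <- fragment_genome(g, 4, seed = 1022)
  cm <- simulate_consensus_maps(g, fr$layout, n_maps = 2, seed = 1023)
  sites <- sort(unique(unlist(lapply(digest_config()$motifs, function(m)
    find_label_sites(g, m)))))
  for (k in seq_len(nrow(cm$truth))) {
    tw <- cm$truth[k, ]
    expected <- sites[sites >= tw$genome_start & sites <= tw$genome_end] -
      tw$genome_start + 1L
    expect_equal(cm$maps[[k]]$sites$position, as.numeric(expected))
  }
})

test_that("label dropout thins at the binomial rate", {
  # dense two-base motif so the label count supports a tight check
  g <- make_genome(8e5, 0.5, seed = 1031)
  fr <- fragment_genome(g, 2, seed = 1032)
  clean <- simulate_consensus_maps(g, fr$layout, motifs = c(x = "GAT"),
                                   n_maps = 1, seed = 1033)
  n0 <- clean$maps[[1L]]$num_sites
  expect_gt(n0, 10000)
  noisy <- simulate_consensus_maps(g, fr$layout, motifs = c(x = "GAT"),
                                   n_maps = 1, dropout = 0.1, seed = 1034)
  retained <- noisy$maps[[1L]]$num_sites / n0
  expect_gt(retained, 0.89)
  expect_lt(retained, 0.91)
})

test_that("truth alignments reflect provenance, orientation and spanning", {
  sc <- make_scenario(1041, genome_length = 8e5, n_scaffolds = 6)
  tx <- sc$truth
  lay <- sc$fragments$layout
  id_of <- stats::setNames(sc$digest$key$CompntId, sc$digest$key$CompntName)

  # the cut scaffold spans both consensus maps: two records
  cut_end <- sc$consensus$truth$genome_end[1L]
  strad <- lay$name[lay$genome_start < cut_end & lay$genome_end > cut_end]
  expect_length(strad, 1L)
  expect_equal(sort(tx$qry_id[tx$ref_id == id_of[[strad]]]), c(1L, 2L))

  # orientation follows the stored scaffold orientation
  for (nm in lay$name[lay$name %in% names(id_of)]) {
    ori <- unique(tx$orientation[tx$ref_id == id_of[[nm]]])
    expect_equal(ori, lay$orientation[lay$name == nm])
  }

  # scaffolds fully inside one window align in full containment: PAT 100
  inv <- invert_xmap(tx)
  full <- inv[inv$qry_len == inv$ref_end - inv$ref_start, ]
  if (nrow(full)) expect_true(all(percent_aligned(full) == 100))
})

test_that("the naive overlap aligner recovers exact offsets", {
  # irregular spacing so that offsets and orientation are unambiguous
  set.seed(1050)
  pos <- round(cumsum(runif(25, 1500, 6500)), 1)
  m <- consensus_map_from_positions(1L, 1e5, pos)
  self <- naive_overlap_align(m, m)
  expect_equal(self$confidence, m$num_sites)
  expect_equal(self$orientation, "+")
  expect_equal(self$ref_start, pos[1L])
  expect_equal(self$ref_end, pos[length(pos)])

  # uniformly shifted copy: the offset is recovered exactly
  shift <- consensus_map_from_positions(2L, 1e5, pos - 1234)
  a <- naive_overlap_align(m, shift)
  expect_equal(a$confidence, m$num_sites)
  expect_equal(a$ref_start - a$qry_start, 1234)

  # mirrored copy aligns as "-" with all labels paired
  revd <- consensus_map_from_positions(3L, 1e5, sort(1e5 - pos))
  b <- naive_overlap_align(m, revd)
  expect_equal(b$orientation, "-")
  expect_equal(b$confidence, m$num_sites)

  # unrelated random maps fall below the acceptance floor
  set.seed(1051)
  r1 <- consensus_map_from_positions(4L, 1e5, sort(runif(25, 1, 1e5)))
  r2 <- consensus_map_from_positions(5L, 1e5, sort(runif(25, 1, 1e5)))
  expect_null(naive_overlap_align(r1, r2))
})

test_that("simulated molecules carry scan provenance and stretch", {
  g <- make_genome(6e5, 0.5, seed = 1061)
  fr <- fragment_genome(g, 3, seed = 1062)
  dig <- digest_fasta(fr$scaffolds)
  scans <- data.frame(flowcell_id = c("fc1", "fc2"), scan_id = c(1L, 1L),
                      stretch = c(1.02, 1.0), n_molecules = 10L)
  sim <- simulate_molecules(dig, scans, mol_length_range = c(4e4, 6e4),
                            seed = 1063)
  expect_length(sim$molecules, 20L)
  expect_setequal(unique(vapply(sim$molecules, `[[`, "", "flowcell_id")),
                  c("fc1", "fc2"))
  # noise-free: every alignment's span ratio is exactly 1 / stretch
  fc1_ids <- vapply(sim$molecules, `[[`, integer(1), "molecule_id")[
    vapply(sim$molecules, `[[`, "", "flowcell_id") == "fc1"]
  a <- sim$alignments[sim$alignments$qry_id %in% fc1_ids, ]
  ratio <- sum(a$ref_end - a$ref_start) / sum(a$qry_end - a$qry_start)
  expect_lt(abs(ratio - 1 / 1.02), 2e-4)
  # BNX round trip of simulator output is the identity
  path <- withr::local_tempfile(fileext = ".bnx")
  write_bnx(sim$molecules, path)
  back <- read_bnx(path)
  expect_equal(molecule_lengths(back), molecule_lengths(sim$molecules))
  expect_equal(lapply(back, `[[`, "label_positions"),
               lapply(sim$molecules, `[[`, "label_positions"))
})
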