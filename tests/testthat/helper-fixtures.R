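# Fixtures are built in code; nothing binary is stored.

# Two molecules with the documented lengths/label counts.
make_bnx_fixture <- function() {
  bnx_set(list(
    molecule_map(1L, 180000.0, c(20000, 55000, 90000, 120000, 166000),
                 scan_id = 1L, flowcell_id = "fc1",
                 extra_rows = "QX11\t0.5\t0.6"),
    molecule_map(2L, 210000.0,
                 c(9000, 31000, 64000, 101000, 140000, 171000, 205000),
                 scan_id = 2L, flowcell_id = "fc1")))
}

make_cmap_fixture <- function() {
  cmap_set(list(
    consensus_map_from_positions(1L, 150000, c(12000.5, 70000, 131000))))
}

# One "+" and one "-" record with known geometry.
make_xmap_fixture <- function() {
  as_plus <- data.frame(
    entry_id = 1L, qry_id = 10L, ref_id = 1L,
    qry_start = 1000, qry_end = 52000, ref_start = 20000, ref_end = 71500,
    orientation = "+", confidence = 15.21, hit_enum = "5M",
    qry_len = 60000, ref_len = 150000, label_channel = 1L,
    alignment = "(1,1)(2,2)", stringsAsFactors = FALSE)
  as_minus <- data.frame(
    entry_id = 2L, qry_id = 11L, ref_id = 1L,
    qry_start = 3000, qry_end = 47000, ref_start = 90000, ref_end = 134500,
    orientation = "-", confidence = 9.05, hit_enum = "4M",
    qry_len = 50000, ref_len = 150000, label_channel = 1L,
    alignment = "(3,4)(4,3)", stringsAsFactors = FALSE)
  stitchmap:::as_xmap(rbind(as_plus, as_minus))
}

# A sequence of harmless background with BspQI motifs planted at known
# 1-based positions (forward strand).
planted_sequence <- function(length, motif_positions,
                             motif = "GCTCTTC") {
  chars <- rep(c("A", "T"), length.out = length)
  for (p in motif_positions) {
    stopifnot(p + nchar(motif) - 1L <= length)
    chars[p:(p + nchar(motif) - 1L)] <- strsplit(motif, "")[[1L]]
  }
  paste(chars, collapse = "")
}

# Brute-force oracles, independent of the implementation under test.
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  best <- NA_real_
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= total / 2) { best <- L; break }
  }
  best
}

find_sites_oracle <- function(sequence, motif) {
  seq_chars <- toupper(sequence)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  hits <- integer()
  m <- nchar(motif)
  for (i in seq_len(nchar(seq_chars) - m + 1L)) {
    w <- substr(seq_chars, i, i + m - 1L)
    if (w == motif || (rc != motif && w == rc)) hits <- c(hits, i)
  }
  hits
}

# Small stitched-genome scenario shared by several tests: two consensus
# windows cut inside one scaffold, noise optional.
make_scenario <- function(seed, genome_length = 2e6, n_scaffolds = 16,
                          n_maps = 2, gc = 0.5, ...) {
  g <- make_genome(genome_length, gc, seed = seed)
  fr <- fragment_genome(g, n_scaffolds, seed = seed + 1L)
  dig <- digest_fasta(fr$scaffolds)
  cm <- simulate_consensus_maps(g, fr$layout, n_maps = n_maps,
                                seed = seed + 2L, ...)
  list(genome = g, fragments = fr, digest = dig, consensus = cm,
       truth = truth_xmap(cm, dig, fr$layout))
}

# A passing-alignment table with no rows (pat column attached).
empty_pass <- function() {
  x <- as.data.frame(empty_xmap())
  x$pat <- numeric()
  x
}

# Filter sets scaled to the simulator's matched-label-count confidence
# proxy (the shape of the default confidence/PAT pairing, on the proxy
# scale).
sim_stitch_config <- function(...) {
  stitch_config(filter_sets = list(c(8, 30), c(4, 90)), ...)
}
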