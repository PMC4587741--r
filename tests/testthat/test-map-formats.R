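test_that("BNX reading handles empty, fixture and malformed input", {
  path <- withr::local_tempfile(fileext = ".bnx")

  writeLines(c("# BNX File Version:\t1.2", "# Label Channels:\t1"), path)
  expect_length(read_bnx(path), 0L)

  writeLines("# no version here", path)
  expect_error(read_bnx(path), "BNX 1.x")

  write_bnx(make_bnx_fixture(), path)
  got <- read_bnx(path)
  expect_length(got, 2L)
  expect_equal(molecule_lengths(got), c(180000, 210000))
  expect_equal(lengths(lapply(got, `[[`, "label_positions")), c(5L, 7L))

  # a 1 line with no preceding 0 header names its line number
  writeLines(c("# BNX File Version:\t1.2", "1\t100.0\t200.0"), path)
  expect_error(read_bnx(path), "line 2")

  writeLines(c("# BNX File Version:\t1.2",
               "0\t1\t1000.0", "1\t10.0\tnope\t1000.0"), path)
  expect_error(read_bnx(path), "non-numeric")
})

test_that("BNX round trip preserves every field", {
  path <- withr::local_tempfile(fileext = ".bnx")
  mols <- make_bnx_fixture()
  write_bnx(mols, path)
  back <- read_bnx(write_bnx(read_bnx(path), path))
  for (i in seq_along(mols)) {
    for (f in c("molecule_id", "length", "label_positions", "scan_id",
                "flowcell_id", "extra_rows"))
      expect_equal(back[[i]][[f]], mols[[i]][[f]], info = f)
  }
  # the 1 line ends with the molecule length, per convention
  one_lines <- grep("^1\t", readLines(path), value = TRUE)
  last_field <- vapply(strsplit(one_lines, "\t"), function(x)
    as.numeric(x[length(x)]), numeric(1))
  expect_equal(last_field, molecule_lengths(mols))
})

test_that("BNX writer refuses molecules violating invariants", {
  m <- make_bnx_fixture()
  bad <- unclass(m)
  bad[[1L]]$label_positions <- c(10, 200001)  # beyond length
  path <- withr::local_tempfile(fileext = ".bnx")
  expect_error(write_bnx(bad, path), "molecule 1")
  expect_error(molecule_map(3L, 1000, c(50, 40)), "ascending")
  expect_error(molecule_map(3L, 0, numeric()), "length")
})

test_that("CMAP read/write round-trips and checks site counts", {
  path <- withr::local_tempfile(fileext = ".cmap")
  maps <- make_cmap_fixture()
  write_cmap(maps, path)
  got <- read_cmap(path)
  expect_length(got, 1L)
  expect_equal(got[[1L]]$num_sites, 3L)
  expect_equal(got[[1L]]$sites$position, c(12000.5, 70000, 131000))
  expect_equal(got[[1L]]$contig_length, 150000)

  # the end marker is on disk at the contig length
  rows <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  last <- strsplit(rows[length(rows)], "\t")[[1L]]
  expect_equal(as.integer(last[5L]), 0L)           # channel 0
  expect_equal(as.numeric(last[6L]), 150000)       # at contig length

  # single site row without the end marker: tolerated with a warning
  writeLines("5\t1000.0\t1\t1\t1\t500.0\t0.0\t1\t1", path)
  expect_warning(single <- read_cmap(path), "end marker")
  expect_equal(single[[1L]]$num_sites, 1L)
  expect_error({
    writeLines(c(rows[1:2]), path)  # NumSites says 3, two site rows
    suppressWarnings(read_cmap(path))
  }, "NumSites")

  writeLines("# CMAP File Version:\t0.1", path)
  expect_length(read_cmap(path), 0L)
})

test_that("CMAP round trip is the identity on simulator output at scale", {
  sc <- make_scenario(61, genome_length = 5e5, n_scaffolds = 4)
  path <- withr::local_tempfile(fileext = ".cmap")
  maps <- c(unclass(sc$digest$maps), unclass(sc$consensus$maps))
  maps <- cmap_set(lapply(seq_along(maps), function(i) {
    m <- maps[[i]]; m$cmap_id <- i
    consensus_map(i, m$contig_length, m$sites)
  }))
  write_cmap(maps, path)
  back <- read_cmap(path)
  expect_length(back, length(maps))
  for (i in seq_along(maps)) {
    expect_equal(back[[i]]$contig_length, maps[[i]]$contig_length)
    expect_equal(back[[i]]$sites$position, maps[[i]]$sites$position)
  }
})

test_that("XMAP parsing normalizes strand convention and validates input", {
  path <- withr::local_tempfile(fileext = ".xmap")
  x <- make_xmap_fixture()
  write_xmap(x, path)

  # on disk, the "-" record stores qry_start > qry_end
  rows <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  f2 <- strsplit(rows[2L], "\t")[[1L]]
  expect_gt(as.numeric(f2[4L]), as.numeric(f2[5L]))

  # in memory both spans ascend, strand in `orientation`
  back <- read_xmap(path)
  expect_equal(nrow(back), 2L)
  expect_true(all(back$qry_start < back$qry_end))
  expect_equal(back$orientation, c("+", "-"))
  expect_equal(back$qry_start, x$qry_start)
  expect_equal(back$alignment, x$alignment)
  expect_equal(back$confidence, x$confidence)

  writeLines("# XMAP File Version:\t0.2", path)
  expect_equal(nrow(read_xmap(path)), 0L)

  writeLines(c("#h ...", "1\t10\t1\t100.0\t200.0\t5.0\t105.0\t+"), path)
  expect_error(read_xmap(path), "Confidence")

  writeLines(c("#h ...",
               "1\t10\t1\t100.0\t200.0\t5.0\t105.0\t*\t9.0"), path)
  expect_error(read_xmap(path), "orientation")
})

test_that("AGP output tiles objects and uses the published gap encodings", {
  lens <- c(A = 10000, B = 8000, C = 4000)
  plan_pos <- super_scaffold_plan(
    "Super_scaffold_1",
    data.frame(component_id = c("A", "B"), orientation = c("+", "-")),
    gaps = 500)
  agp <- agp_from_plans(list(plan_pos), lens)

  s1 <- agp[agp$object_id == "Super_scaffold_1", ]
  expect_equal(nrow(s1), 3L)
  expect_equal(s1$object_end[3L], 18500)
  expect_equal(s1$component_type, c("W", "N", "W"))
  expect_equal(s1$gap_length[2L], 500L)
  expect_equal(unlist(s1[2L, c("gap_type", "linkage", "evidence")],
                      use.names = FALSE), c("scaffold", "yes", "map"))

  # unplaced scaffold becomes a single full-length W object
  un <- agp[agp$object_id == "C", ]
  expect_equal(nrow(un), 1L)
  expect_equal(un$component_type, "W")
  expect_equal(un$object_end, 4000)

  # negative gap becomes the fixed 100 bp U spacer
  plan_neg <- super_scaffold_plan(
    "Super_scaffold_2",
    data.frame(component_id = c("A", "B"), orientation = c("+", "+")),
    gaps = -3000)
  agp2 <- agp_from_plans(list(plan_neg), lens[c("A", "B")])
  mid <- agp2[agp2$part_number == 2L & agp2$object_id == "Super_scaffold_2", ]
  expect_equal(mid$component_type, "U")
  expect_equal(mid$gap_length, 100L)
  expect_equal(unlist(mid[, c("gap_type", "linkage", "evidence")],
                      use.names = FALSE), c("scaffold", "yes", "map"))

  # round trip through the file format
  path <- withr::local_tempfile(fileext = ".agp")
  write_agp(agp, path)
  expect_equal(as.data.frame(read_agp(path)), as.data.frame(agp))

  # a coordinate-tiling violation is caught
  broken <- agp
  broken$object_start[3L] <- broken$object_start[3L] + 1L
  expect_error(validate_agp <- stitchmap:::validate_agp(broken), "tile")
})
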