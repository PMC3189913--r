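test_that("read_tps parses a minimal record", {
  f <- withr::local_tempfile(lines = c("LM=3", "0 0", "1 0", "0 1", "ID=sp1"))
  cfgs <- read_tps(f)
  expect_length(cfgs, 1)
  expect_equal(cfgs[[1]]$k, 3)
  expect_equal(cfgs[[1]]$specimen_id, "sp1")
  expect_equal(cfgs[[1]]$coords, cbind(c(0, 1, 0), c(0, 0, 1)))
})

test_that("read_tps handles 16-landmark records, SCALE, IMAGE and CRLF", {
  set.seed(1)
  xy <- matrix(round(rnorm(32), 4), 16, 2)
  lines <- c("LM=16", apply(xy, 1, paste, collapse = " "),
             "IMAGE=cranium.jpg", "SCALE=0.5", "ID=cranium1")
  f <- withr::local_tempfile()
  writeLines(paste0(lines, "\r"), f, sep = "\n")
  cfgs <- read_tps(f)
  expect_equal(cfgs[[1]]$k, 16)
  expect_equal(cfgs[[1]]$coords, xy * 0.5, tolerance = 1e-12)
  expect_equal(cfgs[[1]]$specimen_id, "cranium1")
})

test_that("read_tps rejects malformed input with line numbers", {
  f1 <- withr::local_tempfile(lines = c("LM=abc", "0 0"))
  expect_error(read_tps(f1), "line 1.*malformed")
  f2 <- withr::local_tempfile(lines = c("LM=3", "0 0", "x y", "0 1"))
  expect_error(read_tps(f2), "line 3")
  f3 <- withr::local_tempfile(lines = c("LM=3", "0 0", "1 0", "0 1", "ID=a",
                                        "LM=4", "0 0", "1 0", "0 1", "2 2",
                                        "ID=b"))
  expect_error(read_tps(f3), "differing landmark counts")
})

test_that("write_tps / read_tps round-trips 50 random configurations", {
  cfgs <- random_configs(50, 9, seed = 23)
  f <- withr::local_tempfile()
  write_tps(cfgs, f)
  back <- read_tps(f)
  expect_length(back, 50)
  for (i in seq_along(cfgs)) {
    expect_equal(back[[i]]$coords, cfgs[[i]]$coords, tolerance = 1e-12)
    expect_equal(back[[i]]$specimen_id, cfgs[[i]]$specimen_id)
  }
})

test_that("write_tps formats the forced minimal record and empty sets", {
  f <- withr::local_tempfile()
  write_tps(list(), f)
  expect_identical(readLines(f), character(0))
  write_tps(list(landmark_config(cbind(c(0, 1, 0), c(0, 0, 1)), "s")), f)
  lines <- readLines(f)
  expect_length(lines, 5)
  expect_equal(lines[1], "LM=3")
  expect_match(lines[5], "^ID=")
  mixed <- c(random_configs(1, 3, 1), random_configs(1, 4, 2))
  expect_error(write_tps(mixed, f), "landmark count differs")
})

test_that("read_nexus_matrix parses dimensions, states and missing data", {
  f <- withr::local_tempfile(lines = c(
    "#NEXUS", "BEGIN DATA;", "  DIMENSIONS NTAX=4 NCHAR=2;",
    "  FORMAT DATATYPE=STANDARD MISSING=- SYMBOLS=\"01\";",
    "  MATRIX", "    A 01", "    B 0-", "    C 11", "    D 10", "  ;", "END;"))
  cm <- read_nexus_matrix(f)
  expect_equal(cm$taxa, c("A", "B", "C", "D"))
  expect_equal(cm$n_chars, 2)
  expect_equal(cm$states[2, 2], "?")  # MISSING symbol normalized
  expect_equal(cm$states[1, ], c("0", "1"))
})

test_that("read_nexus_matrix rejects dimension mismatches", {
  f <- withr::local_tempfile(lines = c(
    "#NEXUS", "BEGIN DATA;", "  DIMENSIONS NTAX=3 NCHAR=2;", "  MATRIX",
    "    A 01", "    B 00", "  ;", "END;"))
  expect_error(read_nexus_matrix(f), "2 taxon rows but NTAX=3")
  f2 <- withr::local_tempfile(lines = c(
    "#NEXUS", "BEGIN DATA;", "  DIMENSIONS NTAX=2 NCHAR=3;", "  MATRIX",
    "    A 01", "    B 00", "  ;", "END;"))
  expect_error(read_nexus_matrix(f2), "NCHAR=3")
})

test_that("NEXUS write/read round-trips a random 12 x 30 matrix", {
  cm <- random_character_matrix(12, 30, seed = 4, states = 0:3,
                                missing_frac = 0.1)
  f <- withr::local_tempfile()
  write_nexus_matrix(cm, f)
  back <- read_nexus_matrix(f)
  expect_identical(back$taxa, cm$taxa)
  expect_identical(back$states, cm$states)
})

test_that("newick readers handle stars, branch lengths and bad input", {
  star <- read_newick("(A,B,C);")
  expect_equal(sort(star$tip.label), c("A", "B", "C"))
  expect_equal(star$Nnode, 1)
  bl <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(sort(bl$edge.length), c(1, 1, 1, 2))
  expect_error(read_newick("((A,B,C);"), "invalid Newick")
})

test_that("newick round-trip preserves a random 20-leaf topology (RF = 0)", {
  set.seed(17)
  tr <- ape::rtree(20)
  back <- read_newick(write_newick(tr))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
})

test_that("measurement tables validate values and ids", {
  f <- withr::local_tempfile(lines = c(
    "specimen_id,group,CBL,c1_height",
    "holotype,Pzdanskyi,236.3,56.0"))
  tab <- read_measurements(f)
  expect_equal(tab$CBL, 236.3)
  expect_equal(tab$c1_height, 56.0)

  f2 <- withr::local_tempfile(lines = "specimen_id,group,CBL")
  empty <- read_measurements(f2)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("specimen_id", "group", "CBL"))

  f3 <- withr::local_tempfile(lines = c(
    "specimen_id,group,CBL", "a,g,236.3", "b,g,-1"))
  expect_error(read_measurements(f3), "non-positive.*row\\(s\\) 2")

  f4 <- withr::local_tempfile(lines = c(
    "specimen_id,group,CBL", "a,g,1", "a,g,2"))
  expect_error(read_measurements(f4), "duplicate specimen_id")
})
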