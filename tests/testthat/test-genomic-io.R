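# bedGraph/BED parsing, validation, and interval algebra

test_that("read_coverage parses bedGraph, skips headers, round-trips", {
  f <- write_lines_tmp(c("track type=bedGraph name=x",
                         "chr1\t0\t5\t2", "chr1\t5\t8\t4", "chr2\t0\t3\t1"))
  tr <- read_coverage(f, "s1")
  expect_s3_class(tr, "CoverageTrack")
  expect_equal(length(tr$gr), 3L)
  expect_equal(start(tr$gr), c(1L, 6L, 1L))   # 0-based half-open -> 1-based
  expect_equal(end(tr$gr), c(5L, 8L, 3L))
  expect_equal(tr$gr$score, c(2, 4, 1))

  out <- tempfile(fileext = ".bedgraph")
  write_coverage(tr, out)
  tr2 <- read_coverage(out, "s1")
  expect_identical(as.character(tr2$gr), as.character(tr$gr))
  expect_equal(tr2$gr$score, tr$gr$score)

  # gzip transparency
  gz <- tempfile(fileext = ".bedgraph.gz")
  write_coverage(tr, gz)
  expect_equal(read_coverage(gz, "s1")$gr$score, tr$gr$score)
})

test_that("read_coverage rejects malformed and overlapping input", {
  empty <- write_lines_tmp(character())
  expect_equal(length(read_coverage(empty, "e")$gr), 0L)

  bad <- write_lines_tmp(c("chr1\t0\t5\t2", "chr1\tfive\t8\t1"))
  expect_error(read_coverage(bad), "line 2")

  short <- write_lines_tmp(c("chr1\t0\t5"))
  expect_error(read_coverage(short), "4 fields")

  ovl <- write_lines_tmp(c("chr1\t0\t5\t2", "chr1\t3\t8\t4"))
  expect_error(read_coverage(ovl), "overlap")

  neg <- write_lines_tmp(c("chr1\t5\t5\t2"))
  expect_error(read_coverage(neg), "end > start")
})

test_that("read_sites parses narrowPeak, validates strand, sorts", {
  f <- write_lines_tmp(
    "chr1\t10\t50\tpeak1\t0\t+\t3.2\t5.1\t-1\t20")
  s <- read_sites(f, "RBPX", "lineA")
  expect_equal(start(s$gr), 11L)
  expect_equal(end(s$gr), 50L)
  expect_equal(as.character(strand(s$gr)), "+")

  empty <- write_lines_tmp(character())
  expect_equal(length(read_sites(empty, "RBPX", "lineA")$gr), 0L)

  set.seed(4)
  starts <- sample(1000L, 10L)
  lines <- sprintf("chr%d\t%d\t%d\tp%d\t0\t%s",
                   sample(1:2, 10, TRUE), starts, starts + 30L, 1:10,
                   sample(c("+", "-"), 10, TRUE))
  s10 <- read_sites(write_lines_tmp(lines), "RBPY", "lineB")
  expect_equal(length(s10$gr), 10L)
  key <- paste(as.character(seqnames(s10$gr)),
               sprintf("%09d", start(s10$gr)))
  expect_false(is.unsorted(key))

  expect_error(read_sites(write_lines_tmp("chr1\t1\t5\tp\t0"),
                          "R", "l"), ">= 6 columns")
  expect_error(read_sites(write_lines_tmp("chr1\t1\t5\tp\t0\t."),
                          "R", "l"), "unknown strand")
})

test_that("merge_cross_cell_line is strand-aware and coalesces book-ends", {
  a <- binding_site_set("R", "lineA", gr1("chr1", 1, 10, "+"))
  b <- binding_site_set("R", "lineB", gr1("chr1", 6, 15, "+"))
  m <- merge_cross_cell_line(a, b)
  expect_equal(m$cell_line, "merged")
  expect_equal(start(m$gr), 1L)
  expect_equal(end(m$gr), 15L)

  bneg <- binding_site_set("R", "lineB", gr1("chr1", 6, 15, "-"))
  m2 <- merge_cross_cell_line(a, bneg)
  expect_equal(length(m2$gr), 2L)   # opposite strands stay separate

  # book-ended: [1,10] then [11,20] in 1-based inclusive are adjacent
  bk <- binding_site_set("R", "lineB", gr1("chr1", 11, 20, "+"))
  expect_equal(length(merge_cross_cell_line(a, bk)$gr), 1L)

  expect_error(merge_cross_cell_line(
    a, binding_site_set("Q", "lineB", gr1("chr1", 1, 5, "+"))),
    "different RBPs")
})

test_that("merge is idempotent, commutative, and never gains bases", {
  set.seed(11)
  for (rep in 1:5) {
    a <- random_sites("R"); b <- random_sites("R")
    b$cell_line <- "lineB"
    m1 <- merge_cross_cell_line(a, b)
    m2 <- merge_cross_cell_line(b, a)
    expect_identical(as.data.frame(m1$gr), as.data.frame(m2$gr))
    again <- merge_cross_cell_line(m1, m1)
    expect_identical(as.data.frame(again$gr), as.data.frame(m1$gr))
    expect_lte(sum(width(m1$gr)), sum(width(a$gr)) + sum(width(b$gr)))
    # merged base count per strand equals the per-base union oracle
    for (st in c("+", "-")) {
      expect_equal(sum(width(m1$gr[strand(m1$gr) == st])),
                   oracle_union_bases(list(a$gr, b$gr), "chrT", st))
    }
  }
})

test_that("partition_union reproduces the two-site worked example", {
  # A binds 1-10 and B binds 5-15 (1-based inclusive): three atoms
  a <- binding_site_set("A", "lineA", gr1("chr1", 1, 10, "+"))
  b <- binding_site_set("B", "lineA", gr1("chr1", 5, 15, "+"))
  p <- partition_union(list(a, b))
  expect_equal(length(p$atoms), 3L)
  expect_equal(start(p$atoms), c(1L, 5L, 11L))
  expect_equal(end(p$atoms), c(4L, 10L, 15L))
  expect_equal(p$members, list("A", c("A", "B"), "B"))

  # single set: atoms equal its merged sites
  single <- partition_union(list(a))
  expect_equal(as.character(granges(single$atoms)),
               as.character(unstrand(granges(a$gr))))

  # three nested intervals -> 5 atoms
  n1 <- binding_site_set("R1", "l", gr1("chr1", 1, 30, "+"))
  n2 <- binding_site_set("R2", "l", gr1("chr1", 11, 20, "+"))
  n3 <- binding_site_set("R3", "l", gr1("chr1", 13, 18, "+"))
  pn <- partition_union(list(n1, n2, n3))
  expect_equal(length(pn$atoms), 5L)
  expect_equal(lengths(pn$members), c(1L, 2L, 3L, 2L, 1L))
})

test_that("partition atoms are disjoint, sorted, cover the union exactly", {
  set.seed(21)
  for (rep in 1:5) {
    sets <- lapply(paste0("R", 1:4), random_sites)
    p <- partition_union(sets)
    expect_true(all(start(p$atoms)[-1] >=
                      end(p$atoms)[-length(p$atoms)] + 0L |
                      as.character(seqnames(p$atoms))[-1] !=
                      as.character(seqnames(p$atoms))[-length(p$atoms)]))
    expect_equal(length(findOverlaps(p$atoms, drop.self = TRUE,
                                     ignore.strand = TRUE)), 0L)
    orc <- oracle_atoms(sets, "chrT")
    expect_equal(start(p$atoms), orc$start1)
    expect_equal(end(p$atoms), orc$end1)
    expect_equal(vapply(p$members, paste, "", collapse = ";"), orc$members)
  }
})

test_that("site_library adds one merged set per RBP seen in both lines", {
  mk <- function(r, cl, off) binding_site_set(r, cl, gr1("chr1", off, off + 9, "+"))
  sets <- list(mk("A", "lineA", 1), mk("B", "lineA", 100),
               mk("A", "lineB", 5), mk("C", "lineB", 200),
               mk("D", "lineB", 300))
  lib <- site_library(sets)
  expect_equal(length(lib), 6L)   # 5 cell-line sets + merged A
  expect_true("A.merged" %in% names(lib))
  expect_equal(start(lib[["A.merged"]]$gr), 1L)
  expect_equal(end(lib[["A.merged"]]$gr), 14L)
})

test_that("annotation reader keeps multi-biotype records", {
  f <- write_lines_tmp(c(
    "chr1\t100\t200\tG1\tpseudogene\tWASHX\t+",
    "chr1\t100\t200\tG1\tunprocessed_pseudogene\tWASHX\t+",
    "chr2\t10\t90\tG2\tmiRNA\tMIR-X\t-"))
  ann <- read_annotation(f)
  expect_s3_class(ann, "AnnotationSet")
  expect_equal(length(ann$gr), 3L)
  expect_setequal(ann$gr$biotype[ann$gr$gene_id == "G1"],
                  c("pseudogene", "unprocessed_pseudogene"))
})
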