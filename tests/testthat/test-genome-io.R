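test_that("segment catalogs round-trip through the TSV dialect", {
  set.seed(4)
  n <- 100
  seg <- segment_catalog(
    sample = rep(c("A", "B"), each = n / 2),
    chrom = rep(c("1", "2"), n / 2),
    start = rep(seq(1, by = 2e6, length.out = n / 2), times = 2),
    end = rep(seq(1, by = 2e6, length.out = n / 2), times = 2) +
      sample(1e3:1e6, n, TRUE),
    n_major = sample(1:4, n, TRUE), n_minor = sample(0:1, n, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(seg, path)
  back <- read_segments(path)
  expect_equal(back, seg, ignore_attr = TRUE)
})

test_that("segment readers reject malformed files with row numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchr\tstart\tend\tnMajor\tnMinor",
               "A\t1\t100\t50\t1\t1"), path)
  expect_error(read_segments(path), "row\\(s\\): 1")
  writeLines(c("sample\tchr\tstart\tend\tnMajor\tnMinor",
               "A\t1\t100\t500\t1\t2"), path)
  expect_error(read_segments(path), "n_major >= n_minor")
  writeLines(c("sample\tchr\tstart\tend\tnMajor",
               "A\t1\t100\t500\t1"), path)
  expect_error(read_segments(path), "missing column")
  # overlapping segments within one sample are invalid
  expect_error(segment_catalog(c("A", "A"), c("1", "1"), c(1, 50),
                               c(100, 150), c(1, 1), c(1, 1)),
               "overlapping")
})

test_that("a single valid row reads as a one-record catalog", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchr\tstart\tend\tnMajor\tnMinor",
               "A\t1\t100\t500\t2\t1"), path)
  seg <- read_segments(path)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_major, 2L)
})

test_that("BEDPE round-trips with the 1-based shift and derives types", {
  set.seed(5)
  n <- 50
  chrom2 <- sample(c("1", "2"), n, TRUE)
  rr <- rearrangement_catalog(
    sample = "S1", chrom1 = "1", pos1 = sort(sample(1e6:9e7, n)),
    chrom2 = chrom2, pos2 = sample(1e6:9e7, n),
    orientation = sample(c("HH", "HT", "TH", "TT"), n, TRUE))
  path <- withr::local_tempfile(fileext = ".bedpe")
  write_rearrangements(rr, path)
  back <- read_rearrangements(path)
  expect_equal(back[names(rr)], rr, ignore_attr = TRUE)
  # coordinate convention: BEDPE start is internal position minus one
  raw <- utils::read.table(path, header = TRUE)
  expect_equal(raw$start1 + 1, rr$pos1)
  # types follow geometry and orientation
  expect_true(all(back$type[back$chrom1 != back$chrom2] == "translocation"))
  intra_ht <- back$chrom1 == back$chrom2 & back$orientation == "HT"
  expect_true(all(back$type[intra_ht] == "deletion"))
  expect_equal(sv_type_from_orientation("1", "1", c("TH", "HH", "TT")),
               c("tandem-duplication", "inversion", "inversion"))
})

test_that("unknown strand symbols are a format error", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c(paste("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                     "name", "score", "strand1", "strand2", sep = "\t"),
               paste("1", 100, 101, "1", 5000, 5001, "S1", ".", "+", "*",
                     sep = "\t")), path)
  expect_error(read_rearrangements(path), "strand")
})

test_that("SNV and metadata readers validate their invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchr\tpos\tref\talt\tvaf",
               "A\t1\t100\tC\tT\t1.2"), path)
  expect_error(read_snvs(path), "vaf")
  writeLines(c("sample\tchr\tpos\tref\talt\tvaf\tcadd",
               "A\t1\t100\tC\tT\t0.4\t22"), path)
  snv <- read_snvs(path)
  expect_equal(snv$cadd, 22)          # annotations carried through
  writeLines(c("sample\tpurity\tploidy\tage",
               "A\t1.4\t2\t60"), path)
  expect_error(read_sample_meta(path), "purity")
})

test_that("translocation typing is enforced by geometry", {
  expect_error(rearrangement_catalog("A", "1", 100, "2", 200, "HT",
                                     type = "deletion"),
               "translocation")
  expect_true(is.na(sv_size(rearrangement_catalog("A", "1", 100, "2", 200,
                                                  "HT"))))
  expect_equal(sv_size(rearrangement_catalog("A", "1", 100, "1", 5100,
                                             "HT")), 5000)
})
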