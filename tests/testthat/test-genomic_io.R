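test_that("read_bed parses BED3 and converts coordinates at the boundary", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("# a comment",
               "track name=test",
               "chr1\t1000\t1200",
               "chr2\t0\t50"), path)
  gr <- read_bed(path)
  expect_length(gr, 2L)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), c("chr1", "chr2"))
  expect_equal(start0(gr), c(1000L, 0L))
  expect_equal(end0(gr), c(1200L, 50L))
  expect_equal(GenomicRanges::width(gr), c(200L, 50L))
})

test_that("read_bed keeps BED6 name/score/strand and maps '.' to '*'", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tpeakA\t5\t+",
               "chr1\t30\t40\tpeakB\t7.5\t.",
               "chr1\t50\t60\tpeakC\t0\t-"), path)
  gr <- read_bed(path)
  expect_equal(S4Vectors::mcols(gr)$name, c("peakA", "peakB", "peakC"))
  expect_equal(S4Vectors::mcols(gr)$score, c(5, 7.5, 0))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "*", "-"))
})

test_that("read_bed reports the 1-based file line of the first bad record", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("# header", "chr1\t10\t20", "chr1\t30"), path)
  expect_error(read_bed(path), "line 3")
  writeLines(c("chr1\t10\t20", "chr1\tfoo\t40"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t50\t50"), path)
  expect_error(read_bed(path), "end <= start")
  expect_error(read_bed(tempfile()), "file not found")
})

test_that("BED6 files round-trip byte for byte", {
  path <- tempfile(fileext = ".bed")
  lines <- c("chr1\t100\t250\tp1\t12\t+",
             "chr1\t300\t420\tp2\t0\t-",
             "chr2\t5\t95\tp3\t3\t.")
  writeLines(lines, path)
  out <- tempfile(fileext = ".bed")
  write_bed(read_bed(path), out)
  expect_identical(readLines(out), lines)
})

test_that("random intervals survive a write/read round trip", {
  set.seed(42)
  for (i in 1:20) {
    gr <- random_intervals(25)
    S4Vectors::mcols(gr)$name <- sprintf("iv%d", seq_along(gr))
    S4Vectors::mcols(gr)$score <- sample(0:1000, length(gr))
    path <- tempfile(fileext = ".bed")
    write_bed(gr, path)
    back <- read_bed(path)
    expect_equal(start0(back), start0(gr))
    expect_equal(end0(back), end0(gr))
    expect_equal(S4Vectors::mcols(back)$score, S4Vectors::mcols(gr)$score)
  }
})

test_that("read_narrowpeak enforces 10 columns and decodes the summit", {
  path <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t300\tpk1\t0\t.\t8.5\t12.2\t9.9\t75",
               "chr1\t500\t700\tpk2\t0\t.\t3.1\t-1\t-1\t-1"), path)
  gr <- read_narrowpeak(path)
  expect_equal(S4Vectors::mcols(gr)$score, c(8.5, 3.1))
  expect_equal(S4Vectors::mcols(gr)$summit, c(75L, NA_integer_))
  writeLines("chr1\t100\t300\tpk1\t0\t.", path)
  expect_error(read_narrowpeak(path), "expected 10 columns")
})

test_that("write_narrowpeak round-trips and fills placeholders", {
  path <- tempfile(fileext = ".narrowPeak")
  lines <- c("chr1\t100\t300\tpk1\t0\t.\t8.5\t12.2\t9.9\t75",
             "chr1\t500\t700\tpk2\t0\t.\t3.1\t-1\t-1\t-1")
  writeLines(lines, path)
  out <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(read_narrowpeak(path), out)
  expect_identical(readLines(out), lines)
  bare <- gr0("chr1", 10, 20)
  write_narrowpeak(bare, out)
  expect_equal(strsplit(readLines(out), "\t")[[1]],
               c("chr1", "10", "20", ".", "0", ".", "0", "-1", "-1", "-1"))
})

test_that("read_alignments parses SAM pairs and tallies drops", {
  sam <- write_sam_fixture(list(
    list(chrom = "chr1", pos = 1001L, len = 200L),
    list(chrom = "chr1", pos = 5001L, len = 150L, mapq = 5L),
    list(chrom = "chr1", pos = 9001L, len = 180L, improper = TRUE),
    list(chrom = "chrM", pos = 101L, len = 120L)))
  aln <- read_alignments(sam, min_mapq = 30L)
  expect_length(aln$fragments, 1L)
  expect_equal(start0(aln$fragments), 1000L)
  expect_equal(end0(aln$fragments), 1200L)
  expect_equal(as.character(GenomicRanges::strand(aln$fragments)), "+")
  expect_equal(aln$contig_tallies[["chr1"]], 2L)
  expect_equal(aln$contig_tallies[["chrM"]], 1L)
  expect_equal(aln$dropped$low_mapq, 1L)
  expect_equal(aln$dropped$improper, 1L)
  expect_equal(aln$dropped$excluded, 1L)
})

test_that("contig tallies count every proper-pair template exactly once", {
  set.seed(7)
  pairs <- lapply(1:30, function(i) {
    list(chrom = sample(c("chr1", "chrM"), 1L),
         pos = sample(1000:50000, 1L), len = sample(100:400, 1L))
  })
  aln <- read_alignments(write_sam_fixture(pairs))
  expect_equal(sum(aln$contig_tallies), 30L)
  expect_equal(length(aln$fragments) + aln$dropped$excluded, 30L)
})

test_that("read_alignments dedup collapses identical templates", {
  sam <- write_sam_fixture(list(
    list(chrom = "chr1", pos = 1001L, len = 200L),
    list(chrom = "chr1", pos = 1001L, len = 200L),
    list(chrom = "chr1", pos = 2001L, len = 200L)))
  aln <- read_alignments(sam, dedup = TRUE)
  expect_length(aln$fragments, 2L)
  expect_equal(aln$dropped$duplicate, 1L)
})

test_that("BED fragment dialect carries mapq in the score column", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t1200\tf1\t60\t+",
               "chr1\t2000\t2150\tf2\t10\t-"), path)
  aln <- read_alignments(path, min_mapq = 30L)
  expect_length(aln$fragments, 1L)
  expect_equal(aln$dropped$low_mapq, 1L)
  expect_equal(sum(aln$contig_tallies), 2L)
})

test_that("read_pfm handles JASPAR layouts and rejects malformed input", {
  path <- tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TEST",
               "A [ 1 2 3 4 ]",
               "C [ 5 6 7 8 ]",
               "G [ 0 1 0 1 ]",
               "T [ 2 2 2 2 ]"), path)
  pfm <- read_pfm(path)
  expect_equal(dim(pfm), c(4L, 4L))
  expect_equal(unname(unclass(pfm)[1, ]), c(1, 2, 3, 4))
  expect_equal(attr(pfm, "motif_id"), "MA0001.1")

  writeLines(c("1 2 3 4", "5 6 7 8", "0 1 0 1", "2 2 2 2"), path)
  expect_equal(unname(unclass(read_pfm(path))[4, ]), c(2, 2, 2, 2))

  writeLines(c("1 2 3", "5 6 7 8", "0 1 0 1", "2 2 2 2"), path)
  expect_error(read_pfm(path), "ragged")
  writeLines(c("1 2 3 -1", "5 6 7 8", "0 1 0 1", "2 2 2 2"), path)
  expect_error(read_pfm(path), "negative")
  writeLines(c("1 2 3 4", "5 6 7 8", "0 1 0 1"), path)
  expect_error(read_pfm(path), "exactly 4")
  writeLines(c("1 2 3", "5 6 7", "0 1 0", "2 2 2"), path)
  expect_error(read_pfm(path), "width")
})

test_that("read_gene_model parses BED12 and refFlat to the same model", {
  bed12 <- tempfile(fileext = ".bed")
  writeLines(paste("chr1", 1000, 5000, "tx1", 0, "+", 1000, 5000, 0, 2,
                   "400,600,", "0,3400,", sep = "\t"), bed12)
  g1 <- read_gene_model(bed12, "bed12")
  expect_equal(start0(g1), 1000L)
  expect_equal(end0(g1), 5000L)
  ex <- S4Vectors::mcols(g1)$exons[[1]]
  expect_equal(IRanges::start(ex), c(1001L, 4401L))
  expect_equal(IRanges::end(ex), c(1400L, 5000L))

  rf <- tempfile(fileext = ".txt")
  writeLines(paste("GENE1", "tx1", "chr1", "+", 1000, 5000, 1000, 5000, 2,
                   "1000,4400,", "1400,5000,", sep = "\t"), rf)
  g2 <- read_gene_model(rf, "refflat")
  expect_equal(start0(g2), start0(g1))
  expect_equal(S4Vectors::mcols(g2)$exons[[1]], ex)
})

test_that("read_gene_model rejects inconsistent exon blocks", {
  path <- tempfile(fileext = ".bed")
  writeLines(paste("chr1", 1000, 5000, "tx1", 0, "+", 1000, 5000, 0, 2,
                   "400,600,", "0,200,", sep = "\t"), path)  # overlapping
  expect_error(read_gene_model(path, "bed12"), "non-overlapping")
  writeLines(paste("chr1", 1000, 5000, "tx1", 0, "+", 1000, 5000, 0, 1,
                   "9000,", "0,", sep = "\t"), path)  # outside span
  expect_error(read_gene_model(path, "bed12"), "outside transcript span")
  writeLines(paste("chr1", 1000, 5000, "tx1", 0, ".", 1000, 5000, 0, 1,
                   "400,", "0,", sep = "\t"), path)
  expect_error(read_gene_model(path, "bed12"), "strand")
})

test_that("tss_sites takes the 5' end per strand and dedups", {
  genes <- gr0("chr1", c(1000, 1000, 3000), c(2000, 2000, 4000),
               strand = c("+", "+", "-"))
  tss <- tss_sites(genes)
  expect_length(tss, 2L)
  expect_equal(GenomicRanges::start(tss), c(1001L, 4000L))
  expect_equal(as.character(GenomicRanges::strand(tss)), c("+", "-"))
  # minus-strand TSS is the last transcribed base: 0-based end - 1
  expect_equal(start0(tss)[2], 4000L - 1L)
  expect_length(tss_sites(genes, dedup = FALSE), 3L)
  expect_error(tss_sites(gr0("chr1", 0, 10)), "stranded")
})

test_that("gene model write/read round trip preserves the model", {
  spec <- simulation_spec(n_fragments = 100L)
  gen <- make_genome(spec)
  path <- tempfile(fileext = ".bed")
  write_gene_model(gen$genes, path)
  back <- read_gene_model(path, "bed12")
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gen$genes))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(gen$genes)))
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(gen$genes)$name)
  expect_equal(unname(S4Vectors::mcols(back)$exons),
               unname(S4Vectors::mcols(gen$genes)$exons))
})
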