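test_that("FASTA round-trips ids, descriptions and wrapped sequences", {
  recs <- seq_set(c("s1", "s2"),
                  c(strrep("ACGT", 60), "TTTTT"),
                  desc = c("first record", ""))
  path <- tempfile(fileext = ".fa")
  write_fasta(recs, path, width = 70)
  back <- read_fasta(path, "nucleotide")
  expect_identical(back$id, recs$id)
  expect_identical(back$desc, recs$desc)
  expect_identical(back$seq, recs$seq)
  # wrapping actually happened
  expect_gt(length(readLines(path)), 4)
})

test_that("read_fasta accepts literal text, uppercases, and maps U to T", {
  df <- read_fasta(">r1 some desc\nacgu\nACGU\n", "nucleotide")
  expect_identical(df$id, "r1")
  expect_identical(df$desc, "some desc")
  expect_identical(df$seq, "ACGTACGT")
})

test_that("read_fasta rejects bad alphabets naming record and character", {
  expect_error(read_fasta(">p1\nACDEFZ\n", "protein"),
               "p1.*Z", class = "viromimic_alphabet_error")
  expect_error(read_fasta(">n1\nACGTE\n", "nucleotide"),
               "n1.*E", class = "viromimic_alphabet_error")
})

test_that("read_fasta rejects structural problems", {
  expect_error(read_fasta("ACGT\n>x\nA\n"), class = "viromimic_io_error")
  expect_error(read_fasta(">a\nACGT\n>a\nACGT\n"), "duplicate",
               class = "viromimic_io_error")
  expect_error(read_fasta(">a\n>b\nACGT\n"), "empty sequence",
               class = "viromimic_io_error")
})

test_that("FASTQ round-trips sequences and integer qualities", {
  recs <- seq_set(c("r1", "r2"), c("ACGTN", "GGGG"),
                  desc = c("lane1", ""),
                  qual = list(c(30L, 31L, 32L, 33L, 2L), c(40L, 40L, 40L, 40L)))
  path <- tempfile(fileext = ".fq")
  write_fastq(recs, path)
  back <- read_fastq(path)
  expect_identical(back$id, recs$id)
  expect_identical(back$seq, recs$seq)
  expect_identical(back$qual, recs$qual)
})

test_that("read_fastq reports malformed records by index", {
  expect_error(read_fastq("@r1\nACGT\n+\nIII\n"),
               "record 1.*4 vs 3", class = "viromimic_io_error")
  expect_error(read_fastq("@r1\nACGT\n+\nIIII\n@r2\nACGT\n"),
               "truncated.*record 2", class = "viromimic_io_error")
  expect_error(read_fastq("r1\nACGT\n+\nIIII\n"), class = "viromimic_io_error")
})

test_that("write_fastq refuses records without qualities", {
  expect_error(write_fastq(seq_set("r1", "ACGT"), tempfile()),
               class = "viromimic_io_error")
})

test_that("hit tables round-trip through the 12-column tabular format", {
  hits <- data.frame(
    qseqid = c("q1", "q2"), sseqid = c("s1", "s2"),
    pident = c(100, 96.77), length = c(30L, 31L), mismatch = c(0L, 1L),
    gapopen = c(0L, 0L), qstart = c(1L, 5L), qend = c(30L, 35L),
    sstart = c(10L, 200L), send = c(99L, 108L),
    evalue = c(3.5e-12, 0.002), bitscore = c(61.2, 30.1),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".m6")
  write_hit_table(hits, path)
  lines <- readLines(path)
  expect_identical(lines[1],
                   "q1\ts1\t100.00\t30\t0\t0\t1\t30\t10\t99\t3.5e-12\t61.2")
  back <- parse_hit_table(path)
  expect_identical(back$qseqid, hits$qseqid)
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-3)
  expect_identical(back$sstart, hits$sstart)
})

test_that("parse_hit_table flags short lines with their line number", {
  path <- tempfile()
  writeLines(c("q\ts\t1\t2\t3\t4\t5\t6\t7\t8\t9\t10", "q\ts\tonly\tfour\tcols"),
             path)
  expect_error(parse_hit_table(path), "line 2", class = "viromimic_io_error")
})

test_that("empty hit tables round-trip", {
  path <- tempfile()
  write_hit_table(empty_hit_table(), path)
  expect_identical(nrow(parse_hit_table(path)), 0L)
})
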