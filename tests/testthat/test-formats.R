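test_that("plot files transcribe directly and round-trip byte-identically", {
  f <- withr::local_tempfile(fileext = ".plot")
  writeLines(c("0 0", "3 1", "0 0"), f)
  p <- readPlot(f, "chr")
  expect_s4_class(p, "InsertionProfile")
  expect_equal(length(p), 3L)
  expect_equal(readsFwd(p), c(0L, 3L, 0L))
  expect_equal(readsRev(p), c(0L, 1L, 0L))
  expect_equal(totalReads(p), 4L)

  g <- withr::local_tempfile(fileext = ".plot")
  writePlot(p, g)
  expect_identical(readBin(g, "raw", file.size(g)),
                   readBin(f, "raw", file.size(f)))
  p2 <- readPlot(g, "chr")
  expect_equal(readsFwd(p2), readsFwd(p))
  expect_equal(readsRev(p2), readsRev(p))
})

test_that("empty and gzipped plot files are handled", {
  f <- withr::local_tempfile(fileext = ".plot")
  file.create(f)
  p <- readPlot(f, "chr")
  expect_equal(length(p), 0L)
  g <- withr::local_tempfile(fileext = ".plot.gz")
  writePlot(p, g)
  expect_equal(length(readPlot(g, "chr")), 0L)

  q <- InsertionProfile("chr", c(5L, 0L), c(0L, 2L))
  gz <- withr::local_tempfile(fileext = ".plot.gz")
  writePlot(q, gz)
  q2 <- readPlot(gz, "chr")
  expect_equal(readsFwd(q2), readsFwd(q))
  expect_equal(readsRev(q2), readsRev(q))
})

test_that("malformed plot lines are rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".plot")
  writeLines(c("0 0", "1 2 3"), f)
  expect_error(readPlot(f), "line 2")
  writeLines(c("0 0", "4 -1"), f)
  expect_error(readPlot(f), "line 2")
  writeLines(c("0 x"), f)
  expect_error(readPlot(f), "line 1")
})

test_that("GFF3 gene features come back as a sorted GRanges", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr 1 5000",
    "chr\tsrc\tgene\t601\t900\t.\t-\t.\tID=gB;Name=geneB",
    "chr\tsrc\tgene\t101\t400\t.\t+\t.\tID=gA;Name=geneA"), f)
  g <- readAnnotation(f)
  expect_equal(g$gene_id, c("gA", "gB"))
  expect_equal(BiocGenerics::start(g), c(101L, 601L))
  expect_equal(BiocGenerics::end(g), c(400L, 900L))
  expect_equal(as.character(BiocGenerics::strand(g)), c("+", "-"))
})

test_that("annotation errors: duplicates, overflow, no genes", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tgene\t1\t100\t.\t+\t.\tID=gA",
    "chr\tsrc\tgene\t200\t300\t.\t+\t.\tID=gA"), f)
  expect_error(readAnnotation(f), "duplicate")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr 1 500",
    "chr\tsrc\tgene\t400\t600\t.\t+\t.\tID=gA"), f)
  expect_error(readAnnotation(f), "sequence-region")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tregion\t1\t500\t.\t+\t.\tID=r1"), f)
  expect_warning(g <- readAnnotation(f), "no gene")
  expect_equal(length(g), 0L)
})

test_that("annotation round-trips through writeAnnotation", {
  sim <- fx_sim()
  f <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotation(sim$genes, f, seqlength = length(sim$profile))
  g <- readAnnotation(f)
  expect_equal(g$gene_id, sim$genes$gene_id)
  expect_equal(BiocGenerics::start(g), BiocGenerics::start(sim$genes))
  expect_equal(BiocGenerics::end(g), BiocGenerics::end(sim$genes))
  expect_equal(as.character(BiocGenerics::strand(g)),
               as.character(BiocGenerics::strand(sim$genes)))
})

test_that("SAM junction extraction follows the 5'-end convention", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr\tLN:200",
    # forward read aligned to bases 11..60: junction at its leftmost base
    paste("r1", 0, "chr", 11, 60, "50M", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t"),
    # reverse read over the same span: junction at its rightmost base
    paste("r2", 16, "chr", 11, 60, "50M", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t"),
    # low mapq, unmapped, and secondary records are skipped and tallied
    paste("r3", 0, "chr", 5, 3, "50M", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t"),
    paste("r4", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t"),
    paste("r5", 256, "chr", 90, 60, "50M", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t")), sam)
  p <- samToProfile(sam, "chr", 200L, min_mapq = 10L)
  fwd <- readsFwd(p); rev <- readsRev(p)
  expect_equal(which(fwd > 0), 11L)
  expect_equal(which(rev > 0), 60L)
  expect_equal(totalReads(p), 2L)
  sk <- attr(p, "skipped")
  expect_equal(unname(sk[c("low_mapq", "unmapped", "secondary")]),
               c(1L, 1L, 1L))
})
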