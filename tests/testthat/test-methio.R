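test_that("cytosine report parsing maps fields, normalises CpG, filters by depth", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("Chr01\t100\t+\t5\t5\tCpG\tCGG", f)
  mt <- read_cytosine_report(f, min_depth = 0)
  expect_equal(nrow(mt), 1L)
  expect_equal(mt$pos, 100L)
  expect_equal(mt$context, "CG")
  expect_equal(mt$n_meth, 5L)
  expect_equal(mt$n_unmeth, 5L)

  writeLines("Chr01\t100\t+\t0\t3\tCHH\tCTT", f)
  expect_equal(nrow(read_cytosine_report(f, min_depth = 5)), 0L)
  expect_equal(nrow(read_cytosine_report(f, min_depth = 3)), 1L)
})

test_that("depth filter keeps exactly the qualifying rows and counts the rest", {
  f <- withr::local_tempfile(fileext = ".txt")
  depths <- data.frame(m = c(5, 0, 2, 9, 1, 0, 3, 6, 2, 10),
                       u = c(3, 2, 1, 0, 2, 3, 1, 2, 1, 5))
  # depths: 8,2,3,9,3,3,4,8,3,15 -> 4 rows with depth >= 5
  writeLines(sprintf("Chr01\t%d\t+\t%d\t%d\tCG\tCGA",
                     seq(10, 100, 10), depths$m, depths$u), f)
  mt <- read_cytosine_report(f, min_depth = 5)
  expect_equal(nrow(mt), 4L)
  expect_equal(attr(mt, "rows_in"), 10L)
  expect_equal(attr(mt, "rows_kept") + attr(mt, "rows_filtered"), 10L)
  # counts preserved bit-exact
  expect_equal(mt$n_meth, c(5L, 9L, 6L, 10L))
  expect_equal(mt$n_unmeth, c(3L, 0L, 2L, 5L))
})

test_that("malformed report lines fail with the line number; empty file is empty", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Chr01\t10\t+\t1\t2\tCG\tCGA",
               "Chr01\t20\t+\tx\t2\tCG\tCGA"), f)
  expect_error(read_cytosine_report(f), "line 2")
  writeLines(c("Chr01\t10\t+\t1\t2\tBAD\tCGA"), f)
  expect_error(read_cytosine_report(f), "line 1")
  file.create(f2 <- withr::local_tempfile(fileext = ".txt"))
  mt <- read_cytosine_report(f2)
  expect_equal(nrow(mt), 0L)
  expect_equal(attr(mt, "rows_in"), 0L)
})

test_that("GFF3 import converts coordinates, derives introns, counts TE classes", {
  ann0 <- toy_annotation()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann0, f)
  ann <- read_gff3(f)
  expect_equal(length(ann$genes), 3L)
  expect_equal(start(ann$genes)[1], 1001L)  # 1-based retained internally
  expect_equal(length(ann$tes), 5L)
  expect_equal(as.vector(table(ann$tes$te_class)[c("LTR/Gypsy",
    "LTR/Copia", "LINE", "DNA")]), c(2L, 1L, 1L, 1L))
  introns <- ann$features[ann$features$type == "intron"]
  expect_equal(length(introns), 3L)
  expect_equal(start(introns)[introns$gene_id == "g1"], 1401L)
  expect_equal(end(introns)[introns$gene_id == "g1"], 1500L)
})

test_that("intron derivation is the transcript span minus exons", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region Chr01 1 1000",
               "Chr01\tx\tgene\t1\t300\t.\t+\t.\tID=gA",
               "Chr01\tx\tmRNA\t1\t300\t.\t+\t.\tID=gA.1;Parent=gA",
               "Chr01\tx\texon\t1\t100\t.\t+\t.\tParent=gA.1",
               "Chr01\tx\texon\t201\t300\t.\t+\t.\tParent=gA.1"), f)
  ann <- read_gff3(f)
  introns <- ann$features[ann$features$type == "intron"]
  expect_equal(start(introns), 101L)
  expect_equal(end(introns), 200L)
})

test_that("TEs without a class attribute become 'other' with a warning", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region Chr01 1 1000",
               "Chr01\tx\ttransposable_element\t10\t100\t.\t.\t.\tID=te1"),
             f)
  expect_warning(ann <- read_gff3(f), "other")
  expect_equal(ann$tes$te_class, "other")
})

test_that("child features outside the parent span are rejected", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region Chr01 1 1000",
               "Chr01\tx\tgene\t100\t300\t.\t+\t.\tID=gA",
               "Chr01\tx\tmRNA\t100\t300\t.\t+\t.\tID=gA.1;Parent=gA",
               "Chr01\tx\texon\t100\t400\t.\t+\t.\tParent=gA.1"), f)
  expect_error(read_gff3(f), "outside")
})

test_that("BED-family readers preserve intervals and scores", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("Chr01\t0\t500\tpeak1\t100", f)
  gr <- read_regions(f, "bed")
  expect_equal(start(gr), 1L)     # 0-based half-open -> 1-based closed
  expect_equal(end(gr), 500L)
  expect_equal(gr$score, 100)
  expect_equal(gr$name, "peak1")

  writeLines("Chr01\t0\t50\t3.5", f)
  bg <- read_regions(f, "bedGraph")
  expect_equal(start(bg), 1L)
  expect_equal(end(bg), 50L)
  expect_equal(bg$score, 3.5)

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(sprintf("Chr01\t%d\t%d\tp%d\t%d\t.\t4.5\t10\t8\t25",
                     (0:6) * 1000, (0:6) * 1000 + 500, 1:7, 1:7 * 10), np)
  pk <- read_regions(np)
  expect_equal(length(pk), 7L)
  expect_equal(pk$score, (1:7) * 10)
})

test_that("invalid intervals are rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("Chr01\t0\t500", "Chr01\t600\t600"), f)
  expect_error(read_regions(f, "bed"), "line 2")
})

test_that("write_regions round-trips random interval sets exactly", {
  set.seed(99)
  gr <- GRanges("Chr01", IRanges(sample(1e5, 100),
                                 width = sample(50:2000, 100, TRUE)),
                strand = sample(c("+", "-", "*"), 100, TRUE))
  gr$name <- sprintf("iv%03d", 1:100)
  gr$score <- round(runif(100) * 1000, 3)
  f <- withr::local_tempfile(fileext = ".bed")
  write_regions(gr, f)
  gr2 <- read_regions(f, "bed")
  expect_equal(start(gr2), start(gr))
  expect_equal(end(gr2), end(gr))
  expect_equal(as.character(strand(gr2)), as.character(strand(gr)))
  expect_equal(gr2$score, gr$score)
  expect_equal(gr2$name, gr$name)
  # empty set -> empty file
  write_regions(GRanges(), f)
  expect_equal(length(read_regions(f, "bed")), 0L)
})

test_that("methylome_table enforces its invariants", {
  expect_error(mk_mt(1, -1, 5), "non-negative")
  expect_error(methylome_table(data.frame(chrom = "c", pos = c(1, 1),
    strand = "+", context = "CG", n_meth = 1, n_unmeth = 1)), "duplicate")
  mt <- mk_mt(c(30, 10, 20), 1, 1)
  expect_equal(mt$pos, c(10L, 20L, 30L))  # sorted on construction
})

test_that("chromosome length tables read as named vectors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Chr01\t1000000", "Chr02\t2000000"), f)
  cl <- read_chrom_lengths(f)
  expect_equal(cl, c(Chr01 = 1e6, Chr02 = 2e6))
})
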