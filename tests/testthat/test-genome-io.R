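test_that("BED tag reading applies the 5' convention and counts the library", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t136\tr1\t0\t+",
               "chr1\t100\t136\tr2\t0\t-",
               "chr2\t5\t41\tr3\t0\t+"), path)
  tc <- read_tags_bed(path)
  expect_equal(attr(tc, "library_size"), 3)
  expect_equal(tc$pos[tc$chrom == "chr1" & tc$strand == "+"], 100)
  expect_equal(tc$pos[tc$chrom == "chr1" & tc$strand == "-"], 135)

  # 3-column files default to + strand
  path3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1 10 46", "chr1 20 56", "chr1 30 66"), path3)
  tc3 <- read_tags_bed(path3)
  expect_equal(attr(tc3, "library_size"), 3)
  expect_true(all(tc3$strand == "+"))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t46", "chr1\t50\t50"), bad)
  expect_error(read_tags_bed(bad), "line 2")
  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_error(read_tags_bed(empty), "empty")
})

test_that("tag collections round-trip through BED", {
  set.seed(42)
  tc <- make_tags(sample(c("chr1", "chr2"), 50, TRUE),
                  sample.int(1e5, 50),
                  sample(c("+", "-"), 50, TRUE))
  path <- withr::local_tempfile(fileext = ".bed")
  write_tags_bed(tc, path)
  back <- read_tags_bed(path, fragment_extension = 150, sample_id = "test")
  expect_equal(back$pos, tc$pos)
  expect_equal(back$strand, tc$strand)
  expect_equal(attr(back, "library_size"), attr(tc, "library_size"))
})

test_that("BED12 and GTF annotations parse to the same coordinate convention", {
  b12 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t1000\t5000\tgA\t0\t+\t1000\t5000\t0\t2\t500,1000,\t0,3000,",
    "chr1\t9000\t12000\tgB\t0\t-\t9000\t12000\t0\t1\t3000,\t0,"), b12)
  ann <- read_gene_annotation(b12, "bed12")
  expect_equal(ann$tss[ann$gene_id == "gA"], 1000)
  expect_equal(ann$tes[ann$gene_id == "gA"], 5000)
  expect_equal(ann$exon_length[ann$gene_id == "gA"], 1500)
  expect_equal(ann$tss[ann$gene_id == "gB"], 12000)

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "gX";',
    'chr1\tsrc\texon\t151\t250\t.\t+\t.\tgene_id "gX";'), gtf)
  ax <- read_gene_annotation(gtf, "gtf")
  # overlapping exons [100,200) and [150,250) union to [100,250)
  expect_equal(ax$exon_starts[[1]], 100)
  expect_equal(ax$exon_ends[[1]], 250)
  expect_equal(ax$exon_length, 150)

  dup <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t0\t100\tg\t0\t+\t0\t100\t0\t1\t100,\t0,",
    "chr1\t200\t300\tg\t0\t+\t200\t300\t0\t1\t100,\t0,"), dup)
  expect_error(read_gene_annotation(dup, "bed12"), "duplicate")

  noex <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id "gY";', noex)
  expect_error(read_gene_annotation(noex, "gtf"), "exon")
})

test_that("promoter and body windows follow the mark-specific geometry", {
  g <- make_genes(c("p", "m", "edge", "short"),
                  "chr1",
                  c(10000, 5000, 100, 10000),
                  c(20000, 9000, 5000, 10400),
                  c("+", "-", "+", "+"))
  pw3 <- promoter_window(g, "H3K4me3")
  # 1 kb window around the TSS for H3K4me3
  expect_equal(unlist(pw3[pw3$gene_id == "p", c("start", "end")],
                      use.names = FALSE), c(9500, 10500))
  # clipped at the chromosome start
  expect_equal(unlist(pw3[pw3$gene_id == "edge", c("start", "end")],
                      use.names = FALSE), c(0, 600))
  # 3 kb window for H3K4me1, TSS of a - gene is its end coordinate
  pw1 <- promoter_window(g, "H3K4me1")
  expect_equal(unlist(pw1[pw1$gene_id == "m", c("start", "end")],
                      use.names = FALSE), c(7500, 10500))

  bw <- gene_body_window(g, "H3K4me3")
  expect_equal(unlist(bw[bw$gene_id == "p", c("start", "end")],
                      use.names = FALSE), c(10500, 20000))
  expect_equal(unlist(bw[bw$gene_id == "m", c("start", "end")],
                      use.names = FALSE), c(5000, 8500))
  expect_true(bw$short[bw$gene_id == "short"])
  expect_false(any(bw$short[bw$gene_id != "short"]))
})

test_that("promoter and body windows are disjoint, end at the TES, and mirror", {
  set.seed(7)
  n <- 50
  start <- sample.int(5e5, n) + 2e4
  len <- sample(2000:50000, n)
  g <- make_genes(sprintf("g%02d", 1:n), "chr1", start, start + len,
                  sample(c("+", "-"), n, TRUE))
  for (mk in c("H3K4me3", "H3K4me1")) {
    pw <- promoter_window(g, mk)
    bw <- gene_body_window(g, mk)
    ok <- !bw$short
    # windows abut without overlap and the union is contiguous up to the TES
    plus <- g$strand == "+"
    expect_equal(bw$start[ok & plus], pw$end[ok & plus])
    expect_equal(bw$end[ok & plus], g$tes[ok & plus])
    expect_equal(bw$end[ok & !plus], pw$start[ok & !plus])
    expect_equal(bw$start[ok & !plus], g$tes[ok & !plus])
    # strand mirror about an arbitrary pivot
    P <- 2e6
    gm <- make_genes(g$gene_id, "chr1", P - g$end, P - g$start,
                     ifelse(g$strand == "+", "-", "+"))
    gm <- gm[match(g$gene_id, gm$gene_id), ]
    pwm <- promoter_window(gm, mk)
    expect_equal(pwm$start, P - pw$end)
    expect_equal(pwm$end, P - pw$start)
    bwm <- gene_body_window(gm, mk)
    expect_equal(bwm$start[ok], P - bw$end[ok])
    expect_equal(bwm$end[ok], P - bw$start[ok])
  }
})

test_that("invalid gene models are rejected", {
  expect_error(make_genes(c("a", "a"), "chr1", c(0, 100), c(50, 200),
                          c("+", "+")), "duplicate")
  expect_error(make_genes("a", "chr1", 100, 100, "+"), "start < end")
  expect_error(gene_annotation(tibble::tibble(
    gene_id = "a", chrom = "chr1", start = 0, end = 100, strand = "+",
    exon_starts = list(c(0, 40)), exon_ends = list(c(50, 90)))),
    "disjoint")
})
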