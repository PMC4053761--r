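test_that("anchor profiles place signal in the correct bin and mirror by strand", {
  # + tag at a + anchor: extended fragment covers the first downstream bins
  tc <- make_tags("chr1", 50000, "+", ext = 150)
  anchors <- tibble::tibble(feature_id = "a1", chrom = "chr1", pos = 50000,
                            strand = "+")
  pm <- anchor_profile(tc, anchors, flank = 1000, bin = 100)
  nonzero <- pm[pm$value > 0, ]
  expect_equal(nonzero$position, c(50, 150))
  expect_equal(nonzero$value[1], (100 / 100) / (1 / 1e6))

  # a mirrored tag at a mirrored - anchor gives the identical profile
  P <- 200000
  tcm <- mirror_tags(tc, P)
  # boundary coordinates reflect as P - x (tag base indices as P - 1 - x)
  am <- tibble::tibble(feature_id = "a1", chrom = "chr1", pos = P - 50000,
                       strand = "-")
  pmm <- anchor_profile(tcm, am, flank = 1000, bin = 100)
  expect_equal(pmm$value, pm$value)
  expect_equal(pmm$position, pm$position)

  # column means define the average curve
  avg <- profile_summary(pm)
  expect_equal(avg$mean_value[avg$position == 50], nonzero$value[1])
})

test_that("metagene profiles are flat for uniform coverage and peaked for promoter-only signal", {
  g <- make_genes(c("gp", "gm"), "chr1", c(100000, 300000),
                  c(120000, 320000), c("+", "-"))
  # uniform dense coverage over gene bodies -> flat body profile
  tcu <- make_tags("chr1", c(seq(95000, 125000, by = 10),
                             seq(295000, 325000, by = 10)),
                   "+", ext = 150)
  mp <- metagene_profile(tcu, g, flank = 2000, bin = 100, n_body_bins = 50)
  body <- profile_summary(mp)
  body <- body[body$segment == "body", ]
  expect_lt(stats::sd(body$mean_value) / mean(body$mean_value), 0.02)

  # promoter-only signal concentrates at the TSS edge; distal body stays ~0
  tcp <- make_tags("chr1", c(rep(100000, 200), rep(319999, 200)),
                   rep(c("+", "-"), each = 200), ext = 150)
  mp2 <- metagene_profile(tcp, g, flank = 2000, bin = 100, n_body_bins = 50)
  s2 <- profile_summary(mp2)
  body2 <- s2$mean_value[s2$segment == "body"]
  expect_gt(max(body2[1:3]), 1000 * max(0.001, mean(body2[10:50])))
  expect_equal(mean(s2$mean_value[s2$segment == "downstream"]), 0)
})

test_that("metagene profiles are strand-mirror invariant and handle degenerate lengths", {
  set.seed(13)
  n <- 20
  start <- sort(sample.int(5e5, n)) * 3 + 1e5
  len <- sample(1500:9000, n)
  strand <- sample(c("+", "-"), n, TRUE)
  g <- make_genes(sprintf("g%02d", 1:n), "chr1", start, start + len, strand)
  tags <- make_tags("chr1", sample.int(2e6, 5000),
                    sample(c("+", "-"), 5000, TRUE))
  mp <- metagene_profile(tags, g, flank = 1000, bin = 100, n_body_bins = 30)

  P <- 4e6
  gm <- make_genes(g$gene_id, "chr1", P - g$end, P - g$start,
                   ifelse(g$strand == "+", "-", "+"))
  mpm <- metagene_profile(mirror_tags(tags, P), gm, flank = 1000, bin = 100,
                          n_body_bins = 30)
  a <- dplyr::arrange(tibble::as_tibble(mp), feature_id, position)
  b <- dplyr::arrange(tibble::as_tibble(mpm), feature_id, position)
  expect_identical(a$value, b$value)

  # gene of length exactly n_body_bins bp: every body bin is 1 bp
  g1 <- make_genes("tiny", "chr1", 10000, 10030, "+")
  mp1 <- metagene_profile(make_tags("chr1", 10010, "+"), g1, flank = 500,
                          bin = 100, n_body_bins = 30)
  expect_equal(sum(mp1$segment == "body"), 30)
  # a 150 bp tag at 10010 covers body bins [10010,10030): 20 bins at full height
  expect_equal(sum(mp1$value[mp1$segment == "body"] > 0), 20)

  # genes shorter than the bin count are excluded and reported
  gshort <- make_genes(c("ok", "small"), "chr1", c(1000, 50000),
                       c(31000, 50010), c("+", "+"))
  mps <- metagene_profile(tags, gshort, flank = 500, bin = 100, n_body_bins = 30)
  expect_equal(attr(mps, "excluded"), "small")
})

test_that("expression stratification ranks descending with deterministic ties and remainder", {
  g <- make_genes(sprintf("g%02d", 1:10), "chr1", (1:10) * 10000,
                  (1:10) * 10000 + 5000, "+")
  ex <- tibble::tibble(gene_id = g$gene_id,
                       expression = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
  s4 <- stratify_by_expression(g, ex, k = 4)
  # 10 genes, k = 4 -> groups of 2/2/2/4 (remainder to the last group)
  expect_equal(as.vector(table(s4$group)), c(2, 2, 2, 4))
  expect_equal(s4$gene_id[s4$group == 1], c("g01", "g02"))

  # ties broken lexicographically by gene_id
  ext <- tibble::tibble(gene_id = g$gene_id, expression = rep(1, 10))
  st <- stratify_by_expression(g, ext, k = 4)
  expect_equal(st$gene_id, sort(g$gene_id))

  # missing genes are excluded and reported
  sm <- stratify_by_expression(g, ex[1:8, ], k = 4)
  expect_equal(as.vector(table(sm$group)), c(2, 2, 2, 2))
  expect_equal(attr(sm, "excluded"), c("g09", "g10"))
})

test_that("fold-change profiles evaluate the formula and are antisymmetric", {
  set.seed(31)
  tc <- make_tags("chr1", sample.int(1e5, 2000), sample(c("+", "-"), 2000, TRUE))
  anchors <- tibble::tibble(feature_id = paste0("a", 1:10), chrom = "chr1",
                            pos = seq(10000, 90000, length.out = 10),
                            strand = "+")
  pa <- anchor_profile(tc, anchors, flank = 1000, bin = 100)
  expect_equal(fold_change_profile(pa, pa)$log2_ratio, rep(0, 20))

  pb <- pa
  pb$value <- 2 * pa$value
  fc <- fold_change_profile(pa, pb, pseudocount = 0)
  nz <- profile_summary(pa)$mean_value > 0
  expect_equal(fc$log2_ratio[nz], rep(1, sum(nz)))

  expect_equal(fold_change_profile(pb, pa, pseudocount = 0.1)$log2_ratio,
               -fold_change_profile(pa, pb, pseudocount = 0.1)$log2_ratio)

  pc <- anchor_profile(tc, anchors[1:5, ], flank = 1000, bin = 100)
  expect_error(fold_change_profile(pa, pc), "match")
})
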