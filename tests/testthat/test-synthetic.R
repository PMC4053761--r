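test_that("simulated genomes are deterministic, non-overlapping and intergenic for enhancers", {
  p <- tiny_params(seed = 5)
  g1 <- simulate_genome(p)
  g2 <- simulate_genome(p)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$enhancers, g2$enhancers)
  expect_identical(g1$gene_truth, g2$gene_truth)
  expect_equal(nrow(g1$genes), p$n_genes)

  # genes disjoint with the minimum gap, per chromosome
  for (ch in unique(g1$genes$chrom)) {
    gs <- g1$genes[g1$genes$chrom == ch, ]
    gs <- gs[order(gs$start), ]
    expect_true(all(gs$start[-1] - gs$end[-nrow(gs)] >= p$min_gene_gap))
    expect_lte(max(gs$end), p$chromosome_length)
  }

  # enhancers never overlap gene +/- margin
  kept <- filter_intergenic(g1$enhancers, g1$genes, margin = p$enhancer_margin)
  expect_equal(nrow(kept), nrow(g1$enhancers))

  # infeasible packing errors with advice
  expect_error(simulate_genome(sim_params(n_genes = 500,
                                          chromosome_length = 1e6, seed = 1)),
               "longer chromosomes")
})

test_that("simulated ChIP libraries are deterministic and conserve the library size", {
  p <- tiny_params(seed = 9)
  g <- simulate_genome(p)
  t1 <- simulate_chip(p, g, "control", "H3K4me3")
  t2 <- simulate_chip(p, g, "control", "H3K4me3")
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  expect_equal(nrow(t1), p$library_size)
  expect_equal(attr(t1, "library_size"), p$library_size)

  # byte-identical BED emission under a fixed seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_tags_bed(t1, f1); write_tags_bed(t2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # different conditions/marks use different substreams
  t3 <- simulate_chip(p, g, "knockdown", "H3K4me3")
  expect_false(identical(t1$pos, t3$pos))

  ec <- simulate_enhancer_chip(p, g, "control", marks = c("H3K4me1", "H3K27ac"))
  expect_equal(nrow(ec$H3K4me1), p$enhancer_library_size)
  expect_equal(nrow(ec$H3K27ac), p$enhancer_library_size)
})

test_that("spread fraction controls the spreading index distribution", {
  p <- tiny_params(seed = 13, spread_fraction = c(control = 0, knockdown = 1))
  g <- simulate_genome(p)
  t0 <- simulate_chip(p, g, "control", "H3K4me3")   # s = 0
  t1 <- simulate_chip(p, g, "knockdown", "H3K4me3") # s = 1
  si0 <- spreading_index(t0, g$genes)
  si1 <- spreading_index(t1, g$genes)
  # with no spreading the body holds only background; with full spreading the
  # promoter holds only background
  expect_lt(stats::median(si0$si), 0.2)
  expect_gt(stats::median(si1$si), 2)
})

test_that("injected spread changes are recovered from measured SI fold changes", {
  p <- sim_params(n_genes = 600, n_enhancers = 50, chromosome_length = 1.5e7,
                  library_size = 6e5, seed = 29)
  g <- simulate_genome(p)
  sic <- spreading_index(simulate_chip(p, g, "control", "H3K4me3"), g$genes)
  sik <- spreading_index(simulate_chip(p, g, "knockdown", "H3K4me3"), g$genes)
  fc <- si_fold_change(sic, sik)
  truth <- dplyr::inner_join(
    dplyr::mutate(true_spread(g, "knockdown"),
                  delta = spread - true_spread(g, "control")$spread),
    fc, by = "gene_id")
  fit <- stats::lm(log2_fold ~ delta, data = truth)
  expect_gt(stats::coef(fit)["delta"], 0)
  expect_lt(summary(fit)$coefficients["delta", 4], 1e-6)
})

test_that("simulated counts couple DE probability to spread change", {
  p <- tiny_params(seed = 31)
  g <- simulate_genome(p)
  cts <- simulate_counts(p, g)
  expect_identical(cts$counts, simulate_counts(p, g)$counts)
  expect_equal(nrow(cts$counts), p$n_genes)
  expect_equal(ncol(cts$counts), 2 + 2 * p$n_replicates)

  # truly DE genes concentrate at high spread-change rank by construction
  tr <- cts$truth
  r <- rank(tr$spread_delta) / nrow(tr)
  expect_gt(mean(r[tr$is_de]), mean(r[!tr$is_de]))

  # beta = 0 decouples DE from spreading
  p0 <- tiny_params(seed = 31, de_beta = 0)
  g0 <- simulate_genome(p0)
  tr0 <- simulate_counts(p0, g0)$truth
  expect_equal(length(unique(round(tr0$de_prob, 12))), 1)

  # dispersion -> 0 gives Poisson-like counts
  pp <- tiny_params(seed = 33, nb_dispersion = 0)
  cp <- simulate_counts(pp, simulate_genome(pp))
  ratio <- var(cp$counts$control_1 - cp$counts$control_2) /
    mean(cp$counts$control_1 + cp$counts$control_2)
  expect_equal(ratio, 1, tolerance = 0.15)
})

test_that("the H3K27ac coupling depresses acetylation where shores spread", {
  p <- sim_params(n_genes = 150, n_enhancers = 300, chromosome_length = 1.5e7,
                  library_size = 1e5, enhancer_library_size = 6e5, seed = 37)
  g <- simulate_genome(p)
  er <- enhancer_regions(g$enhancers, p$core_halfwidth, p$shore_outer)
  ac_c <- enhancer_spreading_index(
    simulate_enhancer_chip(p, g, "control", "H3K27ac")$H3K27ac, er)
  ac_t <- enhancer_spreading_index(
    simulate_enhancer_chip(p, g, "knockdown", "H3K27ac")$H3K27ac, er)
  truth <- true_enhancer_delta(g)
  meas <- log2((ac_t$core_density + 0.05) / (ac_c$core_density + 0.05))
  # gamma < 0: measured acetylation change tracks the injected change
  expect_gt(stats::cor(meas, truth$true_delta_ac_log2), 0.5)
  expect_lt(mean(meas), 0)

  # gamma = 0: H3K27ac is independent of shore spreading
  p0 <- sim_params(n_genes = 150, n_enhancers = 300, chromosome_length = 1.5e7,
                   library_size = 1e5, enhancer_library_size = 6e5,
                   h3k27ac_coupling = 0, seed = 37)
  g0 <- simulate_genome(p0)
  ac0c <- enhancer_spreading_index(
    simulate_enhancer_chip(p0, g0, "control", "H3K27ac")$H3K27ac, er)
  ac0t <- enhancer_spreading_index(
    simulate_enhancer_chip(p0, g0, "knockdown", "H3K27ac")$H3K27ac, er)
  meas0 <- log2((ac0t$core_density + 0.05) / (ac0c$core_density + 0.05))
  expect_lt(abs(stats::cor(meas0, truth$delta_shore)), 0.2)
})
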