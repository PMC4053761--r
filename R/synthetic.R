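# Seeded synthetic-data generator. It emulates the statistical structure the
# analysis assumes -- promoter-peaked H3K4 signal with condition-dependent
# spreading into gene bodies, enhancer-core signal with condition-dependent
# shore spreading coupled to H3K27ac loss, and expression changes coupled to
# spreading -- and records the injected ground truth so every pipeline stage
# can be tested against it without sequencing data. All randomness flows
# through sub-seeds derived deterministically from one master seed.

# Deterministic sub-seed (< 2^31) for a labelled operation.
substream_seed <- function(seed, label) {
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u)) %% 19997L
  (as.integer(seed) %% 100000L) * 20011L + h
}

#' Simulation parameters
#'
#' Defaults define the package's reference synthetic dataset: 2,000 genes on
#' 2 x 30 Mb chromosomes, 1,000 intergenic enhancers, 2e6 ChIP tags per
#' sample, a control gene-body spread fraction of 0.1 rising to 0.4 under
#' knockdown (and likewise for enhancer shores), negative coupling between
#' shore spreading and H3K27ac, and expression changes whose probability
#' rises with the injected spreading change.
#'
#' @param n_genes Number of genes (2000).
#' @param n_chromosomes Chromosomes (2).
#' @param chromosome_length Length of each chromosome in bp (3e7).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length
#'   parameters (median 10 kb, sdlog 0.4).
#' @param min_gene_gap Minimum inter-gene gap in bp (1e4).
#' @param n_enhancers Intergenic enhancers (1000).
#' @param enhancer_margin Minimum enhancer distance from any gene, bp (2000).
#' @param library_size ChIP tags per gene-mark sample (2e6).
#' @param background_rate Background tag weight per bp (0.008).
#' @param signal_tags_per_gene Mean signal tag weight per gene (750).
#' @param spread_fraction Named vector: gene-body spread fraction per
#'   condition (control 0.1, knockdown 0.4).
#' @param spread_multiplier_range Per-gene multiplier on the condition spread
#'   fraction, uniform (0.5, 1.5).
#' @param enhancer_library_size ChIP tags per enhancer-mark sample (1e6).
#' @param enhancer_signal_per_site Mean signal tag weight per enhancer (600).
#' @param enhancer_core_sd Gaussian SD of core signal around the summit, bp
#'   (250).
#' @param core_halfwidth,shore_outer Enhancer geometry in bp (500, 2000).
#' @param shore_fraction Named vector: shore spread fraction per condition
#'   (control 0.1, knockdown 0.4).
#' @param h3k27ac_coupling Coupling gamma <= 0: H3K27ac core mass is scaled
#'   by `exp(gamma * delta_shore_fraction)` (-2).
#' @param count_library_size Expected RNA-seq reads per sample (5e5).
#' @param n_replicates Replicates per condition (2).
#' @param nb_dispersion Negative-binomial dispersion (0.01, i.e. a
#'   biological coefficient of variation of 0.1; 0 gives Poisson counts).
#' @param expression_sdlog Log-normal sdlog of baseline expression (1).
#' @param de_alpha,de_beta Logistic intercept and slope of the probability a
#'   gene is truly DE as a function of its spread-change rank in (0, 1);
#'   defaults `qlogis(0.05)` and 2.
#' @param de_log2fc_range Magnitude range of true |log2 fold changes|,
#'   uniform (0.6, 2).
#' @param read_length Emitted BED record length, bp (36).
#' @param fragment_extension Tag extension used downstream, bp (150).
#' @param seed Master seed (mandatory for reproducibility).
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genes = 2000,
                       n_chromosomes = 2,
                       chromosome_length = 3e7,
                       gene_length_meanlog = log(1e4),
                       gene_length_sdlog = 0.4,
                       min_gene_gap = 1e4,
                       n_enhancers = 1000,
                       enhancer_margin = 2000,
                       library_size = 2e6,
                       background_rate = 0.008,
                       signal_tags_per_gene = 750,
                       spread_fraction = c(control = 0.1, knockdown = 0.4),
                       spread_multiplier_range = c(0.5, 1.5),
                       enhancer_library_size = 1e6,
                       enhancer_signal_per_site = 600,
                       enhancer_core_sd = 250,
                       core_halfwidth = 500,
                       shore_outer = 2000,
                       shore_fraction = c(control = 0.1, knockdown = 0.4),
                       h3k27ac_coupling = -2,
                       count_library_size = 5e5,
                       n_replicates = 2,
                       nb_dispersion = 0.01,
                       expression_sdlog = 1,
                       de_alpha = stats::qlogis(0.05),
                       de_beta = 2,
                       de_log2fc_range = c(0.6, 2),
                       read_length = 36,
                       fragment_extension = 150,
                       seed = 1) {
  p <- as.list(environment())
  if (is.null(p$seed) || !is.finite(p$seed)) abort("sim_params: seed is mandatory")
  if (any(p$spread_fraction < 0 | p$spread_fraction > 1) ||
      any(p$shore_fraction < 0 | p$shore_fraction > 1)) {
    abort("sim_params: spread fractions must lie in [0, 1]")
  }
  if (p$library_size < 1e4 || p$enhancer_library_size < 1e4) {
    abort("sim_params: library sizes must be >= 1e4")
  }
  if (p$nb_dispersion < 0) abort("sim_params: nb_dispersion must be >= 0")
  if (is.null(names(p$spread_fraction)) || is.null(names(p$shore_fraction))) {
    abort("sim_params: spread/shore fractions must be named by condition")
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> %d genes, %d enhancers on %d x %s bp; seed %d\n",
              x$n_genes, x$n_enhancers, x$n_chromosomes,
              format(x$chromosome_length, big.mark = ","),
              as.integer(x$seed)))
  invisible(x)
}

#' Simulate the genome: genes, enhancers and ground truth
#'
#' Genes are placed without overlap, with at least `min_gene_gap` bp between
#' neighbours, the residual space spread uniformly at random; enhancer
#' summits land in inter-gene gaps at least `enhancer_margin` bp from any
#' gene. Per-gene and per-enhancer latent quantities (expression weight,
#' spread multipliers, enhancer activity) are drawn here so all conditions
#' and marks share them.
#'
#' @param params A [sim_params()].
#' @return A `sim_genome` list: `genes` ([gene_annotation()]), `enhancers`
#'   ([peak_set()]), `gene_truth`, `enhancer_truth`, `chrom_lengths`,
#'   `params`.
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(substream_seed(params$seed, "genome"))
  n <- params$n_genes
  chroms <- paste0("chr", seq_len(params$n_chromosomes))
  per <- diff(floor(seq(0, n, length.out = params$n_chromosomes + 1)))
  lens <- pmax(2000, round(stats::rlnorm(n, params$gene_length_meanlog,
                                         params$gene_length_sdlog)))
  rows <- list(); gap_rows <- list()
  idx0 <- 0
  for (ci in seq_along(chroms)) {
    ng <- per[ci]
    gl <- lens[idx0 + seq_len(ng)]
    need <- sum(gl) + (ng + 1) * params$min_gene_gap
    if (need > params$chromosome_length) {
      abort(sprintf(
        "simulate_genome: %s cannot hold %d genes (need %d bp, have %d); use longer chromosomes",
        chroms[ci], ng, need, as.integer(params$chromosome_length)))
    }
    slack <- params$chromosome_length - need
    extra <- c(0, sort(stats::runif(ng, 0, slack)), slack)
    gaps <- params$min_gene_gap + diff(extra)  # ng + 1 gaps incl. both ends
    starts <- cumsum(gaps[seq_len(ng)]) + cumsum(c(0, gl[-ng]))
    rows[[ci]] <- tibble(chrom = chroms[ci],
                         start = floor(starts), end = floor(starts) + gl)
    # inter-gene gaps (including chromosome ends) for enhancer placement
    gs <- floor(starts); ge <- gs + gl
    gap_rows[[ci]] <- tibble(chrom = chroms[ci],
                             start = c(0, ge),
                             end = c(gs, params$chromosome_length))
    idx0 <- idx0 + ng
  }
  g <- bind_rows(rows)
  g$gene_id <- sprintf("g%04d", seq_len(n))
  g$strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- gene_annotation(g)
  gene_truth <- tibble(
    gene_id = g$gene_id,
    expression_weight = stats::rlnorm(n, 0, params$expression_sdlog),
    spread_multiplier = stats::runif(n, params$spread_multiplier_range[1],
                                     params$spread_multiplier_range[2]))
  # enhancers: uniform over gap space shrunk by the margin
  gaps <- bind_rows(gap_rows) |>
    mutate(start = .data$start + params$enhancer_margin + params$shore_outer,
           end = .data$end - params$enhancer_margin - params$shore_outer) |>
    filter(.data$end > .data$start)
  w <- gaps$end - gaps$start
  pick <- sample.int(nrow(gaps), params$n_enhancers, replace = TRUE, prob = w)
  summit <- floor(gaps$start[pick] + stats::runif(params$n_enhancers) * w[pick])
  enh <- peak_set(tibble(peak_id = sprintf("e%04d", seq_len(params$n_enhancers)),
                         chrom = gaps$chrom[pick],
                         start = summit - 200, end = summit + 200,
                         score = 0, summit = summit),
                  name = "synthetic_p300")
  enhancer_truth <- tibble(
    enhancer_id = enh$peak_id,
    activity = stats::rlnorm(params$n_enhancers, 0, 0.5),
    shore_multiplier = stats::runif(params$n_enhancers,
                                    params$spread_multiplier_range[1],
                                    params$spread_multiplier_range[2]))
  structure(list(genes = genes, enhancers = enh,
                 gene_truth = gene_truth, enhancer_truth = enhancer_truth,
                 chrom_lengths = stats::setNames(
                   rep(params$chromosome_length, length(chroms)), chroms),
                 params = params),
            class = "sim_genome")
}

#' True per-gene spread fraction under a condition
#' @param genome A `sim_genome`.
#' @param condition Condition name matching `params$spread_fraction`.
#' @return Tibble `gene_id`, `spread` (the fraction of the gene's signal
#'   placed in its body, clipped to [0, 1]).
#' @export
true_spread <- function(genome, condition) {
  f <- genome$params$spread_fraction[[condition]]
  tibble(gene_id = genome$gene_truth$gene_id,
         spread = pmin(1, pmax(0, f * genome$gene_truth$spread_multiplier)))
}

true_shore <- function(genome, condition) {
  f <- genome$params$shore_fraction[[condition]]
  pmin(1, pmax(0, f * genome$enhancer_truth$shore_multiplier))
}

# Draw one tag collection from component weights and per-component samplers.
# weights: numeric vector; draw_fun(i, k) returns k 5' midpoint positions and
# chromosomes for component i as a list(chrom, mid).
draw_tags <- function(total, weights, draw_fun, params, sample_id) {
  counts <- as.vector(stats::rmultinom(1, total, weights))
  parts <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    parts[[i]] <- draw_fun(i, counts[i])
  }
  parts <- parts[!vapply(parts, is.null, TRUE)]
  chrom <- unlist(lapply(parts, `[[`, "chrom"), use.names = FALSE)
  mid <- unlist(lapply(parts, `[[`, "mid"), use.names = FALSE)
  strand <- sample(c("+", "-"), length(mid), replace = TRUE)
  ext <- params$fragment_extension
  # the 5' position is placed so the extended fragment is centred on mid
  pos <- ifelse(strand == "+", mid - floor(ext / 2),
                mid + floor(ext / 2) - 1)
  L <- params$chromosome_length
  pos <- pmin(pmax(pos, 0), L - 1)
  tag_collection(tibble(chrom = chrom, pos = pos, strand = strand),
                 sample_id = sample_id,
                 fragment_extension = ext,
                 library_size = length(pos))
}

#' Simulate a gene-centred ChIP tag collection
#'
#' Tags are drawn from a mixture: a uniform genomic background, a Gaussian
#' promoter component centred on each TSS (SD = half the mark's promoter
#' half-width), and a uniform gene-body component. The per-gene body weight
#' is the condition's spread fraction times the gene's latent multiplier;
#' per-gene total signal is proportional to the gene's expression rank.
#' Exactly `library_size` tags are emitted.
#'
#' @param params A [sim_params()].
#' @param genome A `sim_genome` from [simulate_genome()].
#' @param condition Condition name (`"control"` or `"knockdown"` by
#'   default).
#' @param mark Mark name (sets the promoter component width).
#' @return A [tag_collection()] named `<mark>_<condition>`.
#' @export
simulate_chip <- function(params, genome, condition, mark = "H3K4me3") {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(substream_seed(params$seed, paste("chip", condition, mark)))
  genes <- genome$genes
  n <- nrow(genes)
  hw <- mark_halfwidth(mark)
  spread <- true_spread(genome, condition)$spread
  body <- gene_body_window(genes, mark)
  spread[body$short] <- 0  # short genes keep all signal at the promoter
  expr_rank <- rank(genome$gene_truth$expression_weight,
                    ties.method = "first")
  w_gene <- params$signal_tags_per_gene * expr_rank / mean(expr_rank)
  bg_w <- params$background_rate * params$chromosome_length *
    params$n_chromosomes
  weights <- c(bg_w, w_gene * (1 - spread), w_gene * spread)
  chroms <- names(genome$chrom_lengths)
  draw_fun <- function(i, k) {
    if (i == 1) {
      ch <- sample(chroms, k, replace = TRUE)
      list(chrom = ch, mid = floor(stats::runif(k, 0, params$chromosome_length)))
    } else if (i <= 1 + n) {
      gi <- i - 1
      list(chrom = rep(genes$chrom[gi], k),
           mid = round(stats::rnorm(k, genes$tss[gi], hw / 2)))
    } else {
      gi <- i - 1 - n
      list(chrom = rep(genes$chrom[gi], k),
           mid = floor(stats::runif(k, body$start[gi], body$end[gi])))
    }
  }
  draw_tags(params$library_size, weights, draw_fun, params,
            paste0(mark, "_", condition))
}

#' Simulate an input (background-only) tag collection
#'
#' @inheritParams simulate_chip
#' @return A [tag_collection()] of uniformly placed tags.
#' @export
simulate_input <- function(params, genome) {
  set.seed(substream_seed(params$seed, "input"))
  chroms <- names(genome$chrom_lengths)
  draw_fun <- function(i, k) {
    ch <- sample(chroms, k, replace = TRUE)
    list(chrom = ch, mid = floor(stats::runif(k, 0, params$chromosome_length)))
  }
  draw_tags(params$library_size, 1, draw_fun, params, "input")
}

#' Simulate enhancer-centred ChIP tag collections
#'
#' H3K4 marks mix a Gaussian core component around each summit with a
#' uniform shore component whose weight is the condition's shore fraction
#' times the enhancer's latent multiplier. H3K27ac is core-only, and its
#' per-enhancer mass is scaled by `exp(gamma * (shore_frac - shore_frac_control))`,
#' so with `gamma < 0` enhancers that gain shore spreading lose acetylation.
#'
#' @inheritParams simulate_chip
#' @param marks Collections to generate (default H3K4me1 and H3K27ac; any of
#'   H3K4me1/2/3 and H3K27ac).
#' @return Named list of [tag_collection()]s.
#' @export
simulate_enhancer_chip <- function(params, genome, condition,
                                   marks = c("H3K4me1", "H3K27ac")) {
  stopifnot(inherits(genome, "sim_genome"))
  enh <- genome$enhancers
  ne <- nrow(enh)
  sh_cond <- true_shore(genome, condition)
  sh_ctrl <- true_shore(genome, names(genome$params$shore_fraction)[1])
  chroms <- names(genome$chrom_lengths)
  bg_w <- params$background_rate * params$chromosome_length *
    params$n_chromosomes
  base_w <- params$enhancer_signal_per_site * genome$enhancer_truth$activity /
    mean(genome$enhancer_truth$activity)
  out <- list()
  for (mk in marks) {
    set.seed(substream_seed(params$seed, paste("enhchip", condition, mk)))
    if (mk == "H3K27ac") {
      w_site <- base_w * exp(params$h3k27ac_coupling * (sh_cond - sh_ctrl))
      weights <- c(bg_w, w_site)
      shore_of <- rep(0, ne)
    } else {
      weights <- c(bg_w, base_w * (1 - sh_cond), base_w * sh_cond)
      shore_of <- sh_cond
    }
    draw_fun <- function(i, k) {
      if (i == 1) {
        ch <- sample(chroms, k, replace = TRUE)
        return(list(chrom = ch,
                    mid = floor(stats::runif(k, 0, params$chromosome_length))))
      }
      if (i <= 1 + ne) {
        ei <- i - 1
        return(list(chrom = rep(enh$chrom[ei], k),
                    mid = round(stats::rnorm(k, enh$summit[ei],
                                             params$enhancer_core_sd))))
      }
      ei <- i - 1 - ne
      side <- sample(c(-1, 1), k, replace = TRUE)
      off <- floor(stats::runif(k, params$core_halfwidth, params$shore_outer))
      list(chrom = rep(enh$chrom[ei], k), mid = enh$summit[ei] + side * off)
    }
    out[[mk]] <- draw_tags(params$enhancer_library_size, weights, draw_fun,
                           params, paste0(mk, "_", condition))
  }
  out
}

#' True per-enhancer changes between two conditions
#'
#' @param genome A `sim_genome`.
#' @param control,treatment Condition names.
#' @return Tibble `enhancer_id`, `shore_control`, `shore_treatment`,
#'   `delta_shore`, `true_delta_ac_log2` (the injected log2 H3K27ac change,
#'   `gamma * delta_shore / log(2)`).
#' @export
true_enhancer_delta <- function(genome, control = "control",
                                treatment = "knockdown") {
  sc <- true_shore(genome, control)
  st <- true_shore(genome, treatment)
  tibble(enhancer_id = genome$enhancer_truth$enhancer_id,
         shore_control = sc, shore_treatment = st,
         delta_shore = st - sc,
         true_delta_ac_log2 = genome$params$h3k27ac_coupling * (st - sc) / log(2))
}

#' Simulate RNA-seq counts with spreading-coupled differential expression
#'
#' Baseline per-gene means are proportional to the latent expression
#' weights. Each gene is truly DE with probability
#' `plogis(de_alpha + de_beta * r)` where `r` in (0, 1) is the gene's rank of
#' injected spread change between the two conditions; DE genes receive a
#' log2 fold change drawn uniformly from `de_log2fc_range` with random sign,
#' applied to the treatment mean. Counts are negative-binomial with
#' dispersion `nb_dispersion` (Poisson when 0).
#'
#' @inheritParams simulate_chip
#' @param control,treatment Condition names (defaults control/knockdown).
#' @return List: `counts` (tibble `gene_id`, `length`, one column per
#'   sample, named `<condition>_<rep>`), `truth` (tibble `gene_id`,
#'   `spread_delta`, `de_prob`, `is_de`, `log2_fc`), `samples_control`,
#'   `samples_treatment`.
#' @export
simulate_counts <- function(params, genome, control = "control",
                            treatment = "knockdown") {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(substream_seed(params$seed, "counts"))
  n <- nrow(genome$genes)
  ds <- true_spread(genome, treatment)$spread -
    true_spread(genome, control)$spread
  r01 <- (rank(ds, ties.method = "first") - 0.5) / n
  de_prob <- stats::plogis(params$de_alpha + params$de_beta * r01)
  is_de <- stats::runif(n) < de_prob
  sign <- sample(c(-1, 1), n, replace = TRUE)
  lfc <- ifelse(is_de,
                sign * stats::runif(n, params$de_log2fc_range[1],
                                    params$de_log2fc_range[2]),
                0)
  w <- genome$gene_truth$expression_weight
  mu_a <- params$count_library_size * w / sum(w)
  mu_b_raw <- mu_a * 2^lfc
  mu_b <- mu_b_raw * params$count_library_size / sum(mu_b_raw)
  rcounts <- function(mu) {
    if (params$nb_dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / params$nb_dispersion)
  }
  counts <- tibble(gene_id = genome$genes$gene_id,
                   length = genome$genes$exon_length)
  sa <- paste0(control, "_", seq_len(params$n_replicates))
  sb <- paste0(treatment, "_", seq_len(params$n_replicates))
  for (s in sa) counts[[s]] <- rcounts(mu_a)
  for (s in sb) counts[[s]] <- rcounts(mu_b)
  list(counts = counts,
       truth = tibble(gene_id = genome$genes$gene_id,
                      spread_delta = ds, de_prob = de_prob,
                      is_de = is_de, log2_fc = lfc),
       samples_control = sa, samples_treatment = sb)
}

#' Write a simulated dataset to disk
#'
#' Emits the exact plain-text formats the readers consume: BED6 tag files,
#' BED12 genes, BED peaks, a counts TSV and truth TSVs.
#'
#' @param genome A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @param tag_collections Named list of [tag_collection()]s to write.
#' @param counts Optional result of [simulate_counts()].
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(genome, dir, tag_collections = list(),
                             counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  g <- genome$genes
  bed12 <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                   g$chrom, as.integer(g$start), as.integer(g$end), g$gene_id,
                   g$strand, as.integer(g$start), as.integer(g$end),
                   lengths(g$exon_starts),
                   vapply(seq_len(nrow(g)), function(i)
                     paste0(paste(as.integer(g$exon_ends[[i]] - g$exon_starts[[i]]),
                                  collapse = ","), ","), ""),
                   vapply(seq_len(nrow(g)), function(i)
                     paste0(paste(as.integer(g$exon_starts[[i]] - g$start[i]),
                                  collapse = ","), ","), ""))
  p <- file.path(dir, "genes.bed12"); writeLines(bed12, p); paths <- c(paths, p)
  e <- genome$enhancers
  p <- file.path(dir, "enhancers.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g", e$chrom, as.integer(e$start),
                     as.integer(e$end), e$peak_id, e$score), p)
  paths <- c(paths, p)
  for (nm in names(tag_collections)) {
    p <- file.path(dir, paste0(nm, ".bed"))
    write_tags_bed(tag_collections[[nm]], p,
                   read_length = genome$params$read_length)
    paths <- c(paths, p)
  }
  readr::write_tsv(genome$gene_truth, file.path(dir, "gene_truth.tsv"))
  readr::write_tsv(genome$enhancer_truth, file.path(dir, "enhancer_truth.tsv"))
  paths <- c(paths, file.path(dir, c("gene_truth.tsv", "enhancer_truth.tsv")))
  if (!is.null(counts)) {
    readr::write_tsv(counts$counts, file.path(dir, "counts.tsv"))
    readr::write_tsv(counts$truth, file.path(dir, "expression_truth.tsv"))
    paths <- c(paths, file.path(dir, c("counts.tsv", "expression_truth.tsv")))
  }
  invisible(paths)
}
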