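# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's interval machinery: plain loops over tags
# and pooled points.

# Extended interval of one tag (0-based half-open), clipped at 0.
oracle_tag_interval <- function(pos, strand, ext) {
  if (strand == "+") c(max(0, pos), pos + ext)
  else c(max(0, pos - ext + 1), pos + 1)
}

# Total extended-tag bp overlapping [start, end) on chrom, by plain loop.
oracle_overlap_bp <- function(tags, chrom, start, end) {
  ext <- attr(tags, "fragment_extension")
  total <- 0
  for (i in seq_len(nrow(tags))) {
    if (tags$chrom[i] != chrom) next
    ti <- oracle_tag_interval(tags$pos[i], tags$strand[i], ext)
    total <- total + max(0, min(end, ti[2]) - max(start, ti[1]))
  }
  total
}

oracle_density <- function(tags, chrom, start, end) {
  (oracle_overlap_bp(tags, chrom, start, end) / (end - start)) /
    (attr(tags, "library_size") / 1e6)
}

# Brute-force spreading index of one gene.
oracle_si <- function(tags, gene, halfwidth, epsilon = 0.05) {
  tss <- if (gene$strand == "+") gene$start else gene$end
  ps <- max(0, tss - halfwidth); pe <- tss + halfwidth
  if (gene$strand == "+") {
    bs <- tss + halfwidth; be <- gene$end
  } else {
    bs <- gene$start; be <- tss - halfwidth
  }
  pd <- oracle_density(tags, gene$chrom, ps, pe)
  bd <- oracle_density(tags, gene$chrom, bs, be)
  bd / max(pd, epsilon)
}

# Brute-force two-sample KS statistic over all pooled points.
oracle_ks_d <- function(a, b) {
  pts <- c(a, b)
  d <- 0
  for (x in pts) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# Quick tag collection from parallel vectors.
make_tags <- function(chrom, pos, strand = "+", ext = 150,
                      sample_id = "test", library_size = NULL) {
  n <- max(length(chrom), length(pos))
  df <- tibble::tibble(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
                       strand = rep_len(strand, n))
  tag_collection(df, sample_id = sample_id, fragment_extension = ext,
                 library_size = library_size %||% n)
}

`%||%` <- rlang::`%||%`

# Single-exon gene annotation from vectors.
make_genes <- function(gene_id, chrom, start, end, strand) {
  gene_annotation(tibble::tibble(gene_id = gene_id, chrom = chrom,
                                 start = start, end = end, strand = strand))
}

# Small deterministic sim_params for fast tests.
tiny_params <- function(seed = 11, ...) {
  sim_params(n_genes = 120, n_enhancers = 80, chromosome_length = 8e6,
             library_size = 1e5, enhancer_library_size = 1e5,
             count_library_size = 5e4, seed = seed, ...)
}

# Reflect a tag collection about pivot P on its chromosome(s): base x -> P-1-x,
# strand flipped. Exact mirror partner for strand-invariance tests.
mirror_tags <- function(tags, pivot) {
  tag_collection(
    tibble::tibble(chrom = tags$chrom, pos = pivot - 1 - tags$pos,
                   strand = ifelse(tags$strand == "+", "-", "+")),
    sample_id = attr(tags, "sample_id"),
    fragment_extension = attr(tags, "fragment_extension"),
    library_size = attr(tags, "library_size"))
}
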