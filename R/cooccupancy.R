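# Promoter occupancy calls, Venn overlap counts, bivalency, and the
# sample-sample promoter-density correlation matrix with hierarchical
# clustering.

#' Promoter occupancy by a peak set
#'
#' A gene's promoter is occupied if any peak overlaps the window
#' `[tss - window, tss + window)` by at least 1 bp (0-based half-open, so a
#' peak exactly abutting the window does not count).
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_annotation()].
#' @param window Half-width of the promoter window in bp (default 2000).
#' @return Tibble `gene_id`, `occupied`.
#' @export
promoter_occupancy <- function(peaks, genes, window = 2000) {
  stopifnot(window > 0)
  occ <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0) next
    pr <- IRanges::IRanges(start = pk$start + 1, end = pk$end)
    gr <- IRanges::IRanges(start = pmax(0, genes$tss[gi] - window) + 1,
                           end = genes$tss[gi] + window)
    occ[gi] <- IRanges::countOverlaps(gr, pr) > 0
  }
  tibble(gene_id = genes$gene_id, occupied = occ)
}

#' Venn region counts for 2-4 occupancy sets
#'
#' @param occupancy Data frame with `gene_id` and 2-4 logical columns, one
#'   per sample/mark, on a common gene universe.
#' @return Tibble with one row per membership pattern (including the
#'   all-absent region) and its `count`; counts sum to the universe size.
#' @export
venn_counts <- function(occupancy) {
  stopifnot(is.data.frame(occupancy))
  sets <- setdiff(names(occupancy), "gene_id")
  sets <- sets[vapply(occupancy[sets], is.logical, TRUE)]
  if (length(sets) < 2 || length(sets) > 4) {
    abort("venn_counts: need 2-4 logical set columns")
  }
  flags <- occupancy[sets]
  if (anyNA(flags)) abort("venn_counts: occupancy vectors contain NA")
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  names(grid) <- sets
  key <- do.call(paste, c(flags, sep = "/"))
  gkey <- do.call(paste, c(grid, sep = "/"))
  cnt <- table(factor(key, levels = gkey))
  out <- as_tibble(grid)
  out$count <- as.integer(cnt)
  out
}

#' Bivalent genes: H3K4me3 and H3K27me3 co-occupancy
#'
#' A bivalent gene carries both the activating H3K4me3 and the repressive
#' H3K27me3 mark at its promoter: the logical AND of the two occupancy
#' calls.
#'
#' @param k4_occ,k27_occ Occupancy tibbles from [promoter_occupancy()] on
#'   the same gene universe.
#' @return Tibble `gene_id`, `bivalent`.
#' @export
bivalent_genes <- function(k4_occ, k27_occ) {
  if (!setequal(k4_occ$gene_id, k27_occ$gene_id)) {
    abort("bivalent_genes: gene universes differ")
  }
  m <- inner_join(k4_occ, k27_occ, by = "gene_id",
                  suffix = c("_k4", "_k27"))
  tibble(gene_id = m$gene_id,
         bivalent = m$occupied_k4 & m$occupied_k27)
}

#' Promoter density matrix across samples
#'
#' RPBM density over the `[tss - window, tss + window)` promoter of every
#' gene, one column per tag collection.
#'
#' @param samples Named list of [tag_collection()]s (>= 2); unnamed lists use
#'   the collections' sample ids.
#' @param genes A [gene_annotation()].
#' @param window Promoter half-width in bp (default 2000).
#' @return Tibble `gene_id` plus one density column per sample.
#' @export
promoter_density_matrix <- function(samples, genes, window = 2000) {
  if (length(samples) < 2) abort("promoter_density_matrix: need >= 2 samples")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- vapply(samples, function(s) attr(s, "sample_id"), "")
  }
  prom <- tibble(chrom = genes$chrom,
                 start = pmax(0, genes$tss - window),
                 end = genes$tss + window)
  out <- tibble(gene_id = genes$gene_id)
  for (nm in names(samples)) {
    out[[nm]] <- interval_density(samples[[nm]], prom)$density
  }
  out
}

#' Correlate samples on log promoter densities and cluster
#'
#' Pearson correlation of `log2(density + pseudocount)` between all sample
#' pairs, followed by average-linkage hierarchical clustering on the
#' `1 - r` distance. Samples are ordered alphabetically before clustering so
#' the result is invariant to the input column order.
#'
#' @param mat Density matrix from [promoter_density_matrix()] (`gene_id`
#'   plus numeric sample columns).
#' @param pseudocount RPBM pseudocount before the log (default 0.1).
#' @return A `chromspread_clust`: list with `correlation` (matrix),
#'   `hclust`, `leaf_order` (sample labels) and `newick` (dendrogram
#'   string); has [tidy()] and [glance()] methods.
#' @export
correlate_and_cluster <- function(mat, pseudocount = 0.1) {
  cols <- setdiff(names(mat), "gene_id")
  if (length(cols) < 2) abort("correlate_and_cluster: need >= 2 samples")
  cols <- sort(cols)
  x <- log2(as.matrix(mat[cols]) + pseudocount)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("correlate_and_cluster: sample %s has constant density",
                  cols[sds == 0][1]))
  }
  r <- stats::cor(x, method = "pearson")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  nwk <- if (requireNamespace("ape", quietly = TRUE)) {
    ape::write.tree(ape::as.phylo(hc))
  } else {
    NA_character_
  }
  structure(list(correlation = r, hclust = hc,
                 leaf_order = hc$labels[hc$order], newick = nwk),
            class = "chromspread_clust")
}

#' @export
print.chromspread_clust <- function(x, ...) {
  cat("<chromspread_clust>", ncol(x$correlation), "samples; leaf order:",
      paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.chromspread_clust <- function(x, ...) {
  r <- x$correlation
  idx <- which(upper.tri(r), arr.ind = TRUE)
  tibble(sample_a = rownames(r)[idx[, 1]],
         sample_b = colnames(r)[idx[, 2]],
         correlation = r[idx])
}

#' @export
glance.chromspread_clust <- function(x, ...) {
  off <- x$correlation[upper.tri(x$correlation)]
  tibble(n_samples = ncol(x$correlation),
         min_correlation = min(off), max_correlation = max(off))
}
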