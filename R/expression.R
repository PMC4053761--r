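# RPKM quantification and threshold-based differential-expression calling.
# The built-in caller is a per-gene exact binomial test on pooled counts: a
# deliberate, documented stand-in that models sampling noise only. For real
# data with biological replicates the canonical path is a precomputed DE
# table from a negative-binomial framework (see as_de_result()).

#' Reads per kilobase of exon model per million reads
#'
#' `RPKM = 1e9 * count / (library_size * exon_length)`.
#'
#' @param count Non-negative read counts.
#' @param exon_length Exon-model lengths in bp (> 0).
#' @param library_size Mapped reads in the library (> 0).
#' @return RPKM values.
#' @export
rpkm <- function(count, exon_length, library_size) {
  if (any(exon_length <= 0)) abort("rpkm: exon_length must be > 0")
  if (any(library_size <= 0)) abort("rpkm: library_size must be > 0")
  if (any(count < 0)) abort("rpkm: counts must be >= 0")
  1e9 * count / (library_size * exon_length)
}

#' Call differentially expressed genes between two conditions
#'
#' Counts are pooled within each condition and each gene is tested with a
#' two-sided exact binomial test of the condition-B count against the
#' library-size-ratio expectation; p-values are Benjamini-Hochberg
#' corrected. A gene is differentially expressed when all three hold: fold
#' change above `fold_threshold` (in either direction), FDR below
#' `fdr_threshold`, and the larger group-mean RPKM above `min_rpkm`. Genes
#' with zero counts in both conditions get no test and are excluded from
#' the BH correction.
#'
#' The binomial test models sampling noise only; with biologically variable
#' replicates it is anticonservative, and a replicate-aware DE table should
#' be supplied via [as_de_result()] instead.
#'
#' @param counts Data frame with `gene_id`, `length` (exon-model bp) and one
#'   integer count column per sample.
#' @param samples_a,samples_b Column names of the two conditions (control,
#'   treatment).
#' @param fold_threshold Fold-change threshold (default 1.5).
#' @param fdr_threshold FDR threshold (default 0.001).
#' @param min_rpkm Expression floor on the larger group-mean RPKM
#'   (default 1).
#' @param pseudocount RPKM pseudocount for the fold change (default 0.1).
#' @return A `de_result` tibble: `gene_id`, pooled `count_a`/`count_b`,
#'   `mean_rpkm_a`/`mean_rpkm_b`, `log2_fc`, `p_value`, `fdr`, `is_de`.
#' @export
call_de <- function(counts, samples_a, samples_b, fold_threshold = 1.5,
                    fdr_threshold = 0.001, min_rpkm = 1, pseudocount = 0.1) {
  stopifnot(is.data.frame(counts), length(samples_a) >= 1,
            length(samples_b) >= 1)
  miss <- setdiff(c(samples_a, samples_b), names(counts))
  if (length(miss) > 0) {
    abort(paste0("call_de: missing sample column(s): ",
                 paste(miss, collapse = ", ")))
  }
  ca <- as.matrix(counts[samples_a]); cb <- as.matrix(counts[samples_b])
  if (any(ca < 0) || any(cb < 0)) abort("call_de: negative counts")
  lib_a <- sum(ca); lib_b <- sum(cb)
  if (lib_a < 1 || lib_b < 1) abort("call_de: empty condition")
  a <- rowSums(ca); b <- rowSums(cb)
  p0 <- lib_b / (lib_a + lib_b)
  n <- a + b
  pval <- rep(NA_real_, length(n))
  testable <- n > 0
  pval[testable] <- vapply(which(testable), function(i) {
    stats::binom.test(b[i], n[i], p = p0)$p.value
  }, 0)
  fdr <- rep(NA_real_, length(n))
  fdr[testable] <- stats::p.adjust(pval[testable], method = "BH")
  rpkm_a <- rpkm(ca, counts$length, rep(colSums(ca), each = nrow(ca)))
  rpkm_b <- rpkm(cb, counts$length, rep(colSums(cb), each = nrow(cb)))
  mean_a <- rowMeans(matrix(rpkm_a, nrow = nrow(ca)))
  mean_b <- rowMeans(matrix(rpkm_b, nrow = nrow(cb)))
  log2_fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  is_de <- testable & !is.na(fdr) & fdr < fdr_threshold &
    abs(log2_fc) > log2(fold_threshold) &
    pmax(mean_a, mean_b) > min_rpkm
  out <- tibble(gene_id = counts$gene_id,
                count_a = a, count_b = b,
                mean_rpkm_a = mean_a, mean_rpkm_b = mean_b,
                log2_fc = log2_fc, p_value = pval, fdr = fdr,
                is_de = is_de)
  structure(out, class = c("de_result", class(tibble())),
            fold_threshold = fold_threshold, fdr_threshold = fdr_threshold,
            min_rpkm = min_rpkm, lib_a = lib_a, lib_b = lib_b)
}

#' Adopt a precomputed differential-expression table
#'
#' Takes a replicate-aware DE table (e.g. from a negative-binomial exact
#' test) verbatim and applies the pipeline's thresholds to flag DE genes.
#'
#' @param table Data frame with `gene_id`, `log2_fc`, `fdr` and optionally
#'   `mean_rpkm` (used for the expression floor when present).
#' @inheritParams call_de
#' @return A `de_result` tibble with `is_de` recomputed from the thresholds.
#' @export
as_de_result <- function(table, fold_threshold = 1.5, fdr_threshold = 0.001,
                         min_rpkm = 1) {
  need <- c("gene_id", "log2_fc", "fdr")
  if (!all(need %in% names(table))) {
    abort(paste0("as_de_result: need columns ", paste(need, collapse = ", ")))
  }
  out <- as_tibble(table)
  floor_ok <- if ("mean_rpkm" %in% names(out)) out$mean_rpkm > min_rpkm else TRUE
  out$is_de <- !is.na(out$fdr) & out$fdr < fdr_threshold &
    abs(out$log2_fc) > log2(fold_threshold) & floor_ok
  structure(out, class = c("de_result", class(tibble())),
            fold_threshold = fold_threshold, fdr_threshold = fdr_threshold,
            min_rpkm = min_rpkm)
}

#' @export
glance.de_result <- function(x, ...) {
  tested <- if ("p_value" %in% names(x)) x$p_value else x$fdr
  tibble(n_genes = nrow(x),
         n_tested = sum(!is.na(tested)),
         n_de = sum(x$is_de),
         n_up = sum(x$is_de & x$log2_fc > 0),
         n_down = sum(x$is_de & x$log2_fc < 0),
         fold_threshold = attr(x, "fold_threshold"),
         fdr_threshold = attr(x, "fdr_threshold"),
         min_rpkm = attr(x, "min_rpkm"))
}
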