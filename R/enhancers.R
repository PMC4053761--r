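# Enhancer core/shore analysis. Enhancers are p300-bound sites (peak
# summits); the core is a symmetric window around the summit, the shores are
# the immediately flanking regions on both sides. The enhancer spreading
# index is shore density over core density, and changes in shore spreading
# are related to changes in core H3K27ac (the enhancer-activity readout).

#' Enhancer core and shore geometry
#'
#' @param peaks A [peak_set()] of p300 (or other enhancer-proxy) sites.
#' @param core_halfwidth Core half-width in bp (default 500).
#' @param shore_outer Outer edge of the shores in bp from the summit
#'   (default 2000); must exceed `core_halfwidth`.
#' @return An `enhancer_table` tibble: `enhancer_id`, `chrom`, `summit`,
#'   `core_start`, `core_end`, `shore_left_start`, `shore_left_end`,
#'   `shore_right_start`, `shore_right_end` (shores disjoint from the core).
#' @export
enhancer_regions <- function(peaks, core_halfwidth = 500, shore_outer = 2000) {
  if (shore_outer <= core_halfwidth) {
    abort("enhancer_regions: shore_outer must exceed core_halfwidth")
  }
  tibble(enhancer_id = peaks$peak_id,
         chrom = peaks$chrom,
         summit = peaks$summit,
         core_start = pmax(0, peaks$summit - core_halfwidth),
         core_end = peaks$summit + core_halfwidth,
         shore_left_start = pmax(0, peaks$summit - shore_outer),
         shore_left_end = pmax(0, peaks$summit - core_halfwidth),
         shore_right_start = peaks$summit + core_halfwidth,
         shore_right_end = peaks$summit + shore_outer)
}

#' Enhancer spreading index: shore over core density
#'
#' Core and shore densities are exact RPBM interval densities; the shore
#' density pools both shores (total overlap bp over total shore length), and
#' `si = shore_density / max(core_density, epsilon)`.
#'
#' @param tags A [tag_collection()].
#' @param enhancers An `enhancer_table` from [enhancer_regions()], or a
#'   [peak_set()] (converted with default geometry).
#' @param epsilon Core-density floor in RPBM (default 0.05).
#' @return Tibble `enhancer_id`, `condition`, `core_density`,
#'   `shore_density`, `si`.
#' @export
enhancer_spreading_index <- function(tags, enhancers, epsilon = 0.05) {
  if (!"core_start" %in% names(enhancers)) {
    enhancers <- enhancer_regions(enhancers)
  }
  core <- interval_density(tags, tibble(chrom = enhancers$chrom,
                                        start = enhancers$core_start,
                                        end = enhancers$core_end))$density
  ov_l <- overlap_bp(tags, tibble(chrom = enhancers$chrom,
                                  start = enhancers$shore_left_start,
                                  end = pmax(enhancers$shore_left_end,
                                             enhancers$shore_left_start + 1)))
  len_l <- enhancers$shore_left_end - enhancers$shore_left_start
  ov_l[len_l <= 0] <- 0
  ov_r <- overlap_bp(tags, tibble(chrom = enhancers$chrom,
                                  start = enhancers$shore_right_start,
                                  end = enhancers$shore_right_end))
  len_r <- enhancers$shore_right_end - enhancers$shore_right_start
  # pooled shores: total overlap bp over total shore length
  shore <- ((ov_l + ov_r) / (pmax(len_l, 0) + len_r)) /
    (attr(tags, "library_size") / 1e6)
  tibble(enhancer_id = enhancers$enhancer_id,
         condition = attr(tags, "sample_id"),
         core_density = core,
         shore_density = shore,
         si = shore / pmax(core, epsilon))
}

#' Order enhancers by a signal and split into groups
#'
#' Enhancers are ranked by descending density of `signal` (typically
#' H3K27ac) over `summit +/- window`, with ties broken by id, and split into
#' `k` equal-size groups (remainder to the last group), as in
#' [stratify_by_expression()]. Group 1 is the top fraction (e.g. top 25%
#' H3K27ac for `k = 4`).
#'
#' @param peaks A [peak_set()] or `enhancer_table`.
#' @param signal A [tag_collection()] of the sorting mark.
#' @param window Half-width of the scored window in bp (default 500).
#' @param k Number of groups (default 4).
#' @return Tibble `enhancer_id`, `signal_density`, `rank`, `group`.
#' @export
sort_enhancers_by_signal <- function(peaks, signal, window = 500, k = 4) {
  id <- if ("enhancer_id" %in% names(peaks)) peaks$enhancer_id else peaks$peak_id
  if (length(id) < k) abort("sort_enhancers_by_signal: fewer enhancers than groups")
  d <- interval_density(signal, tibble(chrom = peaks$chrom,
                                       start = pmax(0, peaks$summit - window),
                                       end = peaks$summit + window))$density
  out <- tibble(enhancer_id = id, signal_density = d) |>
    arrange(desc(.data$signal_density), .data$enhancer_id)
  n <- nrow(out)
  size <- floor(n / k)
  grp <- rep(k, n)
  grp[seq_len(size * (k - 1))] <- rep(seq_len(k - 1), each = size)
  mutate(out, rank = row_number(), group = grp)
}

#' Per-enhancer changes in spreading and acetylation
#'
#' Combines spreading-index tables for an H3K4 mark in two conditions with
#' H3K27ac core densities in the same conditions into per-enhancer log2
#' changes: `delta_si = log2((si_t + p)/(si_c + p))` and `delta_ac` likewise
#' on the H3K27ac core density.
#'
#' @param si_control,si_treatment Tibbles from [enhancer_spreading_index()]
#'   for the H3K4 mark.
#' @param ac_control,ac_treatment Tibbles from [enhancer_spreading_index()]
#'   for H3K27ac (only `core_density` is used: H3K27ac is read out at the
#'   element itself).
#' @param pseudocount Pseudocount for both ratios (default 0.05).
#' @return Tibble `enhancer_id`, `si_control`, `si_treatment`, `delta_si`,
#'   `ac_control`, `ac_treatment`, `delta_ac`.
#' @export
enhancer_delta <- function(si_control, si_treatment, ac_control, ac_treatment,
                           pseudocount = 0.05) {
  m <- tibble(enhancer_id = si_control$enhancer_id, si_control = si_control$si) |>
    inner_join(tibble(enhancer_id = si_treatment$enhancer_id,
                      si_treatment = si_treatment$si), by = "enhancer_id") |>
    inner_join(tibble(enhancer_id = ac_control$enhancer_id,
                      ac_control = ac_control$core_density), by = "enhancer_id") |>
    inner_join(tibble(enhancer_id = ac_treatment$enhancer_id,
                      ac_treatment = ac_treatment$core_density), by = "enhancer_id")
  if (nrow(m) == 0) abort("enhancer_delta: no enhancers in common")
  mutate(m,
         delta_si = log2((.data$si_treatment + pseudocount) /
                           (.data$si_control + pseudocount)),
         delta_ac = log2((.data$ac_treatment + pseudocount) /
                           (.data$ac_control + pseudocount)))
}

#' Shore spreading versus enhancer activity
#'
#' Splits enhancers at the median change in spreading index into low- and
#' high-spreading groups and compares the two groups' distributions of
#' H3K27ac change with ECDFs and a two-sample Kolmogorov-Smirnov test. A
#' left-shifted high-group ECDF means enhancers that gained shore H3K4
#' methylation systematically lost acetylation.
#'
#' @param delta Tibble from [enhancer_delta()] (needs `enhancer_id`,
#'   `delta_si`, `delta_ac`).
#' @return A `shore_shift` object: `groups` (the input with a
#'   low/high `group` column), `ecdf_low`, `ecdf_high` (tables of
#'   `delta_ac`), and `ks` (a `chromspread_ks`); has [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
shore_spreading_vs_acetylation <- function(delta) {
  med <- stats::median(delta$delta_si)
  grp <- ifelse(delta$delta_si > med, "high", "low")
  if (min(table(factor(grp, levels = c("low", "high")))) < 2) {
    abort("shore_spreading_vs_acetylation: need >= 2 enhancers per group")
  }
  groups <- mutate(as_tibble(delta), group = grp)
  lo <- groups$delta_ac[groups$group == "low"]
  hi <- groups$delta_ac[groups$group == "high"]
  structure(list(groups = groups,
                 ecdf_low = ecdf_table(lo),
                 ecdf_high = ecdf_table(hi),
                 ks = ks_two_sample(hi, lo),
                 median_delta_si = med),
            class = "shore_shift")
}

#' @export
print.shore_shift <- function(x, ...) {
  cat(sprintf("<shore_shift> %d enhancers split at median delta-SI %.3g\n",
              nrow(x$groups), x$median_delta_si))
  cat(sprintf("  median delta-H3K27ac: low %.3g, high %.3g\n",
              stats::median(x$groups$delta_ac[x$groups$group == "low"]),
              stats::median(x$groups$delta_ac[x$groups$group == "high"])))
  print(x$ks)
  invisible(x)
}

#' @export
tidy.shore_shift <- function(x, ...) {
  x$groups |>
    group_by(.data$group) |>
    summarise(n = n(),
              median_delta_si = stats::median(.data$delta_si),
              median_delta_ac = stats::median(.data$delta_ac),
              .groups = "drop")
}

#' @export
glance.shore_shift <- function(x, ...) {
  tibble(n = nrow(x$groups),
         ks_statistic = x$ks$statistic,
         ks_p_value = x$ks$p_value,
         median_shift = stats::median(x$groups$delta_ac[x$groups$group == "high"]) -
           stats::median(x$groups$delta_ac[x$groups$group == "low"]))
}

#' Keep only intergenic peaks
#'
#' Drops peaks overlapping any gene extended by `margin` bp on both sides.
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_annotation()].
#' @param margin Gene margin in bp (default 2000).
#' @return The intergenic subset of `peaks`.
#' @export
filter_intergenic <- function(peaks, genes, margin = 2000) {
  keep <- rep(TRUE, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gs <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(gs) == 0) next
    gr <- IRanges::IRanges(start = pmax(0, gs$start - margin) + 1,
                           end = gs$end + margin)
    pr <- IRanges::IRanges(start = peaks$start[pi] + 1, end = peaks$end[pi])
    keep[pi] <- IRanges::countOverlaps(pr, gr) == 0
  }
  peaks[keep, , drop = FALSE]
}
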