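# Binned density tracks and exact per-interval densities. All densities are
# computed from extended tags: each 5' position is extended fragment_extension
# bp in its strand direction, clipped at the chromosome start.

# Extended-tag intervals (0-based half-open) for one chromosome of a
# tag_collection, as an IRanges (1-based closed, the Bioconductor convention).
tag_iranges <- function(tags, chrom) {
  ext <- attr(tags, "fragment_extension")
  sub <- tags[tags$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) return(IRanges::IRanges())
  plus <- sub$strand == "+"
  start0 <- ifelse(plus, sub$pos, sub$pos - ext + 1)
  start0 <- pmax(start0, 0)
  end0 <- ifelse(plus, sub$pos + ext, sub$pos + 1)
  IRanges::IRanges(start = start0 + 1, end = end0)
}

# Total extended-tag bp overlapping each query interval (0-based half-open
# tibble with chrom/start/end). Returns a double vector, one value per row.
overlap_bp <- function(tags, intervals) {
  out <- numeric(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    qi <- which(intervals$chrom == ch)
    tr <- tag_iranges(tags, ch)
    if (length(tr) == 0) next
    qr <- IRanges::IRanges(start = pmax(0, intervals$start[qi]) + 1,
                           end = intervals$end[qi])
    hits <- IRanges::findOverlaps(tr, qr)
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(tr[S4Vectors::queryHits(hits)],
                                             qr[S4Vectors::subjectHits(hits)]))
    acc <- rowsum(as.double(ov), S4Vectors::subjectHits(hits))
    out[qi[as.integer(rownames(acc))]] <- acc[, 1]
  }
  out
}

#' Exact per-interval tag density (RPBM)
#'
#' The density of a mark over an interval is the total extended-tag base
#' pairs overlapping it, divided by the interval length, per million mapped
#' tags: reads per base pair per million reads (RPBM). It is computed exactly
#' from the tags, not from a binned track, so there are no bin-edge
#' artifacts.
#'
#' @param tags A [tag_collection()].
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open, non-empty).
#' @return The input with a `density` column (RPBM) appended.
#' @export
interval_density <- function(tags, intervals) {
  stopifnot(is.data.frame(intervals))
  if (any(intervals$end <= intervals$start, na.rm = TRUE)) {
    abort("interval_density: intervals must be non-empty")
  }
  ov <- overlap_bp(tags, intervals)
  out <- as_tibble(intervals)
  out$density <- (ov / (intervals$end - intervals$start)) /
    (attr(tags, "library_size") / 1e6)
  out
}

# ---- binned tracks ----------------------------------------------------------

new_density_track <- function(df, bin_size, normalization, library_size,
                              sample_id) {
  structure(as_tibble(df),
            class = c("density_track", class(tibble())),
            bin_size = bin_size, normalization = normalization,
            library_size = library_size, sample_id = sample_id)
}

#' Binned raw coverage track
#'
#' Each extended tag contributes its bp overlap with each bin divided by the
#' bin size, so a fully contained tag of length L adds L/bin_size to its bin.
#' Values are average per-bp coverage within the bin.
#'
#' @param tags A [tag_collection()].
#' @param bin_size Bin width in bp (default 50).
#' @param chrom_lengths Optional named vector of chromosome lengths; tags
#'   extending beyond a declared length are clipped with a warning.
#' @return A `density_track` tibble (`chrom`, `start`, `end`, `value`) with
#'   normalization `"raw_count"`.
#' @export
compute_density <- function(tags, bin_size = 50, chrom_lengths = NULL) {
  stopifnot(bin_size >= 1)
  rows <- list()
  for (ch in sort(unique(tags$chrom))) {
    tr <- tag_iranges(tags, ch)
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(IRanges::end(tr))
    }
    if (any(IRanges::end(tr) > len)) {
      warning(sprintf("clipping %d tag(s) beyond %s length %d",
                      sum(IRanges::end(tr) > len), ch, as.integer(len)))
      tr <- IRanges::restrict(tr, start = 1L, end = as.integer(len))
      tr <- tr[IRanges::width(tr) > 0]
    }
    n_bins <- ceiling(len / bin_size)
    cov <- IRanges::coverage(tr, width = n_bins * bin_size)
    starts <- seq(1, n_bins * bin_size, by = bin_size)
    vs <- IRanges::viewSums(IRanges::Views(cov, start = starts,
                                           width = bin_size))
    rows[[ch]] <- tibble(chrom = ch,
                         start = as.double(starts - 1),
                         end = as.double(starts - 1 + bin_size),
                         value = as.double(vs) / bin_size)
  }
  new_density_track(bind_rows(rows), bin_size, "raw_count",
                    attr(tags, "library_size"), attr(tags, "sample_id"))
}

#' RPBM-normalize a raw coverage track
#'
#' Divides raw per-bp coverage by (library size / 1e6): reads per base pair
#' per million mapped reads.
#'
#' @param track A `density_track` with normalization `"raw_count"`.
#' @return The track with normalization `"RPBM"`.
#' @export
rpbm_normalize <- function(track) {
  if (!identical(attr(track, "normalization"), "raw_count")) {
    abort("rpbm_normalize expects a raw_count track")
  }
  lib <- attr(track, "library_size")
  if (is.null(lib) || lib < 1) abort("library_size must be >= 1")
  out <- track
  out$value <- track$value / (lib / 1e6)
  attr(out, "normalization") <- "RPBM"
  out
}

#' Input-normalized log2 ratio track
#'
#' @param treat,control RPBM-normalized `density_track`s on identical bins.
#' @param pseudocount Added to both densities before the ratio (default 0.1
#'   RPBM) so input-free bins stay finite.
#' @return A `density_track` with `value = log2((treat + p)/(control + p))`.
#' @export
log2_ratio_track <- function(treat, control, pseudocount = 0.1) {
  if (!identical(attr(treat, "bin_size"), attr(control, "bin_size"))) {
    abort("log2_ratio_track: bin sizes differ")
  }
  for (tr in list(treat, control)) {
    if (!identical(attr(tr, "normalization"), "RPBM")) {
      abort("log2_ratio_track expects RPBM tracks")
    }
  }
  m <- inner_join(treat, control, by = c("chrom", "start", "end"),
                  suffix = c("_t", "_c"))
  if (nrow(m) != nrow(treat) || nrow(m) != nrow(control)) {
    abort("log2_ratio_track: bins do not match between tracks")
  }
  out <- tibble(chrom = m$chrom, start = m$start, end = m$end,
                value = log2((m$value_t + pseudocount) /
                               (m$value_c + pseudocount)))
  new_density_track(out, attr(treat, "bin_size"), "log2_ratio",
                    NA_real_, paste0(attr(treat, "sample_id"), "/",
                                     attr(control, "sample_id")))
}

#' Write a density track as bedGraph
#' @param track A `density_track`.
#' @param path Output path (4 columns, 0-based half-open).
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", track$chrom,
                     as.integer(track$start), as.integer(track$end),
                     track$value), path)
  invisible(path)
}

# ---- minimal enrichment caller ---------------------------------------------

#' Minimal window-merging enrichment caller
#'
#' A deliberately simple island caller for synthetic pipelines: fixed
#' windows are scored by the library-normalized treat/control count ratio;
#' windows passing both a minimum tag count and the ratio threshold are
#' merged into islands, tolerating up to `gap` bp of unenriched windows
#' between them. It mimics the shape of SICER-style islands, not their
#' statistics; real peak calls should be supplied as inputs.
#'
#' @param tags Treatment [tag_collection()].
#' @param control Control/input [tag_collection()].
#' @param window Window size in bp (default 200).
#' @param gap Maximum unenriched span bridged within an island, bp (default
#'   400).
#' @param threshold Minimum library-normalized (treat+1)/(control+1) count
#'   ratio (default 2).
#' @param min_count Minimum treatment tag-equivalents per window (default 8)
#'   so sparse background windows cannot qualify by ratio alone.
#' @return A `peak_set`; the score is the island's maximum window ratio.
#' @export
simple_enrichment_caller <- function(tags, control, window = 200, gap = 400,
                                     threshold = 2, min_count = 8) {
  stopifnot(window >= 1)
  lib_t <- attr(tags, "library_size")
  lib_c <- attr(control, "library_size")
  scale <- lib_c / lib_t
  rows <- list()
  for (ch in sort(unique(tags$chrom))) {
    tr <- tag_iranges(tags, ch)
    if (length(tr) == 0) next
    len <- max(IRanges::end(tr))
    n_bins <- ceiling(len / window)
    starts0 <- (seq_len(n_bins) - 1) * window
    ivs <- tibble(chrom = ch, start = starts0, end = starts0 + window)
    cnt_t <- overlap_bp(tags, ivs) / attr(tags, "fragment_extension")
    cnt_c <- overlap_bp(control, ivs) / attr(control, "fragment_extension")
    ratio <- (cnt_t + 1) * scale / (cnt_c + 1)
    enriched <- ratio >= threshold & cnt_t >= min_count
    if (!any(enriched)) next
    idx <- which(enriched)
    gap_bins <- floor(gap / window)
    brk <- c(TRUE, diff(idx) > gap_bins + 1)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      members <- idx[grp == g]
      rows[[length(rows) + 1]] <- tibble(
        chrom = ch,
        start = starts0[members[1]],
        end = starts0[members[length(members)]] + window,
        score = max(ratio[members]))
    }
  }
  if (length(rows) == 0) {
    return(peak_set(tibble(chrom = character(), start = double(),
                           end = double(), score = double()),
                    name = paste0(attr(tags, "sample_id"), "_islands")))
  }
  peak_set(bind_rows(rows),
           name = paste0(attr(tags, "sample_id"), "_islands"))
}
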