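# Position-aligned signal matrices: fixed-flank anchor profiles (TSS,
# enhancer summit) and length-scaled TSS->TES metagene profiles. Profiles are
# stored long (feature_id, position, value) so they chain with dplyr; values
# are exact interval densities (RPBM), and genes are weighted equally when
# averaged.

new_profile_matrix <- function(df, anchor_kind, bin, extra = list()) {
  out <- structure(as_tibble(df),
                   class = c("profile_matrix", class(tibble())),
                   anchor_kind = anchor_kind, bin = bin)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Anchor-centered signal profile
#'
#' Density in fixed-width bins around a set of anchor positions (TSSs, peak
#' summits). Rows are oriented so that downstream of the anchor is rightward
#' for both strands; position labels are bin centers relative to the anchor
#' (negative = upstream).
#'
#' @param tags A [tag_collection()].
#' @param anchors Data frame with `feature_id`, `chrom`, `pos` and optionally
#'   `strand` (default `"+"`); anchors on chromosomes absent from the tags
#'   still yield zero rows, but anchors are never silently reordered.
#' @param flank Half-width of the profiled window in bp (default 5000); must
#'   be a multiple of `bin`.
#' @param bin Bin width in bp (default 100).
#' @return A `profile_matrix`: long tibble `feature_id`, `position`, `value`
#'   (RPBM), with `anchor_kind = "center"`.
#' @export
anchor_profile <- function(tags, anchors, flank = 5000, bin = 100) {
  stopifnot(is.data.frame(anchors), flank %% bin == 0, flank > 0)
  anchors <- as_tibble(anchors)
  if (!"strand" %in% names(anchors)) anchors$strand <- "+"
  if (!"feature_id" %in% names(anchors)) {
    anchors$feature_id <- paste0("a", seq_len(nrow(anchors)))
  }
  n_bins <- 2L * as.integer(flank / bin)
  centers <- -flank + (seq_len(n_bins) - 0.5) * bin
  n <- nrow(anchors)
  plus <- rep(anchors$strand == "+", each = n_bins)
  j <- rep(seq_len(n_bins), times = n)
  pos0 <- rep(anchors$pos, each = n_bins)
  start <- ifelse(plus, pos0 - flank + (j - 1) * bin,
                  pos0 + flank - j * bin)
  ivs <- tibble(chrom = rep(anchors$chrom, each = n_bins),
                start = start, end = start + bin)
  ov <- rep(0, nrow(ivs))
  valid <- ivs$end > 0
  ivs$start <- pmax(ivs$start, 0)
  nonempty <- valid & ivs$end > ivs$start
  ov[nonempty] <- overlap_bp(tags, ivs[nonempty, , drop = FALSE])
  value <- (ov / bin) / (attr(tags, "library_size") / 1e6)
  new_profile_matrix(
    tibble(feature_id = rep(anchors$feature_id, each = n_bins),
           position = rep(centers, times = n),
           value = value),
    anchor_kind = "center", bin = bin, extra = list(flank = flank))
}

#' Length-scaled TSS-to-TES metagene profile
#'
#' Fixed-width flank bins upstream of the TSS and downstream of the TES, with
#' the gene body divided into `n_body_bins` equal-length bins per gene so
#' genes of different lengths align. Genes shorter than `n_body_bins` bp are
#' excluded and reported via the `excluded` attribute.
#'
#' @param tags A [tag_collection()].
#' @param genes A [gene_annotation()].
#' @param flank Flank span in bp (default 5000), a multiple of `bin`.
#' @param bin Flank bin width in bp (default 100).
#' @param n_body_bins Number of scaled body bins (default 100).
#' @return A `profile_matrix` with `anchor_kind = "scaled_gene"`; `position`
#'   is the matrix column index and `segment` one of upstream/body/downstream.
#' @export
metagene_profile <- function(tags, genes, flank = 5000, bin = 100,
                             n_body_bins = 100) {
  stopifnot(flank %% bin == 0, n_body_bins >= 1)
  glen <- genes$end - genes$start
  keep <- glen >= n_body_bins
  excluded <- genes$gene_id[!keep]
  g <- genes[keep, , drop = FALSE]
  n_flank <- as.integer(flank / bin)
  n_tot <- 2L * n_flank + n_body_bins
  rows <- purrr::map(seq_len(nrow(g)), function(i) {
    s <- g$start[i]; e <- g$end[i]; plus <- g$strand[i] == "+"
    # body bin boundaries as offsets from the TSS along the transcription
    # direction, so + and - genes are exact mirrors of each other
    off <- floor((e - s) * (0:n_body_bins) / n_body_bins)
    if (plus) {
      body_start <- s + off[-length(off)]; body_end <- s + off[-1]
    } else {
      body_start <- e - off[-1]; body_end <- e - off[-length(off)]
    }
    up_start <- if (plus) s - flank + (seq_len(n_flank) - 1) * bin else
      e + flank - seq_len(n_flank) * bin
    down_start <- if (plus) e + (seq_len(n_flank) - 1) * bin else
      s - seq_len(n_flank) * bin
    tibble(gene_id = g$gene_id[i],
           chrom = g$chrom[i],
           position = seq_len(n_tot),
           segment = rep(c("upstream", "body", "downstream"),
                         c(n_flank, n_body_bins, n_flank)),
           start = c(up_start, body_start, down_start),
           end = c(up_start + bin, body_end, down_start + bin))
  })
  ivs <- bind_rows(rows)
  ov <- rep(0, nrow(ivs))
  ivs$start_c <- pmax(ivs$start, 0)
  ok <- ivs$end > ivs$start_c
  ovq <- overlap_bp(tags, tibble(chrom = ivs$chrom[ok],
                                 start = ivs$start_c[ok],
                                 end = ivs$end[ok]))
  ov[ok] <- ovq
  width <- pmax(ivs$end - ivs$start_c, 1)
  value <- (ov / width) / (attr(tags, "library_size") / 1e6)
  new_profile_matrix(
    tibble(feature_id = ivs$gene_id, position = ivs$position,
           segment = ivs$segment, value = value),
    anchor_kind = "scaled_gene", bin = bin,
    extra = list(flank = flank, n_body_bins = n_body_bins,
                 excluded = excluded))
}

#' Average profile curve
#'
#' Column means of a profile matrix, weighting features equally.
#'
#' @param profile A `profile_matrix`.
#' @return Tibble `position` (plus `segment` for metagene profiles) and
#'   `mean_value`.
#' @export
profile_summary <- function(profile) {
  keys <- intersect(c("position", "segment"), names(profile))
  profile |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(mean_value = mean(.data$value), .groups = "drop") |>
    arrange(.data$position)
}

#' Stratify genes by expression into equal-size groups
#'
#' Genes are ranked by expression descending (group 1 = highest expressed)
#' and split into `k` equal-size groups; the remainder goes to the last
#' (lowest) group. Ties are broken by `gene_id` so the split is
#' deterministic. Genes without an expression value are excluded and
#' reported via the `excluded` attribute.
#'
#' @param genes A [gene_annotation()] or data frame with `gene_id`.
#' @param expression Data frame with `gene_id` and `expression` (e.g. RPKM).
#' @param k Number of groups (default 4 for quartiles).
#' @return Tibble `gene_id`, `expression`, `rank`, `group` (1..k).
#' @export
stratify_by_expression <- function(genes, expression, k = 4) {
  stopifnot(k >= 2)
  m <- inner_join(tibble(gene_id = genes$gene_id), expression, by = "gene_id")
  excluded <- setdiff(genes$gene_id, m$gene_id)
  m <- arrange(m, desc(.data$expression), .data$gene_id)
  n <- nrow(m)
  if (n < k) abort("fewer genes than groups")
  size <- floor(n / k)
  grp <- rep(k, n)
  grp[seq_len(size * (k - 1))] <- rep(seq_len(k - 1), each = size)
  out <- mutate(m, rank = row_number(), group = grp)
  attr(out, "excluded") <- excluded
  out
}

#' Cross-condition log2 fold-change profile
#'
#' Per-position `log2((mean_B + p) / (mean_A + p))` between two profile
#' matrices with matched features and positions (e.g. knockdown over
#' control).
#'
#' @param profile_a Control `profile_matrix`.
#' @param profile_b Treatment `profile_matrix`.
#' @param pseudocount RPBM added to both means (default 0.1).
#' @return Tibble `position`, `mean_control`, `mean_treatment`, `log2_ratio`.
#' @export
fold_change_profile <- function(profile_a, profile_b, pseudocount = 0.1) {
  sa <- profile_summary(profile_a)
  sb <- profile_summary(profile_b)
  keys <- intersect(names(sa), c("position", "segment"))
  if (!identical(sa[keys], sb[keys]) ||
      !setequal(unique(profile_a$feature_id), unique(profile_b$feature_id))) {
    abort("fold_change_profile: positions or feature sets do not match")
  }
  tibble(position = sa$position,
         mean_control = sa$mean_value,
         mean_treatment = sb$mean_value,
         log2_ratio = log2((sb$mean_value + pseudocount) /
                             (sa$mean_value + pseudocount)))
}
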