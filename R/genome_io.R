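#' @importFrom rlang %||% abort .data
#' @importFrom dplyr arrange mutate filter select group_by summarise ungroup
#'   left_join inner_join bind_rows n dense_rank row_number desc across
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 map_int map_dbl pmap
NULL

# ---- tag collections --------------------------------------------------------

#' Build a tag collection from 5' read positions
#'
#' A tag collection is the atom of all density computation: the strand-aware
#' 5' position of every mapped read, one row per tag, sorted by chromosome and
#' position, together with the library size used for per-million normalization
#' and the number of base pairs each tag is extended in its strand direction
#' when counted against an interval.
#'
#' @param tags Data frame with columns `chrom`, `pos` (0-based 5' position)
#'   and `strand` (`"+"` or `"-"`).
#' @param sample_id Label for the sample the tags came from.
#' @param fragment_extension Base pairs each tag is extended in its strand
#'   direction before overlap counting. 150 bp is a conventional ChIP fragment
#'   proxy.
#' @param library_size Total mapped tag count; defaults to `nrow(tags)` and
#'   may be overridden when the collection is a subset of a larger library.
#' @return A `tag_collection`: a tibble of sorted tags carrying `sample_id`,
#'   `library_size` and `fragment_extension` as attributes.
#' @export
tag_collection <- function(tags, sample_id = "sample",
                           fragment_extension = 150,
                           library_size = nrow(tags)) {
  stopifnot(is.data.frame(tags))
  need <- c("chrom", "pos", "strand")
  if (!all(need %in% names(tags))) {
    abort(paste0("tags must have columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(tags) < 1) abort("tag collection is empty")
  if (!all(tags$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  if (any(!is.finite(tags$pos)) || any(tags$pos < 0)) {
    abort("tag positions must be finite and >= 0")
  }
  if (!is.numeric(library_size) || library_size < 1) {
    abort("library_size must be >= 1")
  }
  if (!is.numeric(fragment_extension) || fragment_extension < 1) {
    abort("fragment_extension must be >= 1")
  }
  out <- as_tibble(tags[, need])
  out$chrom <- as.character(out$chrom)
  out$pos <- as.double(out$pos)
  out <- arrange(out, .data$chrom, .data$pos)
  structure(out,
            class = c("tag_collection", class(tibble())),
            sample_id = as.character(sample_id),
            library_size = as.double(library_size),
            fragment_extension = as.double(fragment_extension))
}

#' @export
print.tag_collection <- function(x, ...) {
  cat(sprintf("<tag_collection> %s: %s tags on %d chromosome(s), library %s, extension %d bp\n",
              attr(x, "sample_id"),
              format(nrow(x), big.mark = ","),
              length(unique(x$chrom)),
              format(attr(x, "library_size"), big.mark = ","),
              as.integer(attr(x, "fragment_extension"))))
  NextMethod()
}

#' Library size of a tag collection
#' @param tags A `tag_collection`.
#' @return Scalar library size.
#' @export
library_size <- function(tags) attr(tags, "library_size")

split_fields <- function(lines) {
  strsplit(trimws(lines), "[ \t]+")
}

#' Read aligned-tag BED into a tag collection
#'
#' Each BED record is one mapped read; the tag's 5' position is `start` for
#' `+` strand records and `end - 1` for `-` strand records (0-based
#' half-open BED coordinates). Files with fewer than 6 columns default all
#' strands to `+`.
#'
#' @param path BED file (3+ or 6+ columns, whitespace-delimited).
#' @param fragment_extension See [tag_collection()].
#' @param sample_id Defaults to the file name without extension.
#' @return A `tag_collection` with `library_size` equal to the record count.
#' @export
read_tags_bed <- function(path, fragment_extension = 150,
                          sample_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty tag file: ", path))
  fields <- split_fields(lines)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                  which(nf < 3)[1], path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.double(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.double(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d in %s: need 0 <= start < end",
                  bad[1], path))
  }
  strand <- rep("+", length(lines))
  has6 <- nf >= 6
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  badst <- which(!strand %in% c("+", "-"))
  if (length(badst) > 0) {
    abort(sprintf("malformed BED line %d in %s: strand must be + or -",
                  badst[1], path))
  }
  pos <- ifelse(strand == "+", start, end - 1)
  tag_collection(tibble(chrom = chrom, pos = pos, strand = strand),
                 sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
                 fragment_extension = fragment_extension)
}

#' Write a tag collection as BED6
#'
#' Each tag is written as a `read_length`-bp record whose 5' end is the tag
#' position, so reading the file back with [read_tags_bed()] reproduces the
#' collection exactly.
#'
#' @param tags A `tag_collection`.
#' @param path Output path.
#' @param read_length Record length in bp (default 36, a typical short read).
#' @export
write_tags_bed <- function(tags, path, read_length = 36) {
  plus <- tags$strand == "+"
  start <- ifelse(plus, tags$pos, pmax(0, tags$pos - read_length + 1))
  end <- ifelse(plus, tags$pos + read_length, tags$pos + 1)
  out <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                 tags$chrom, as.integer(start), as.integer(end),
                 paste0("t", seq_len(nrow(tags))), tags$strand)
  writeLines(out, path)
  invisible(path)
}

# ---- marks ------------------------------------------------------------------

#' Promoter half-width for a histone mark
#'
#' H3K4me3 peaks tightly at promoters while H3K4me2 and H3K4me1 are
#' progressively broader, so the promoter bin is a 1 kb, 1.5 kb or 3 kb
#' window around the TSS for the three marks respectively. Any other mark
#' (e.g. H3K27me3 for co-occupancy calls) uses `default`.
#'
#' @param mark Mark name, e.g. `"H3K4me3"`.
#' @param default Half-width in bp for marks without a convention (2000).
#' @return Half-width in bp.
#' @export
mark_halfwidth <- function(mark, default = 2000) {
  known <- c(H3K4me3 = 500, H3K4me2 = 750, H3K4me1 = 1500)
  hw <- unname(known[mark])
  hw[is.na(hw)] <- default
  if (any(hw <= 0)) abort("promoter half-width must be > 0")
  hw
}

# ---- gene annotation --------------------------------------------------------

#' Construct a validated gene annotation
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), and optionally list-columns
#'   `exon_starts`/`exon_ends`. Genes without exon structure are treated as
#'   single-exon.
#' @return A `gene_annotation` tibble with derived columns `tss`, `tes`
#'   (strand-aware start/end of transcription) and `exon_length`.
#' @export
gene_annotation <- function(genes) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    abort(paste0("genes must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("duplicate gene_id: %s",
                  genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  if (!all(genes$strand %in% c("+", "-"))) abort("gene strand must be + or -")
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    abort("genes need 0 <= start < end")
  }
  g <- as_tibble(genes)
  if (!"exon_starts" %in% names(g)) {
    g$exon_starts <- map(g$start, identity)
    g$exon_ends <- map(g$end, identity)
  }
  ok <- pmap(list(g$exon_starts, g$exon_ends, g$start, g$end),
             function(es, ee, s, e) {
               length(es) == length(ee) && length(es) >= 1 &&
                 all(es < ee) && !is.unsorted(es) &&
                 all(es >= s) && all(ee <= e) &&
                 (length(es) == 1 || all(es[-1] >= ee[-length(ee)]))
             })
  if (!all(unlist(ok))) {
    abort(sprintf("gene %s: exons must be sorted, disjoint and inside the gene",
                  g$gene_id[!unlist(ok)][1]))
  }
  g$exon_length <- map_dbl(seq_len(nrow(g)),
                           function(i) sum(g$exon_ends[[i]] - g$exon_starts[[i]]))
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g$tes <- ifelse(g$strand == "+", g$end, g$start)
  g <- arrange(g, .data$chrom, .data$start)
  structure(g, class = c("gene_annotation", class(tibble())))
}

#' Read a gene annotation from BED12 or GTF
#'
#' BED12 yields one gene model per record (the `name` field is the gene id,
#' `thickStart`/`thickEnd` are ignored); block coordinates become exons. GTF
#' `exon` features are grouped by `gene_id` and their interval union becomes
#' the exon structure; 1-based inclusive GTF coordinates are converted to the
#' package's 0-based half-open convention on read.
#'
#' @param path Annotation file.
#' @param dialect `"bed12"` or `"gtf"`.
#' @return A `gene_annotation`.
#' @export
read_gene_annotation <- function(path, dialect = c("bed12", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed12") read_genes_bed12(path) else read_genes_gtf(path)
}

read_genes_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty annotation: ", path))
  fields <- split_fields(lines)
  if (any(lengths(fields) < 12)) {
    abort(sprintf("malformed BED12 line %d in %s",
                  which(lengths(fields) < 12)[1], path))
  }
  f <- function(i) vapply(fields, `[[`, "", i)
  start <- as.double(f(2)); end <- as.double(f(3))
  sizes <- map(f(11), function(s) as.double(strsplit(s, ",")[[1]]))
  offs <- map(f(12), function(s) as.double(strsplit(s, ",")[[1]]))
  nb <- as.integer(f(10))
  if (any(map_int(sizes, length) != nb) || any(map_int(offs, length) != nb)) {
    abort("BED12 blockCount does not match block lists")
  }
  exon_starts <- map2(start, offs, `+`)
  exon_ends <- map2(exon_starts, sizes, `+`)
  gene_annotation(tibble(
    gene_id = f(4), chrom = f(1), start = start, end = end, strand = f(6),
    exon_starts = exon_starts, exon_ends = exon_ends))
}

read_genes_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(paste0("empty annotation: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9)) {
    abort(sprintf("malformed GTF line %d in %s",
                  which(lengths(fields) < 9)[1], path))
  }
  f <- function(i) vapply(fields, `[[`, "", i)
  type <- f(3)
  attrs <- f(9)
  gid <- sub('.*gene_id[ ]+"([^"]+)".*', "\\1", attrs)
  if (any(gid == attrs)) {
    abort(sprintf("GTF line %d lacks a gene_id attribute",
                  which(gid == attrs)[1]))
  }
  is_exon <- type == "exon"
  if (!any(is_exon)) abort("GTF has no exon features")
  no_exon <- setdiff(unique(gid), unique(gid[is_exon]))
  if (length(no_exon) > 0) {
    abort(sprintf("GTF gene %s has no exon features", no_exon[1]))
  }
  ex <- tibble(gene_id = gid[is_exon],
               chrom = f(1)[is_exon],
               start = as.double(f(4)[is_exon]) - 1,  # GTF is 1-based inclusive
               end = as.double(f(5)[is_exon]),
               strand = f(7)[is_exon])
  per <- ex |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              exon_starts = list(interval_union(.data$start, .data$end)$start),
              exon_ends = list(interval_union(.data$start, .data$end)$end),
              .groups = "drop") |>
    mutate(start = map_dbl(.data$exon_starts, min),
           end = map_dbl(.data$exon_ends, max))
  gene_annotation(per)
}

# Union of possibly overlapping intervals (0-based half-open).
interval_union <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  us <- ue <- numeric(0)
  for (i in seq_along(start)) {
    if (length(us) > 0 && start[i] <= ue[length(ue)]) {
      ue[length(ue)] <- max(ue[length(ue)], end[i])
    } else {
      us <- c(us, start[i]); ue <- c(ue, end[i])
    }
  }
  list(start = us, end = ue)
}

# ---- peaks ------------------------------------------------------------------

#' Read a peak/island BED file
#'
#' @param path BED3+ file; column 4 (if present) is the peak name and column 5
#'   the score.
#' @param name Label for the peak set (defaults to file name).
#' @return A `peak_set` tibble with columns `peak_id`, `chrom`, `start`,
#'   `end`, `score`, `summit` (interval midpoint unless provided upstream).
#' @export
read_peaks_bed <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty peak file: ", path))
  fields <- split_fields(lines)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed peak BED line %d in %s", which(nf < 3)[1], path))
  }
  f <- function(i, default) {
    ifelse(nf >= i, vapply(fields, function(x) x[min(i, length(x))], ""), default)
  }
  start <- as.double(vapply(fields, `[[`, "", 2L))
  end <- as.double(vapply(fields, `[[`, "", 3L))
  if (any(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)) {
    abort(paste0("peak with start >= end in ", path))
  }
  score <- suppressWarnings(as.double(f(5, "0")))
  score[!is.finite(score)] <- 0
  peak_set(tibble(
    peak_id = ifelse(nf >= 4, f(4, ""), paste0("peak", seq_along(lines))),
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end, score = score),
    name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a peak set
#' @param peaks Data frame with `chrom`, `start`, `end` and optionally
#'   `peak_id`, `score`, `summit`.
#' @param name Label for the set.
#' @return A `peak_set` tibble sorted by position, with the summit defaulting
#'   to the interval midpoint.
#' @export
peak_set <- function(peaks, name = "peaks") {
  stopifnot(is.data.frame(peaks))
  if (!all(c("chrom", "start", "end") %in% names(peaks))) {
    abort("peaks must have chrom, start, end")
  }
  p <- as_tibble(peaks)
  if (any(p$start < 0) || any(p$start >= p$end)) {
    abort("peaks need 0 <= start < end")
  }
  if (!"peak_id" %in% names(p)) p$peak_id <- paste0("peak", seq_len(nrow(p)))
  if (!"score" %in% names(p)) p$score <- 0
  if (any(!is.finite(p$score))) abort("peak scores must be finite")
  if (!"summit" %in% names(p)) p$summit <- floor((p$start + p$end) / 2)
  p <- arrange(p, .data$chrom, .data$start)
  structure(p[, c("peak_id", "chrom", "start", "end", "score", "summit")],
            class = c("peak_set", class(tibble())), name = name)
}

# ---- promoter / gene-body windows ------------------------------------------

#' Promoter window around the TSS
#'
#' The promoter bin is a symmetric window around the TSS whose half-width
#' depends on the mark (see [mark_halfwidth()]), clipped at the chromosome
#' start.
#'
#' @param genes A `gene_annotation` (or compatible data frame with `gene_id`,
#'   `chrom`, `tss`, `strand`).
#' @param mark Mark name, or `halfwidth` to override directly.
#' @param halfwidth Optional explicit half-width in bp.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_window <- function(genes, mark = "H3K4me3", halfwidth = NULL) {
  hw <- halfwidth %||% mark_halfwidth(mark)
  tibble(gene_id = genes$gene_id,
         chrom = genes$chrom,
         start = pmax(0, genes$tss - hw),
         end = genes$tss + hw,
         strand = genes$strand)
}

#' Gene-body window: promoter edge to the TES
#'
#' The transcribed region downstream of the promoter bin, extending to the
#' TES. Genes too short to leave a non-empty body are flagged `short` and are
#' excluded from spreading-index analyses.
#'
#' @inheritParams promoter_window
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`, `short`;
#'   `start`/`end` are `NA` for short genes.
#' @export
gene_body_window <- function(genes, mark = "H3K4me3", halfwidth = NULL) {
  hw <- halfwidth %||% mark_halfwidth(mark)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss + hw, genes$start)
  end <- ifelse(plus, genes$end, genes$tss - hw)
  short <- start >= end
  tibble(gene_id = genes$gene_id,
         chrom = genes$chrom,
         start = ifelse(short, NA_real_, start),
         end = ifelse(short, NA_real_, end),
         strand = genes$strand,
         short = short)
}
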