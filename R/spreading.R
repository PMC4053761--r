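# The spreading index (SI) and its downstream statistics. The SI of a gene
# is the density of an H3K4 methylation mark in the gene body divided by its
# density in the promoter bin; an increase means methylation has spread away
# from the promoter. Cross-condition shifts are assessed with ECDFs and a
# two-sample Kolmogorov-Smirnov test, and coupling to differential expression
# or bivalency with sliding-window fractions along a ranked gene list.

#' Per-gene spreading index
#'
#' For every gene the promoter density (RPBM over the mark-specific promoter
#' bin, see [promoter_window()]) and gene-body density (promoter edge to the
#' TES, see [gene_body_window()]) are computed exactly from the tags, and
#' `si = body_density / max(promoter_density, epsilon)`. Genes too short to
#' have a body are excluded and reported via the `excluded_short` attribute.
#'
#' @param tags A [tag_collection()].
#' @param genes A [gene_annotation()].
#' @param mark Mark name; sets the promoter half-width (see
#'   [mark_halfwidth()]).
#' @param epsilon Promoter-density floor in RPBM (default 0.05) guarding
#'   against division by zero at unmarked promoters.
#' @param halfwidth Optional explicit promoter half-width in bp.
#' @return A `spreading_record` tibble: `gene_id`, `mark`, `condition` (the
#'   tag collection's sample id), `promoter_density`, `body_density`, `si`.
#' @export
spreading_index <- function(tags, genes, mark = "H3K4me3", epsilon = 0.05,
                            halfwidth = NULL) {
  prom <- promoter_window(genes, mark, halfwidth)
  body <- gene_body_window(genes, mark, halfwidth)
  keep <- !body$short
  pd <- interval_density(tags, prom[keep, c("chrom", "start", "end")])$density
  bd <- interval_density(tags, body[keep, c("chrom", "start", "end")])$density
  out <- tibble(gene_id = genes$gene_id[keep],
                mark = mark,
                condition = attr(tags, "sample_id"),
                promoter_density = pd,
                body_density = bd,
                si = bd / pmax(pd, epsilon))
  structure(out, class = c("spreading_record", class(tibble())),
            epsilon = epsilon,
            excluded_short = genes$gene_id[!keep])
}

#' Cross-condition spreading-index fold change
#'
#' Per-gene `(si_treatment + pseudocount) / (si_control + pseudocount)` over
#' the intersection of the two gene sets. Genes whose promoter density is
#' below the floor in both conditions carry no usable promoter signal and
#' are dropped.
#'
#' @param control,treatment `spreading_record` tibbles from
#'   [spreading_index()] (e.g. shLuc and shKdm5b).
#' @param pseudocount SI pseudocount (default 0.05).
#' @param min_promoter Promoter-density floor below which, in both
#'   conditions, a gene is excluded (default: the records' epsilon).
#' @return Tibble `gene_id`, `si_control`, `si_treatment`, `fold`,
#'   `log2_fold`, with attributes `n_common` and `n_dropped`.
#' @export
si_fold_change <- function(control, treatment, pseudocount = 0.05,
                           min_promoter = NULL) {
  eps <- min_promoter %||% attr(control, "epsilon") %||% 0.05
  m <- inner_join(
    tibble(gene_id = control$gene_id, si_control = control$si,
           prom_c = control$promoter_density),
    tibble(gene_id = treatment$gene_id, si_treatment = treatment$si,
           prom_t = treatment$promoter_density),
    by = "gene_id")
  if (nrow(m) == 0) abort("si_fold_change: no genes in common")
  n_common <- nrow(m)
  m <- filter(m, .data$prom_c >= eps | .data$prom_t >= eps)
  out <- tibble(gene_id = m$gene_id,
                si_control = m$si_control,
                si_treatment = m$si_treatment,
                fold = (m$si_treatment + pseudocount) /
                  (m$si_control + pseudocount))
  out$log2_fold <- log2(out$fold)
  attr(out, "n_common") <- n_common
  attr(out, "n_dropped") <- n_common - nrow(out)
  out
}

#' Empirical cumulative distribution table
#'
#' Right-continuous ECDF: `F(x) = (# values <= x) / n`, evaluated at the
#' sorted unique values.
#'
#' @param values Finite numeric vector, length >= 1.
#' @return Tibble `x`, `cum_fraction`.
#' @export
ecdf_table <- function(values) {
  if (length(values) == 0) abort("ecdf_table: empty input")
  if (any(!is.finite(values))) abort("ecdf_table: values must be finite")
  x <- sort(unique(values))
  tibble(x = x,
         cum_fraction = cumsum(tabulate(match(sort(values), x))) /
           length(values))
}

# Survival function of the Kolmogorov distribution, Q(lambda) = P(K > lambda).
# Standard two-branch evaluation: the Jacobi theta form for small lambda and
# the alternating exponential series otherwise, truncated at an absolute
# tolerance of 1e-6 (the conventional stopping rule for this distribution).
kolmogorov_sf <- function(lambda, tol = 1e-6) {
  if (lambda <= 0) return(1)
  if (lambda < 1) {
    k_max <- floor(sqrt(2 - log(tol)))
    k <- seq.int(1, by = 2, length.out = ceiling((k_max - 1) / 2))
    cdf <- sqrt(2 * pi) / lambda * sum(exp(-k^2 * pi^2 / (8 * lambda^2)))
    return(max(0, min(1, 1 - cdf)))
  }
  z <- -2 * lambda^2
  sgn <- -1; k <- 1; old <- 0; cdf <- 1
  while (abs(old - cdf) > tol) {
    old <- cdf
    cdf <- cdf + 2 * sgn * exp(z * k^2)
    sgn <- -sgn; k <- k + 1
  }
  max(0, min(1, 1 - cdf))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the exact supremum of `|F_a(x) - F_b(x)|` over the pooled sample
#' points; the p-value comes from the asymptotic Kolmogorov distribution at
#' `sqrt(n_eff) * D` with effective size `n_eff = n_a n_b / (n_a + n_b)`,
#' appropriate for the large gene and enhancer sets this package compares.
#'
#' @param a,b Finite numeric vectors, each of length >= 2.
#' @return A `chromspread_ks` object with elements `statistic` (D),
#'   `p_value`, `n_a`, `n_b`, `n_eff`; has [tidy()] and [glance()] methods.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("ks_two_sample: need n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("ks_two_sample: values must be finite")
  }
  sa <- sort(a); sb <- sort(b)
  pooled <- sort(unique(c(sa, sb)))
  fa <- findInterval(pooled, sa) / length(a)
  fb <- findInterval(pooled, sb) / length(b)
  d <- max(abs(fa - fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  p <- kolmogorov_sf(sqrt(n_eff) * d)
  structure(list(statistic = d, p_value = p,
                 n_a = length(a), n_b = length(b), n_eff = n_eff),
            class = "chromspread_ks")
}

#' @export
print.chromspread_ks <- function(x, ...) {
  cat(sprintf("Two-sample Kolmogorov-Smirnov: D = %.4g, p = %.3g (n = %d, %d)\n",
              x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' @export
tidy.chromspread_ks <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_a = x$n_a, n_b = x$n_b, n_eff = x$n_eff)
}

#' @export
glance.chromspread_ks <- function(x, ...) tidy.chromspread_ks(x)

#' Sliding-window fraction along a ranked gene list
#'
#' Genes are sorted ascending by an ordering statistic (e.g. SI fold change,
#' promoter density change) with ties broken by `gene_id`, and the fraction
#' of flagged genes (differentially expressed, bivalent, ...) is computed in
#' windows of `window` genes advanced by `step`.
#'
#' @param data Data frame with `gene_id`, an ordering column and a logical
#'   flag column.
#' @param order_by Name of the ordering column.
#' @param flag Name of the logical flag column.
#' @param window Window size in genes (default 1000, as for DE-coupling; 500
#'   is conventional for bivalency).
#' @param step Step in genes (default 1, maximally smooth).
#' @return A `sliding_window_series` tibble: `window_index`, `start_rank`,
#'   `center_rank`, `fraction` in [0, 1].
#' @export
sliding_window_fraction <- function(data, order_by, flag, window = 1000,
                                    step = 1) {
  stopifnot(is.data.frame(data), step >= 1)
  vals <- data[[order_by]]
  flags <- data[[flag]]
  if (is.null(vals) || is.null(flags)) {
    abort("sliding_window_fraction: ordering or flag column not found")
  }
  n <- nrow(data)
  if (window > n) abort("sliding_window_fraction: window larger than gene set")
  tie <- if ("gene_id" %in% names(data)) data$gene_id else seq_len(n)
  o <- order(vals, tie)
  flags <- as.logical(flags[o])
  cs <- c(0, cumsum(flags))
  starts <- seq(1, n - window + 1, by = step)
  frac <- (cs[starts + window] - cs[starts]) / window
  out <- tibble(window_index = seq_along(starts),
                start_rank = starts,
                center_rank = starts + (window - 1) / 2,
                fraction = frac)
  structure(out, class = c("sliding_window_series", class(tibble())),
            window = window, step = step, n_genes = n,
            order_by = order_by, flag = flag)
}

#' Classify per-gene density change between conditions
#'
#' Labels each gene `increased`, `no_change` or `decreased` from the
#' pseudocounted density ratio: increased if
#' `(treatment + p)/(control + p) >= up_fold`, decreased if `<= down_fold`.
#' Boundary values go to the changed class (a ratio of exactly `up_fold`
#' counts as increased).
#'
#' @param data Data frame holding both density columns.
#' @param control,treatment Names of the control and treatment density
#'   columns (RPBM).
#' @param up_fold,down_fold Symmetric thresholds, defaults 1.5 and 1/1.5.
#' @param pseudocount RPBM pseudocount (default 0.05).
#' @return The input with `ratio` and `change`
#'   (factor increased/no_change/decreased) appended.
#' @export
classify_density_change <- function(data, control, treatment,
                                    up_fold = 1.5, down_fold = 1 / 1.5,
                                    pseudocount = 0.05) {
  stopifnot(up_fold > 1, down_fold < 1)
  r <- (data[[treatment]] + pseudocount) / (data[[control]] + pseudocount)
  lab <- ifelse(r >= up_fold, "increased",
                ifelse(r <= down_fold, "decreased", "no_change"))
  out <- as_tibble(data)
  out$ratio <- r
  out$change <- factor(lab, levels = c("increased", "no_change", "decreased"))
  out
}
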