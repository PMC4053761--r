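# ggplot2 helpers for the package's result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_step geom_tile labs
#'   autoplot scale_fill_viridis_c theme_minimal
NULL

#' @export
autoplot.profile_matrix <- function(object, ...) {
  avg <- profile_summary(object)
  ggplot(avg, aes(x = .data$position, y = .data$mean_value)) +
    geom_line() +
    labs(x = if (identical(attr(object, "anchor_kind"), "scaled_gene"))
           "metagene bin (TSS → TES)" else "position relative to anchor (bp)",
         y = "mean density (RPBM)") +
    theme_minimal()
}

#' @export
autoplot.sliding_window_series <- function(object, ...) {
  ggplot(object, aes(x = .data$center_rank, y = 100 * .data$fraction)) +
    geom_line() +
    labs(x = paste0("gene rank by ", attr(object, "order_by"),
                    " (low → high)"),
         y = paste0("% ", attr(object, "flag"), " genes per ",
                    attr(object, "window"), "-gene window")) +
    theme_minimal()
}

#' @export
autoplot.shore_shift <- function(object, ...) {
  df <- bind_rows(
    mutate(object$ecdf_low, group = "low ΔSI"),
    mutate(object$ecdf_high, group = "high ΔSI"))
  ggplot(df, aes(x = .data$x, y = 100 * .data$cum_fraction,
                 colour = .data$group)) +
    geom_step() +
    labs(x = "ΔH3K27ac (log2)", y = "% enhancers below x",
         colour = NULL) +
    theme_minimal()
}

#' ECDF comparison of spreading indices between conditions
#'
#' The classic rightward-shift display: the cumulative fraction of genes
#' with SI below x, one curve per condition.
#'
#' @param ... Named `spreading_record` tibbles (names become curve labels;
#'   unnamed arguments use their `condition` column).
#' @return A ggplot.
#' @export
plot_si_ecdf <- function(...) {
  records <- list(...)
  nms <- names(records) %||% rep("", length(records))
  dfs <- purrr::map2(records, seq_along(records), function(r, i) {
    label <- if (nzchar(nms[i])) nms[i] else r$condition[1]
    mutate(ecdf_table(r$si), condition = label)
  })
  ggplot(bind_rows(dfs),
         aes(x = .data$x, y = 100 * .data$cum_fraction,
             colour = .data$condition)) +
    geom_step() +
    labs(x = "spreading index", y = "% genes below x", colour = NULL) +
    theme_minimal()
}

#' Heat map of a profile matrix
#'
#' Features in rows (ordered by `row_order` if given, e.g. expression or
#' H3K27ac rank, top first), positions in columns.
#'
#' @param profile A `profile_matrix`.
#' @param row_order Optional character vector of feature ids, top row first.
#' @return A ggplot.
#' @export
plot_profile_heatmap <- function(profile, row_order = NULL) {
  df <- as_tibble(profile)
  lev <- rev(row_order %||% unique(df$feature_id))
  df$feature_id <- factor(df$feature_id, levels = lev)
  df <- df[!is.na(df$feature_id), , drop = FALSE]
  ggplot(df, aes(x = .data$position, y = .data$feature_id,
                 fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = "RPBM") +
    labs(x = "position", y = NULL) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}
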