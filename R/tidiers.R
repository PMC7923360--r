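#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p_value`, `method`,
#'   `alternative`, `n_splits`, `n_a`, `n_b`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, method = x$method,
         alternative = x$alternative, n_splits = x$n_splits,
         n_a = x$n_a, n_b = x$n_b)
}

#' @rdname tidy.perm_test
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' Tidy a duplicate report
#'
#' @param x A `duplicate_report`.
#' @param ... Unused.
#' @return Tibble of flagged pairs with cluster membership and keeper flag
#'   columns joined on.
#' @method tidy duplicate_report
#' @export
tidy.duplicate_report <- function(x, ...) {
  if (length(x$clusters) == 0) {
    return(tibble(id = character(), cluster = integer(),
                  keeper = logical()))
  }
  purrr::imap_dfr(x$clusters, function(cl, k) {
    tibble(id = cl, cluster = k, keeper = cl %in% x$keepers)
  })
}

#' @rdname tidy.duplicate_report
#' @method glance duplicate_report
#' @export
glance.duplicate_report <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), n_clusters = length(x$clusters),
         n_dropped = length(x$drop), threshold = x$threshold)
}

#' Heatmap of an RDM
#'
#' @param object An `rdm`.
#' @param ... Unused.
#' @return A ggplot object (tile map of correlation distances).
#' @method autoplot rdm
#' @export
autoplot.rdm <- function(object, ...) {
  ids <- stimulus_ids(object)
  df <- as_tibble(as.data.frame(as.table(unclass(object))),
                  .name_repair = ~c("row", "col", "distance"))
  df$row <- factor(df$row, levels = rev(ids))
  df$col <- factor(df$col, levels = ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 2),
                                  name = "1 - Pearson r") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Line plot of per-layer selective-unit percentages
#'
#' @param fractions Data frame with `layer`, `percent` and optionally
#'   `instance` / `group` columns (e.g. stacked [layer_fractions()]
#'   results).
#' @return A ggplot object.
#' @export
plot_layer_fractions <- function(fractions) {
  fractions <- as_tibble(fractions)
  aes <- ggplot2::aes(x = .data$layer, y = .data$percent)
  if ("group" %in% names(fractions)) {
    aes$colour <- rlang::quo(.data$group)
  }
  p <- ggplot2::ggplot(fractions, aes)
  if ("instance" %in% names(fractions)) {
    p <- p + ggplot2::stat_summary(fun = mean, geom = "line") +
      ggplot2::stat_summary(fun = mean, geom = "point")
  } else {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = "network layer", y = "% selective units") +
    ggplot2::theme_minimal()
}

#' Receptive-field progression plot
#'
#' @param stack Output of [solve_kernels()] (needs `rf_deg` and
#'   `target_deg`) or [effective_rf()] with `rf_deg`.
#' @return A ggplot object of RF size (degrees) against layer.
#' @export
plot_rf_progression <- function(stack) {
  if (!"rf_deg" %in% names(stack)) {
    abort("`stack` needs an `rf_deg` column (supply `px_per_deg`).")
  }
  p <- ggplot2::ggplot(stack, ggplot2::aes(x = .data$layer)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rf_deg)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rf_deg))
  if ("target_deg" %in% names(stack)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$target_deg),
                                 shape = 4, colour = "red")
  }
  p + ggplot2::labs(x = "layer", y = "effective RF (deg)") +
    ggplot2::theme_minimal()
}
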