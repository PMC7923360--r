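#' Identify condition-selective network units
#'
#' In-silico electrophysiology: each unit's responses to condition A stimuli
#' (e.g. faces) are contrasted with its responses to condition B stimuli
#' (e.g. places) by a one-sided Wilcoxon rank-sum test (A > B; "selective"
#' is directional). P-values are corrected by Benjamini-Hochberg FDR across
#' all units of the whole network, and a unit is selective when its adjusted
#' p-value is below `alpha`. Units with identical constant responses in both
#' conditions carry no evidence and are never selective.
#'
#' @param responses_a,responses_b Numeric matrices, stimuli x units, with
#'   identical unit columns (typically 50 stimuli per condition).
#' @param layer_of_unit Optional integer vector assigning each unit to a
#'   network layer (carried into the result).
#' @param alpha Significance level on the FDR-adjusted p-value (default
#'   0.05).
#' @return Tibble with one row per unit: `unit`, `layer` (NA if not given),
#'   `p_value`, `p_fdr`, `selective`.
#' @export
selective_units <- function(responses_a, responses_b, layer_of_unit = NULL,
                            alpha = 0.05) {
  responses_a <- as.matrix(responses_a)
  responses_b <- as.matrix(responses_b)
  if (ncol(responses_a) != ncol(responses_b)) {
    abort("Conditions must cover the same units.")
  }
  if (nrow(responses_a) < 2 || nrow(responses_b) < 2) {
    abort("Need at least 2 stimuli per condition.")
  }
  m <- ncol(responses_a)
  if (!is.null(layer_of_unit) && length(layer_of_unit) != m) {
    abort("`layer_of_unit` must have one entry per unit.")
  }
  p <- vapply(seq_len(m), function(j) {
    a <- responses_a[, j]
    b <- responses_b[, j]
    if (max(c(a, b)) == min(c(a, b))) return(1)
    suppressWarnings(
      stats::wilcox.test(a, b, alternative = "greater")$p.value)
  }, numeric(1))
  p_fdr <- stats::p.adjust(p, method = "BH")
  tibble(
    unit = seq_len(m),
    layer = if (is.null(layer_of_unit)) NA_integer_
            else as.integer(layer_of_unit),
    p_value = p,
    p_fdr = p_fdr,
    selective = p_fdr < alpha
  )
}

#' Percentage of selective units per layer
#'
#' @param units Tibble from [selective_units()] with a non-missing `layer`
#'   column (or any data frame with logical `selective` and `layer`).
#' @return Tibble with `layer`, `n_units`, `n_selective`, `percent`
#'   (= 100 * selective / total within the layer).
#' @export
layer_fractions <- function(units) {
  units <- as_tibble(units)
  if (anyNA(units$layer)) {
    abort("Every unit needs a layer assignment; empty layers are invalid.")
  }
  units |>
    dplyr::group_by(layer = .data$layer) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      n_selective = sum(.data$selective),
      percent = 100 * sum(.data$selective) / dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$layer)
}

#' Compare per-layer selective fractions between training sets
#'
#' For each layer, a paired Wilcoxon signed-rank test on the per-instance
#' selective-unit percentages of the two groups (instances are paired by
#' index, i.e. by initialisation seed order), Bonferroni-corrected over
#' layers. Layers where every instance pair is tied give p = 1 by
#' convention.
#'
#' @param fractions_a,fractions_b Data frames with columns `instance`,
#'   `layer`, `percent` (e.g. row-bound [layer_fractions()] outputs per
#'   instance); both groups must have the same instances and layers.
#' @param alpha Significance level on the Bonferroni-adjusted p (default
#'   0.05).
#' @return Tibble with `layer`, `mean_a`, `mean_b`, `p_value`,
#'   `p_bonferroni`, `significant`.
#' @export
compare_groups <- function(fractions_a, fractions_b, alpha = 0.05) {
  fa <- dplyr::arrange(as_tibble(fractions_a), .data$layer, .data$instance)
  fb <- dplyr::arrange(as_tibble(fractions_b), .data$layer, .data$instance)
  if (!identical(fa$layer, fb$layer) || !identical(fa$instance, fb$instance)) {
    abort("Both groups must cover identical (instance, layer) cells.")
  }
  layers <- unique(fa$layer)
  res <- purrr::map_dfr(layers, function(l) {
    xa <- fa$percent[fa$layer == l]
    xb <- fb$percent[fb$layer == l]
    d <- xa - xb
    p <- if (all(d == 0)) 1 else {
      suppressWarnings(
        stats::wilcox.test(xa, xb, paired = TRUE)$p.value)
    }
    tibble(layer = l, mean_a = mean(xa), mean_b = mean(xb), p_value = p)
  })
  res$p_bonferroni <- bonferroni(res$p_value, m = length(layers))
  res$significant <- res$p_bonferroni < alpha
  res
}
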