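#' Frequency-concreteness index (FCI)
#'
#' The FCI combines how often a noun occurs in a spoken-language corpus with
#' how concrete human raters judge it to be. Both quantities are normalised by
#' their maximum over the candidate lexicon and averaged with equal weight:
#'
#' \deqn{FCI = 0.5 \frac{f}{\max f} + 0.5 \frac{c}{\max c}}
#'
#' so a word at both corpus maxima scores exactly 1 and the index lies in
#' (0, 1] for any word with positive frequency or concreteness.
#'
#' @param frequency Numeric vector of non-negative corpus occurrence counts.
#' @param concreteness Numeric vector of mean ratings on a 1-5 Likert scale.
#' @param max_frequency,max_concreteness Positive normalising maxima, normally
#'   the column maxima of the lexicon the words are drawn from.
#' @return Numeric vector of FCI values.
#' @examples
#' compute_fci(51e6, 5, max_frequency = 51e6, max_concreteness = 5)
#' @export
compute_fci <- function(frequency, concreteness, max_frequency,
                        max_concreteness) {
  stopifnot_scalar_number(max_frequency, "max_frequency")
  stopifnot_scalar_number(max_concreteness, "max_concreteness")
  if (max_frequency <= 0 || max_concreteness <= 0) {
    abort("Invalid lexicon table: normalising maxima must be > 0.")
  }
  if (any(frequency < 0, na.rm = TRUE)) {
    abort("`frequency` must be non-negative.")
  }
  if (any(concreteness < 1 | concreteness > 5, na.rm = TRUE)) {
    abort("`concreteness` must lie in [1, 5].")
  }
  0.5 * frequency / max_frequency + 0.5 * concreteness / max_concreteness
}

#' Add FCI values to a lexicon table
#'
#' @param lexicon Data frame with columns `word`, `frequency`, `concreteness`.
#'   Rows with missing concreteness are dropped with a warning (no rating
#'   means the word cannot be scored).
#' @return The lexicon as a tibble with an added `fci` column.
#' @examples
#' lex <- gen_lexicon(100, seed = 1)
#' add_fci(lex)
#' @export
add_fci <- function(lexicon) {
  lexicon <- as_tibble(lexicon)
  required <- c("word", "frequency", "concreteness")
  missing_cols <- setdiff(required, names(lexicon))
  if (length(missing_cols) > 0) {
    abort(paste0("`lexicon` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n_missing <- sum(is.na(lexicon$concreteness))
  if (n_missing > 0) {
    warn(sprintf("Dropping %d word(s) with missing concreteness rating.",
                 n_missing))
    lexicon <- dplyr::filter(lexicon, !is.na(.data$concreteness))
  }
  if (nrow(lexicon) == 0) {
    abort("Empty lexicon: nothing to score.")
  }
  max_f <- max(lexicon$frequency)
  max_c <- max(lexicon$concreteness)
  if (max_f <= 0 || max_c <= 0) {
    abort("Invalid lexicon table: column maxima must be > 0.")
  }
  dplyr::mutate(lexicon,
                fci = compute_fci(.data$frequency, .data$concreteness,
                                  max_f, max_c))
}

#' Select category candidates by concreteness and FCI rank
#'
#' Keeps words whose mean concreteness rating reaches `concreteness_min`
#' (default 4.0 on the 1-5 scale, i.e. clearly "physical things"), ranks them
#' by FCI and returns the top `top_n`. Ties in FCI are broken by higher
#' concreteness, then alphabetically by word, so the ranking is deterministic
#' and invariant to input order.
#'
#' @inheritParams add_fci
#' @param concreteness_min Minimum concreteness rating for inclusion.
#' @param top_n Number of top-ranked candidates to return.
#' @return Tibble with columns `word`, `frequency`, `concreteness`, `fci`,
#'   `rank`, sorted by rank. May be shorter than `top_n` (or empty) if few
#'   words pass the concreteness filter.
#' @examples
#' lex <- gen_lexicon(1000, seed = 1)
#' select_candidates(lex, concreteness_min = 4, top_n = 25)
#' @export
select_candidates <- function(lexicon, concreteness_min = 4.0,
                              top_n = 3500L) {
  stopifnot_scalar_number(concreteness_min, "concreteness_min")
  stopifnot_scalar_number(top_n, "top_n", lower = 0)
  scored <- add_fci(lexicon)
  scored |>
    dplyr::filter(.data$concreteness >= concreteness_min) |>
    dplyr::arrange(dplyr::desc(.data$fci), dplyr::desc(.data$concreteness),
                   .data$word) |>
    dplyr::slice_head(n = as.integer(top_n)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Read a lexicon table from delimited text
#'
#' @param path CSV/TSV file with columns `word`, `frequency`, `concreteness`.
#' @return Tibble with those columns.
#' @export
read_lexicon_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  as_tibble(tab)[, c("word", "frequency", "concreteness")]
}
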