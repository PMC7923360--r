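#' Category inventories
#'
#' A category inventory is a tibble with columns `category` (unique labels)
#' and `size` (image counts >= 1), plus a dataset name attribute. It is the
#' unit on which dataset trimming operates.
#'
#' @param category Character vector of unique category labels.
#' @param size Integer image counts, one per category, all >= 1.
#' @param name Dataset label.
#' @return Tibble of class `category_inventory`.
#' @export
category_inventory <- function(category, size, name = "dataset") {
  if (length(category) != length(size) || anyDuplicated(category)) {
    abort("`category` must be unique and match `size` in length.")
  }
  if (any(size < 1)) abort("All category sizes must be >= 1.")
  out <- tibble(category = as.character(category), size = as.integer(size))
  attr(out, "dataset") <- name
  class(out) <- c("category_inventory", class(out))
  out
}

#' Randomly subsample categories from an inventory
#'
#' Draws a uniformly random subset of `n` categories, reproducible under
#' `seed`.
#'
#' @param inv A [category_inventory()] (or data frame with `category`,
#'   `size`).
#' @param n Number of categories to keep; must not exceed the inventory.
#' @param seed Optional integer seed.
#' @return A `category_inventory` with `n` rows.
#' @export
subsample_categories <- function(inv, n, seed = NULL) {
  if (n > nrow(inv)) {
    abort("`n` exceeds the number of categories in the inventory.")
  }
  keep <- with_seed_(seed, sort(sample.int(nrow(inv), n)))
  out <- inv[keep, ]
  attr(out, "dataset") <- attr(inv, "dataset")
  out
}

#' Trim two inventories to identical category-size distributions
#'
#' Both inventories (which must already have equal category counts; use
#' [subsample_categories()] first) are sorted by size, largest first (ties
#' broken alphabetically by category name), and paired rank-wise: largest
#' with largest, and so on. Within each pair the larger category is
#' downsampled to the smaller one's count, so the trimmed datasets share the
#' category count and the exact distribution of images per category — the
#' sorted size vectors of both outputs equal the element-wise minimum of the
#' two sorted input vectors.
#'
#' Which images to drop is a uniform draw without replacement; the removal
#' plan records how many images each category loses so the caller can apply
#' it to an image manifest (see [subsample_ids()]).
#'
#' @param a,b `category_inventory` objects with equal category counts.
#' @param seed Optional integer seed recorded in the plan (image-level
#'   removal is delegated to [subsample_ids()] with this seed).
#' @return List with `a` and `b` (trimmed inventories) and `plan`, a tibble
#'   with columns `rank`, `category_a`, `size_a`, `category_b`, `size_b`,
#'   `target`, `remove_a`, `remove_b`.
#' @export
trim_pair <- function(a, b, seed = NULL) {
  if (nrow(a) != nrow(b)) {
    abort("Inventories must have equal category counts; subsample first.")
  }
  sort_inv <- function(x) {
    x[order(-x$size, x$category), ]
  }
  sa <- sort_inv(a)
  sb <- sort_inv(b)
  target <- pmin(sa$size, sb$size)
  plan <- tibble(
    rank = seq_len(nrow(sa)),
    category_a = sa$category, size_a = sa$size,
    category_b = sb$category, size_b = sb$size,
    target = target,
    remove_a = sa$size - target,
    remove_b = sb$size - target
  )
  attr(plan, "seed") <- seed
  ta <- category_inventory(sa$category, target,
                           name = attr(a, "dataset") %||% "a")
  tb <- category_inventory(sb$category, target,
                           name = attr(b, "dataset") %||% "b")
  list(a = ta, b = tb, plan = plan)
}

#' Uniformly downsample image ids to a target count
#'
#' @param ids Character vector of image ids in one category.
#' @param n Target count (<= `length(ids)`).
#' @param seed Optional integer seed.
#' @return Character vector of `n` retained ids (original order preserved).
#' @export
subsample_ids <- function(ids, n, seed = NULL) {
  if (n > length(ids)) abort("`n` exceeds the number of ids.")
  keep <- with_seed_(seed, sort(sample.int(length(ids), n)))
  ids[keep]
}

#' Write a trimming removal plan as JSON
#'
#' @param plan The `plan` element of [trim_pair()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trim_plan_json <- function(plan, path) {
  jsonlite::write_json(list(seed = attr(plan, "seed"), plan = plan),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
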