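#' Preprocess an image for duplicate detection
#'
#' Crops the central square (side `min(width, height)`), resizes it to
#' `side` x `side` pixels with bilinear interpolation, and flattens the
#' result channel-major (channel by channel, columns within channel) into a
#' feature vector. This is the representation on which per-category PCA and
#' pairwise correlation operate.
#'
#' @param pixels Numeric array `H x W x C` (or `H x W` matrix for a single
#'   channel), values on any common scale.
#' @param side Output side length in pixels (default 128).
#' @param grayscale If `TRUE`, average channels to luminance before
#'   flattening.
#' @return Numeric vector of length `side^2 * C` (or `side^2` if grayscale).
#' @export
preprocess_image <- function(pixels, side = 128L, grayscale = FALSE) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  }
  d <- dim(pixels)
  if (length(d) != 3 || d[1] < 1 || d[2] < 1) {
    abort("`pixels` must be a non-empty H x W x C array.")
  }
  h <- d[1]; w <- d[2]; nc <- d[3]
  s <- min(h, w)
  r0 <- floor((h - s) / 2)
  c0 <- floor((w - s) / 2)
  crop <- pixels[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s), , drop = FALSE]
  if (s != side) {
    # EBImage images are (x = width, y = height): transpose in and out.
    img <- EBImage::Image(aperm(crop, c(2, 1, 3)))
    out <- EBImage::imageData(EBImage::resize(img, w = side, h = side))
    dim(out) <- c(side, side, nc)
    crop <- aperm(out, c(2, 1, 3))
  }
  if (grayscale && nc > 1) {
    crop <- array(rowMeans(matrix(crop, ncol = nc)), dim = c(side, side, 1))
  }
  as.vector(crop)
}

#' Per-category PCA of preprocessed image vectors
#'
#' Principal component analysis of the image feature vectors of one
#' category, retaining the smallest number of components whose cumulative
#' explained-variance ratio reaches `variance_kept` (default 90%). Rows of
#' the returned matrix are per-image component scores ("loadings" in the
#' duplicate-detection sense).
#'
#' @param features Numeric matrix, images x features (rows are
#'   [preprocess_image()] vectors), at least 2 rows; rownames (image ids)
#'   are preserved.
#' @param variance_kept Fraction of variance to preserve, in (0, 1].
#' @return Numeric matrix images x k of PCA scores with attribute
#'   `"variance_explained"` (cumulative ratio at k).
#' @export
category_pca <- function(features, variance_kept = 0.90) {
  features <- as.matrix(features)
  if (nrow(features) < 2) abort("PCA needs at least 2 images.")
  stopifnot_scalar_number(variance_kept, "variance_kept", lower = 0, upper = 1)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(var_ratio) >= variance_kept - 1e-12)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(features)
  attr(scores, "variance_explained") <- sum(var_ratio[seq_len(k)])
  scores
}

#' Find near-duplicate images from PCA scores
#'
#' Every unordered image pair whose PCA score vectors correlate (Pearson)
#' above `threshold` is flagged as a duplicate pair. Flagged pairs are
#' chained into clusters by connected components, and within each cluster
#' the image with the largest pixel resolution (`width * height`) is the
#' keeper; resolution ties go to the lexicographically smallest id. With a
#' single retained component Pearson correlation is undefined; two scores
#' then count as duplicates when they are equal within 1e-9 (the 1-D
#' degenerate dialect).
#'
#' @param scores Matrix images x components from [category_pca()], rownames
#'   = image ids.
#' @param manifest Data frame with columns `id`, `width`, `height` covering
#'   all images in `scores` (extra columns such as `category` pass through).
#' @param threshold Duplicate cutoff on Pearson r (default 0.975, strict
#'   `>`).
#' @return Object of class `duplicate_report`: list with `pairs` (tibble
#'   `id1`, `id2`, `similarity`), `clusters` (list of character id vectors),
#'   `keepers` (character), `drop` (character ids to remove), `threshold`.
#' @export
find_duplicates <- function(scores, manifest, threshold = 0.975) {
  scores <- as.matrix(scores)
  ids <- rownames(scores) %||% paste0("img", seq_len(nrow(scores)))
  rownames(scores) <- ids
  manifest <- as_tibble(manifest)
  if (!all(ids %in% manifest$id)) {
    abort("`manifest` must contain every image id in `scores`.")
  }
  res <- stats::setNames(manifest$width * manifest$height, manifest$id)

  n <- nrow(scores)
  pairs <- tibble(id1 = character(), id2 = character(),
                  similarity = numeric())
  if (n >= 2) {
    if (ncol(scores) >= 2) {
      sim <- stats::cor(t(scores))
    } else {
      # degenerate 1-D scores: duplicate iff equal within 1e-9
      eq <- outer(scores[, 1], scores[, 1],
                  function(a, b) abs(a - b) <= 1e-9)
      sim <- ifelse(eq, 1, -1)
    }
    hits <- which(upper.tri(sim) & sim > threshold, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      pairs <- tibble(id1 = ids[hits[, 1]], id2 = ids[hits[, 2]],
                      similarity = sim[hits]) |>
        dplyr::arrange(.data$id1, .data$id2)
    }
  }

  clusters <- list()
  keepers <- character()
  if (nrow(pairs) > 0) {
    g <- igraph::graph_from_data_frame(pairs[, c("id1", "id2")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    membership <- comp$membership
    clusters <- lapply(seq_len(comp$no), function(k) {
      sort(names(membership)[membership == k])
    })
    keepers <- vapply(clusters, function(cl) {
      r <- res[cl]
      best <- cl[r == max(r)]
      sort(best)[1]
    }, character(1))
    ord <- order(vapply(clusters, `[`, character(1), 1))
    clusters <- clusters[ord]
    keepers <- keepers[ord]
  }
  drop <- setdiff(unlist(clusters), keepers)
  structure(list(pairs = pairs, clusters = clusters, keepers = keepers,
                 drop = sort(drop), threshold = threshold),
            class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat(sprintf(
    "<duplicate_report: %d pair(s), %d cluster(s), %d image(s) to drop (r > %g)>\n",
    nrow(x$pairs), length(x$clusters), length(x$drop), x$threshold))
  invisible(x)
}

#' De-duplicate one image category end to end
#'
#' Convenience wrapper chaining [preprocess_image()], [category_pca()] and
#' [find_duplicates()] for the images of a single category.
#'
#' @param images Named list of pixel arrays (names = image ids).
#' @param manifest Data frame with `id`, `width`, `height` for those images.
#' @param side,variance_kept,threshold,grayscale Passed to the stages.
#' @return A `duplicate_report`.
#' @export
dedup_category <- function(images, manifest, side = 128L,
                           variance_kept = 0.90, threshold = 0.975,
                           grayscale = FALSE) {
  feats <- t(vapply(images, preprocess_image, side = side,
                    grayscale = grayscale,
                    FUN.VALUE = numeric(side * side *
                      (if (grayscale) 1L else dim(images[[1]])[3]))))
  rownames(feats) <- names(images)
  scores <- category_pca(feats, variance_kept = variance_kept)
  find_duplicates(scores, manifest, threshold = threshold)
}

#' Remove images flagged as not safe for work
#'
#' Splits a manifest into kept and removed rows by the NSFW probability
#' column: a record is removed only when its score strictly exceeds the
#' threshold. Records with a missing score pass with a warning (no evidence
#' to remove them).
#'
#' @param manifest Data frame with a numeric `nsfw_score` column in
#'   \[0, 1\] (NA allowed).
#' @param threshold Removal cutoff (default 0.8, strict `>`).
#' @return List with tibbles `kept` and `removed`, input order preserved.
#' @export
filter_nsfw <- function(manifest, threshold = 0.8) {
  manifest <- as_tibble(manifest)
  if (!"nsfw_score" %in% names(manifest)) {
    abort("`manifest` needs an `nsfw_score` column.")
  }
  s <- manifest$nsfw_score
  if (anyNA(s)) {
    warn(sprintf("%d record(s) lack an NSFW score and are kept.",
                 sum(is.na(s))))
  }
  remove <- !is.na(s) & s > threshold
  list(kept = manifest[!remove, ], removed = manifest[remove, ])
}

#' Keep categories with enough images
#'
#' @param counts Data frame with columns `category` and `count` (images
#'   available per category).
#' @param minimum Minimum image count for a category to survive (default
#'   700, inclusive).
#' @return Tibble of surviving rows.
#' @export
filter_min_images <- function(counts, minimum = 700L) {
  counts <- as_tibble(counts)
  if (any(counts$count < 0)) abort("Counts must be non-negative.")
  dplyr::filter(counts, .data$count >= minimum)
}

#' Serialize a duplicate report to JSON
#'
#' @param report A `duplicate_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_duplicate_report_json <- function(report, path) {
  jsonlite::write_json(
    list(threshold = report$threshold, pairs = report$pairs,
         clusters = report$clusters, keepers = report$keepers,
         drop = report$drop),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
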