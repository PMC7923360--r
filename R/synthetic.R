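#' Synthetic lexicon with Zipfian frequencies
#'
#' Draws word frequencies by sampling tokens from a Zipf law with exponent
#' 1 (probability of rank r proportional to 1/r), the canonical model of
#' word-frequency tables built from large spoken-language corpora, and
#' concreteness ratings uniform on the 1-5 Likert scale.
#'
#' @param n_words Number of words.
#' @param seed Optional integer seed.
#' @param n_tokens Corpus size in tokens (default 1e6).
#' @return Tibble with `word`, `frequency`, `concreteness`.
#' @export
gen_lexicon <- function(n_words, seed = NULL, n_tokens = 1e6) {
  if (n_words < 1) abort("`n_words` must be >= 1.")
  with_seed_(seed, {
    p <- (1 / seq_len(n_words))
    counts <- as.vector(stats::rmultinom(1, size = n_tokens, prob = p / sum(p)))
    tibble(
      word = sprintf("w%05d", seq_len(n_words)),
      frequency = counts,
      concreteness = stats::runif(n_words, 1, 5)
    )
  })
}

# Smooth random image: low-pass noise made by bilinear upsampling of a small
# random grid, so image content is dominated by low spatial frequencies (as
# in natural photographs) and PCA similarity structure is non-degenerate.
smooth_noise_image <- function(height, width, n_channels = 3L,
                               base_res = 6L) {
  base <- array(stats::runif(base_res * base_res * n_channels),
                dim = c(base_res, base_res, n_channels))
  img <- EBImage::Image(aperm(base, c(2, 1, 3)))
  out <- EBImage::imageData(EBImage::resize(img, w = width, h = height))
  dim(out) <- c(width, height, n_channels)
  aperm(out, c(2, 1, 3))
}

resize_image <- function(pixels, height, width) {
  img <- EBImage::Image(aperm(pixels, c(2, 1, 3)))
  out <- EBImage::imageData(EBImage::resize(img, w = width, h = height))
  dim(out) <- c(width, height, dim(pixels)[3])
  aperm(out, c(2, 1, 3))
}

#' Synthetic image set with planted near-duplicates
#'
#' Generates `n_base` independent smooth-noise images at varied resolutions,
#' then copies `n_dup` of them under a random transform — exact copy,
#' rescaling by 0.5x or 2x, or an aspect-ratio change (symmetric crop of up
#' to 8% of the longer dimension) — the disguises a duplicate-removal stage
#' must see through. Ground truth lists each (original, copy) pair.
#'
#' @param n_base Number of independent images.
#' @param n_dup Number of planted duplicates (<= `n_base`).
#' @param seed Optional integer seed.
#' @param category Category label stamped on the manifest.
#' @param size_range Inclusive range of base image side lengths in pixels.
#' @return List with `images` (named list of H x W x 3 arrays), `manifest`
#'   (tibble `id`, `category`, `width`, `height`), and `truth` (tibble
#'   `original`, `copy`, `transform`).
#' @export
gen_image_set <- function(n_base, n_dup, seed = NULL, category = "synthetic",
                          size_range = c(120L, 200L)) {
  if (n_dup > n_base) abort("`n_dup` must not exceed `n_base`.")
  with_seed_(seed, {
    ids <- sprintf("img%03d", seq_len(n_base))
    hs <- sample(size_range[1]:size_range[2], n_base, replace = TRUE)
    ws <- sample(size_range[1]:size_range[2], n_base, replace = TRUE)
    images <- stats::setNames(
      lapply(seq_len(n_base), function(i) smooth_noise_image(hs[i], ws[i])),
      ids)
    truth <- tibble(original = character(), copy = character(),
                    transform = character())
    if (n_dup > 0) {
      dup_of <- sample.int(n_base, n_dup)
      transforms <- sample(c("identity", "half", "double", "aspect"),
                           n_dup, replace = TRUE)
      for (k in seq_len(n_dup)) {
        src <- images[[dup_of[k]]]
        d <- dim(src)
        copy <- switch(
          transforms[k],
          identity = src,
          half = resize_image(src, round(d[1] / 2), round(d[2] / 2)),
          double = resize_image(src, d[1] * 2, d[2] * 2),
          aspect = {
            # crop the longer dimension, capped so it never drops below the
            # shorter one: the central square (the duplicate signature)
            # survives while width:height changes
            if (d[1] >= d[2]) {
              cut <- min(round(0.04 * d[1]), floor((d[1] - d[2]) / 2))
              src[(cut + 1):(d[1] - cut), , , drop = FALSE]
            } else {
              cut <- min(round(0.04 * d[2]), floor((d[2] - d[1]) / 2))
              src[, (cut + 1):(d[2] - cut), , drop = FALSE]
            }
          }
        )
        cid <- sprintf("%s_dup", ids[dup_of[k]])
        images[[cid]] <- copy
        truth <- dplyr::bind_rows(truth, tibble(
          original = ids[dup_of[k]], copy = cid, transform = transforms[k]))
      }
    }
    manifest <- tibble(
      id = names(images),
      category = category,
      width = unname(vapply(images, function(x) dim(x)[2], integer(1))),
      height = unname(vapply(images, function(x) dim(x)[1], integer(1)))
    )
    list(images = images, manifest = manifest, truth = truth)
  })
}

#' Synthetic multi-subject RDM stack
#'
#' Draws a latent stimuli x features signal matrix; each subject's
#' activation pattern is the shared signal plus white Gaussian noise with
#' standard deviation `noise_sd`, and the subject RDM is computed from those
#' activations with [compute_rdm()] — so every generated RDM is a valid
#' correlation-distance RDM by construction (noise lives on activations,
#' never directly on dissimilarities).
#'
#' @param n_subjects Number of subjects (>= 2 for noise-ceiling use).
#' @param n_stimuli Number of stimuli (>= 3).
#' @param n_features Response channels per stimulus (default 30).
#' @param noise_sd Per-subject activation noise SD (signal is unit SD).
#' @param seed Optional integer seed.
#' @return List with `truth` (noiseless `rdm`) and `subjects` (list of
#'   subject `rdm`s).
#' @export
gen_subject_rdms <- function(n_subjects, n_stimuli, n_features = 30L,
                             noise_sd = 0.5, seed = NULL) {
  if (n_stimuli < 3 || n_features < 2) {
    abort("Need at least 3 stimuli and 2 features.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  with_seed_(seed, {
    signal <- matrix(stats::rnorm(n_stimuli * n_features),
                     nrow = n_stimuli,
                     dimnames = list(sprintf("s%03d", seq_len(n_stimuli)),
                                     NULL))
    subjects <- lapply(seq_len(n_subjects), function(s) {
      acts <- signal + matrix(stats::rnorm(length(signal), sd = noise_sd),
                              nrow = n_stimuli)
      rownames(acts) <- rownames(signal)
      compute_rdm(acts)
    })
    list(truth = compute_rdm(signal), subjects = subjects)
  })
}

#' Synthetic per-instance score sets for two training groups
#'
#' Normal draws around per-group means: equal means give an exchangeable
#' null for permutation-test calibration, shifted means a known effect for
#' power checks.
#'
#' @param n_instances Instances per group.
#' @param mean_a,mean_b Group means.
#' @param sd Common standard deviation.
#' @param seed Optional integer seed.
#' @return List with numeric vectors `a` and `b`.
#' @export
gen_instance_scores <- function(n_instances, mean_a = 0, mean_b = 0,
                                sd = 1, seed = NULL) {
  if (n_instances < 2) abort("Need >= 2 instances per group.")
  with_seed_(seed, {
    list(a = stats::rnorm(n_instances, mean_a, sd),
         b = stats::rnorm(n_instances, mean_b, sd))
  })
}

#' Synthetic unit-response set with planted face-selective units
#'
#' Null units draw condition A and B responses from the same standard
#' normal; a planted fraction receives a `+effect_size` (in SD units) shift
#' in condition A. Units are assigned to layers round-robin. Returns the
#' ground-truth mask for recovery checks.
#'
#' @param n_units Total units across the network.
#' @param n_stimuli Stimuli per condition (default 50, as in a face/place
#'   probe set).
#' @param selective_fraction Fraction of units planted as selective.
#' @param effect_size Mean shift (in SDs) of condition A for planted units.
#' @param n_layers Number of layers for round-robin assignment.
#' @param seed Optional integer seed.
#' @return List with `responses_a`, `responses_b` (stimuli x units),
#'   `layer_of_unit`, `truth` (logical mask of planted units).
#' @export
gen_unit_responses <- function(n_units, n_stimuli = 50L,
                               selective_fraction = 0.1, effect_size = 3,
                               n_layers = 4L, seed = NULL) {
  if (n_units < 1 || n_stimuli < 2) {
    abort("Need >= 1 unit and >= 2 stimuli per condition.")
  }
  stopifnot_scalar_number(selective_fraction, "selective_fraction",
                          lower = 0, upper = 1)
  with_seed_(seed, {
    n_sel <- round(selective_fraction * n_units)
    truth <- rep(FALSE, n_units)
    if (n_sel > 0) truth[sample.int(n_units, n_sel)] <- TRUE
    a <- matrix(stats::rnorm(n_stimuli * n_units), nrow = n_stimuli)
    b <- matrix(stats::rnorm(n_stimuli * n_units), nrow = n_stimuli)
    a[, truth] <- a[, truth] + effect_size
    list(responses_a = a, responses_b = b,
         layer_of_unit = rep_len(seq_len(n_layers), n_units),
         truth = truth)
  })
}

#' Synthetic category-size inventory
#'
#' @param n_categories Number of categories.
#' @param min_size,max_size Inclusive bounds for uniform integer sizes.
#' @param seed Optional integer seed.
#' @param name Dataset label.
#' @return A [category_inventory()].
#' @export
gen_category_sizes <- function(n_categories, min_size, max_size,
                               seed = NULL, name = "synthetic") {
  if (min_size < 1 || max_size < min_size) {
    abort("Need 1 <= min_size <= max_size.")
  }
  with_seed_(seed, {
    category_inventory(
      category = sprintf("%s_c%04d", name, seq_len(n_categories)),
      size = sample(min_size:max_size, n_categories, replace = TRUE),
      name = name
    )
  })
}

#' Stimulus metadata from a class composition
#'
#' Expands a class -> count composition into one record per stimulus with
#' its class and binary animacy label.
#'
#' @param composition Data frame with columns `class`, `count`, `animate`
#'   (logical).
#' @return Tibble with `stimulus`, `class`, `animate`; total rows equal the
#'   sum of counts.
#' @export
gen_stimulus_metadata <- function(composition) {
  composition <- as_tibble(composition)
  if (nrow(composition) == 0) {
    return(tibble(stimulus = character(), class = character(),
                  animate = logical()))
  }
  if (any(composition$count < 0)) abort("Counts must be non-negative.")
  expanded <- tidyr::uncount(composition, weights = .data$count)
  dplyr::mutate(expanded,
                stimulus = sprintf("s%04d", dplyr::row_number()),
                .before = 1)
}

#' Stimulus composition of the 1,200-natural-scene set
#'
#' Printed composition of the large natural-scene stimulus set: 312 animate
#' stimuli (of which 8 human) and 888 inanimate (of which 64 plants).
#'
#' @return Composition tibble for [gen_stimulus_metadata()].
#' @export
composition_natural_scenes <- function() {
  tibble(
    class = c("human", "animal", "plant", "object"),
    count = c(8L, 304L, 64L, 824L),
    animate = c(TRUE, TRUE, FALSE, FALSE)
  )
}

#' Stimulus composition of the 92-object set
#'
#' Printed composition of the segmented-object stimulus set: human and
#' nonhuman faces and bodies (12 each) plus 23 natural and 21 manmade
#' inanimate objects.
#'
#' @return Composition tibble for [gen_stimulus_metadata()].
#' @export
composition_objects_92 <- function() {
  tibble(
    class = c("human_face", "human_body", "animal_face", "animal_body",
              "natural_object", "manmade_object"),
    count = c(12L, 12L, 12L, 12L, 23L, 21L),
    animate = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}
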