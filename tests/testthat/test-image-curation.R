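test_that("preprocessing crops the centre square and resizes correctly", {
  # square input at the target side: identity up to flattening
  sq <- array(runif(128 * 128 * 3), dim = c(128, 128, 3))
  expect_identical(preprocess_image(sq, side = 128), as.vector(sq))

  # 128 x 256 input: central columns 65..192 (1-based) retained
  wide <- array(runif(128 * 256 * 3), dim = c(128, 256, 3))
  expect_identical(preprocess_image(wide, side = 128),
                   as.vector(wide[, 65:192, ]))

  # constant image stays constant through crop + bilinear resize
  flat <- array(0.4, dim = c(90, 60, 3))
  v <- preprocess_image(flat, side = 32)
  expect_length(v, 32 * 32 * 3)
  expect_true(all(abs(v - 0.4) < 1e-12))

  expect_error(preprocess_image(array(0, dim = c(0, 5, 3))), "non-empty")
})

test_that("category PCA keeps the fewest components reaching the variance", {
  # rank-1 data: all points on one line through the mean -> 1 component
  set.seed(41)
  base <- runif(30)
  rank1 <- outer(seq(-2, 2, length.out = 10), base)
  expect_identical(ncol(category_pca(rank1, 0.9)), 1L)

  # random matrix: retained components must explain >= 90% of variance
  x <- matrix(rnorm(50 * 300), nrow = 50)
  sc <- category_pca(x, 0.90)
  total_var <- sum(apply(scale(x, scale = FALSE), 2, function(c) sum(c^2)))
  kept_var <- sum(sc^2)
  expect_gte(kept_var / total_var, 0.90)
  # and one fewer component would not reach it
  vr <- apply(sc, 2, function(c) sum(c^2)) / total_var
  expect_lt(sum(vr[-length(vr)]), 0.90)

  # duplicated vectors get identical score rows
  dup <- rbind(x[1:5, ], x[1:5, ])
  sd2 <- category_pca(dup, 0.9)
  expect_equal(sd2[1:5, ], sd2[6:10, ], ignore_attr = TRUE)

  expect_error(category_pca(x[1, , drop = FALSE]), "at least 2")
})

test_that("pairwise similarity equals brute-force Pearson on score rows", {
  set.seed(51)
  sc <- matrix(rnorm(8 * 5), nrow = 8,
               dimnames = list(sprintf("i%d", 1:8), NULL))
  man <- tibble::tibble(id = rownames(sc), width = 10, height = 10)
  rep <- find_duplicates(sc, man, threshold = -2)  # report all pairs
  for (k in seq_len(nrow(rep$pairs))) {
    i <- rep$pairs$id1[k]
    j <- rep$pairs$id2[k]
    expect_equal(rep$pairs$similarity[k],
                 pearson_brute(sc[i, ], sc[j, ]), tolerance = 1e-10)
  }
  expect_identical(nrow(rep$pairs), 28L)  # all C(8,2) pairs reported
})

test_that("duplicate clusters chain transitively and keep max resolution", {
  # a ~ b, b ~ c, a !~ c must still form one cluster {a, b, c}
  base <- rnorm(6)
  sc <- rbind(a = base, b = base + 0.02 * rnorm(6),
              c = base + 0.04 * rnorm(6), d = rnorm(6))
  man <- tibble::tibble(id = c("a", "b", "c", "d"),
                        width = c(10, 50, 20, 10), height = c(10, 50, 20, 10))
  rep <- find_duplicates(sc, man, threshold = 0.9)
  expect_identical(rep$clusters, list(c("a", "b", "c")))
  expect_identical(rep$keepers, "b")  # largest resolution wins
  expect_identical(rep$drop, c("a", "c"))

  # resolution tie -> lexicographically smallest id
  man2 <- tibble::tibble(id = c("a", "b", "c", "d"), width = 10, height = 10)
  expect_identical(find_duplicates(sc, man2, threshold = 0.9)$keepers, "a")
})

test_that("duplicate detection is invariant to image order", {
  im <- gen_image_set(30, 6, seed = 3)
  rep1 <- dedup_category(im$images, im$manifest)
  perm <- sample(length(im$images))
  rep2 <- dedup_category(im$images[perm], im$manifest)
  expect_identical(rep1$clusters, rep2$clusters)
  expect_identical(rep1$keepers, rep2$keepers)
  # two byte-identical images correlate at r = 1 and are flagged
  ident <- im$truth[im$truth$transform == "identity", ]
  if (nrow(ident) > 0) {
    keys <- pair_keys(rep1$pairs$id1, rep1$pairs$id2)
    expect_true(all(pair_keys(ident$original, ident$copy) %in% keys))
  }
})

test_that("single-component fallback flags only equal 1-D scores", {
  sc <- matrix(c(0.5, 0.5 + 2e-10, 3, -1), ncol = 1,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  man <- tibble::tibble(id = rownames(sc), width = 1:4, height = 1)
  rep <- find_duplicates(sc, man)
  expect_identical(pair_keys(rep$pairs$id1, rep$pairs$id2), "a b")
})

test_that("NSFW filter removes only scores strictly above threshold", {
  man <- tibble::tibble(id = c("a", "b", "c"),
                        nsfw_score = c(0.79, 0.80, 0.81))
  out <- filter_nsfw(man, threshold = 0.8)
  expect_identical(out$removed$id, "c")
  expect_identical(out$kept$id, c("a", "b"))

  expect_identical(nrow(filter_nsfw(
    tibble::tibble(id = "x", nsfw_score = 0))$removed), 0L)
  expect_identical(nrow(filter_nsfw(
    tibble::tibble(id = "x", nsfw_score = 1))$removed), 1L)
  # missing score: kept, with a warning
  expect_warning(
    out2 <- filter_nsfw(tibble::tibble(id = "x", nsfw_score = NA_real_)),
    "lack an NSFW score")
  expect_identical(out2$kept$id, "x")
})

test_that("minimum-image filter keeps counts at or above the floor", {
  counts <- tibble::tibble(category = c("a", "b", "c"),
                           count = c(699L, 700L, 701L))
  expect_identical(filter_min_images(counts)$category, c("b", "c"))
  expect_identical(nrow(filter_min_images(counts[0, ])), 0L)
  expect_identical(filter_min_images(counts, minimum = 1),
                   counts)
})

test_that("duplicate reports serialise to JSON and tidy into tables", {
  im <- gen_image_set(20, 4, seed = 6)
  rep <- dedup_category(im$images, im$manifest)
  td <- tidy(rep)
  expect_true(all(c("id", "cluster", "keeper") %in% names(td)))
  expect_identical(sum(td$keeper), length(rep$clusters))
  path <- withr::local_tempfile(fileext = ".json")
  write_duplicate_report_json(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_identical(length(parsed$clusters), length(rep$clusters))
})
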