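make_toy_db <- function() {
  icons <- make_icons(3, 60, seed = 2)
  imgs <- lapply(seq_along(icons), function(i) {
    fr <- frame_icon(icons[[i]]$pixels, 128)
    density_image(fr, paste0("img", i))
  })
  pois <- rep(list(cbind(64, 64)), length(imgs))
  list(images = imgs, pois = pois)
}

test_that("variance filter keeps high-contrast windows only", {
  flat <- matrix(100, 128, 128)
  flat[33:48, 33:48] <- matrix(c(0, 255), 16, 16)   # one busy patch
  img <- density_image(flat, "v")
  centers <- rbind(c(40, 40), c(100, 100), c(40, 100), c(100, 40))
  kept <- local_variance_filter(img, centers, 40)
  expect_equal(nrow(kept), 1)
  expect_equal(kept[1, ], c(40, 40), ignore_attr = TRUE)
  # constant image: local variance 0 >= global variance 0, all kept
  const_img <- density_image(matrix(7, 64, 64), "c")
  kept2 <- local_variance_filter(const_img, centers %/% 2, 32)
  expect_equal(nrow(kept2), 4)
  expect_equal(kept2, centers %/% 2, ignore_attr = TRUE)  # order preserved
})

test_that("db_index enumerates POIs deterministically with metadata", {
  db <- make_toy_db()
  idx <- db_index(db$images, pois = db$pois, S = 100)
  expect_s3_class(idx, "kd2d_index")
  expect_equal(nrow(idx), 3)
  expect_equal(idx$image_id, paste0("img", 1:3))
  expect_identical(idx, db_index(db$images, pois = db$pois, S = 100))
  meta <- attr(idx, "meta")
  expect_equal(meta$S, 100L)
  expect_equal(meta$beta, 100^2 / 12)
  expect_equal(meta$mode, "poi-list")
  expect_error(db_index(list(), S = 10), "empty")
})

test_that("grid indexing with stride S yields floor(N/S) * floor(M/S) rows", {
  img <- density_image(matrix(runif(256 * 192, 0, 255), 256, 192), "g")
  idx <- db_index(list(img), S = 64, stride = 64L)
  expect_equal(nrow(idx), 4 * 3)
  expect_equal(attr(idx, "meta")$mode, "grid")
})

test_that("descriptor distance is the squared euclidean metric", {
  v <- c(1, 0, 0, 0, 0, 0); w <- c(0, 1, 0, 0, 0, 0)
  expect_equal(descriptor_distance(v, v), 0)
  expect_equal(descriptor_distance(v, w), 2)
  set.seed(3)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(descriptor_distance(a, b), descriptor_distance(b, a))
  expect_equal(descriptor_distance(a, b), sum((a - b)^2))
  d1 <- comp_desc(test_blob(32, 16, 16), 16, 16, prep_step(32))
  d2 <- comp_desc(test_blob(64, 32, 32), 32, 32, prep_step(64))
  expect_error(descriptor_distance(d1, d2), "not comparable")
})

test_that("search ranks by distance with deterministic tie-breaking", {
  db <- make_toy_db()
  idx <- db_index(db$images, pois = db$pois, S = 100)
  q <- describe_poi(db$images[[2]], 64, 64, S = 100)
  res <- db_search(q, idx, k = 3)
  expect_equal(res$image_id[1], "img2")
  expect_equal(res$distance[1], 0)
  expect_true(all(diff(res$distance) >= 0))
  # permuting index rows must not change the ranking
  shuf <- idx[c(3, 1, 2), ]
  attr(shuf, "meta") <- attr(idx, "meta")
  class(shuf) <- class(idx)
  expect_equal(db_search(q, shuf, k = 3), res, ignore_attr = TRUE)
  over <- db_search(q, idx, k = 10)
  expect_equal(nrow(over), 3)
  expect_true(attr(over, "truncated"))
  expect_error(db_search(comp_desc(test_blob(32, 16, 16), 16, 16,
                                   prep_step(32)), idx),
               "do not match")
})

test_that("indexes round-trip through the TSV format without rank changes", {
  db <- make_toy_db()
  idx <- db_index(db$images, pois = db$pois, S = 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_index(idx, path)
  back <- read_index(path)
  expect_equal(attr(back, "meta"), attr(idx, "meta"))
  expect_equal(back$Q20, idx$Q20, tolerance = 1e-7)
  q <- describe_poi(db$images[[1]], 64, 64, S = 100)
  expect_equal(db_search(q, back, k = 3)$image_id,
               db_search(q, idx, k = 3)$image_id)
  # header carries provenance
  hdr <- readLines(path, n = 6)
  expect_true(any(grepl("^# S=100$", hdr)))
  expect_true(any(grepl("^# beta=", hdr)))
})
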