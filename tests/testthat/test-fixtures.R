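test_that("icon generation is deterministic, varied and separated", {
  a <- make_icons(9, 60, seed = 1)
  b <- make_icons(9, 60, seed = 1)
  expect_identical(lapply(a, `[[`, "pixels"), lapply(b, `[[`, "pixels"))
  for (ic in a) {
    expect_gt(stats::var(as.vector(ic$pixels)), 0)
    expect_true(all(ic$pixels >= 0 & ic$pixels <= 255))
  }
  # ink stays inside the inscribed circle so rotations stay in-frame
  ctr <- (60 - 1) / 2
  rr <- sqrt(outer(((0:59) - ctr)^2, ((0:59) - ctr)^2, "+"))
  for (ic in a) expect_true(all((255 - ic$pixels)[rr > 29] == 0))
})

test_that("dataset spec validates the combination bookkeeping", {
  spec <- dataset_spec()
  expect_equal(spec$n_icons * length(spec$angles) * length(spec$scales),
               spec$slots * spec$n_canvases)
  expect_error(dataset_spec(n_canvases = 3), "must equal")
  expect_error(dataset_spec(n_icons = 10), "must equal")
  expect_error(dataset_spec(n_icons = 100, slots = 81), "slots")
})

test_that("built datasets cover every combination once, balanced by class", {
  ds <- build_dataset(dataset_spec(seed = 1))
  expect_length(ds$canvases, 4)
  for (cv in ds$canvases)
    expect_equal(dim(cv$pixels), c(600L, 600L))
  expect_equal(nrow(ds$truth), 324)
  expect_equal(as.integer(table(ds$truth$icon)), rep(36L, 9))  # 12 x 3
  combos <- unique(ds$truth[c("icon", "angle", "scale")])
  expect_equal(nrow(combos), 324)
  # slot centres unique per canvas
  expect_false(any(duplicated(ds$truth[c("canvas", "x", "y")])))
  expect_length(ds$queries, 9)
  for (q in ds$queries) expect_equal(dim(q$pixels), c(150L, 150L))
})

test_that("identity placements are pixel-identical to the raw icon", {
  ds <- build_dataset(dataset_spec(seed = 2))
  icons <- make_icons(9, 60, seed = 2)
  id <- ds$truth[ds$truth$angle == 0 & ds$truth$scale == 1, ]
  expect_equal(nrow(id), 9)
  for (i in seq_len(nrow(id))) {
    cv <- ds$canvases[[id$canvas[i]]]$pixels
    rr <- (id$x[i] - 30 + 1):(id$x[i] + 30)
    cc <- (id$y[i] - 30 + 1):(id$y[i] + 30)
    expect_equal(cv[rr, cc], icons[[id$icon[i]]]$pixels,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("salt-and-pepper degradation hits the requested pixel fraction", {
  ds <- build_dataset(dataset_spec(seed = 1))
  cv <- ds$canvases[[1]]
  expect_identical(add_salt_pepper(cv, 0)$pixels, cv$pixels)
  full <- add_salt_pepper(cv, 1, seed = 4)
  expect_true(all(full$pixels %in% c(0, 255)))
  noisy <- add_salt_pepper(cv, 0.3, seed = 4)
  frac_selected <- 0.3                      # selected without replacement
  changed <- mean(noisy$pixels != cv$pixels)
  # a selected pixel keeps its value when the coin matches the original,
  # so observed changes fall a little below the selection density
  expect_lt(abs(changed - frac_selected), 0.16)
  expect_gt(changed, 0.10)
  expect_identical(add_salt_pepper(cv, 0.3, seed = 4)$pixels, noisy$pixels)
  expect_false(identical(add_salt_pepper(cv, 0.3, seed = 5)$pixels,
                         noisy$pixels))
})

test_that("retrieval scoring maps hits through the slot geometry", {
  ds <- build_dataset(dataset_spec(seed = 1))
  spec <- ds$spec
  # perfect results: each query retrieves 5 of its own placements
  perfect <- lapply(1:9, function(q) {
    own <- ds$truth[ds$truth$icon == q, ][1:5, ]
    data.frame(image_id = paste0("canvas", own$canvas),
               x_p = own$x, y_p = own$y, distance = seq(0, 4) / 10)
  })
  sc <- score_retrieval(perfect, ds$truth, spec, k = 5)
  expect_equal(sc$top1, 1); expect_equal(sc$topk, 1)
  # corrupt three retrievals below rank 1 -> 42/45 and 9/9
  mixed <- perfect
  other <- ds$truth[ds$truth$icon == 2, ][6:8, ]
  mixed[[1]][3:5, c("image_id", "x_p", "y_p")] <-
    data.frame(paste0("canvas", other$canvas), other$x, other$y)
  sc2 <- score_retrieval(mixed, ds$truth, spec, k = 5)
  expect_equal(sc2$top1_hits, 9)
  expect_equal(sc2$topk_hits, 42)
  expect_equal(sc2$topk, 42 / 45, tolerance = 1e-12)
  # one rank-1 miss out of 9 queries
  mixed1 <- perfect
  mixed1[[3]][1, c("image_id", "x_p", "y_p")] <-
    data.frame(paste0("canvas", other$canvas[1]), other$x[1], other$y[1])
  expect_equal(score_retrieval(mixed1, ds$truth, spec, k = 5)$top1,
               8 / 9, tolerance = 1e-12)
  # a POI away from every slot centre is a protocol violation
  broken <- perfect
  broken[[1]]$x_p[1] <- broken[[1]]$x_p[1] + 60
  expect_error(score_retrieval(broken, ds$truth, spec, k = 5),
               "slot centre")
})

test_that("noisy grid indexing with the variance filter finds a particle", {
  # a synthetic noisy field with two bright particles: the variance
  # filter drops empty regions and search puts the second particle on top
  set.seed(77)
  field <- matrix(runif(256 * 256, 90, 110), 256, 256)
  put <- function(f, cx, cy) {
    blob <- test_blob(40, 19.5, 19.5, width = 6)
    f[(cx - 19):(cx + 20), (cy - 19):(cy + 20)] <-
      f[(cx - 19):(cx + 20), (cy - 19):(cy + 20)] + blob
    f
  }
  field <- put(field, 60, 60); field <- put(field, 180, 196)
  img <- density_image(field, "micrograph")
  idx <- db_index(list(img), S = 40, stride = 8L,
                  variance_filter = TRUE, filter_window = 40L)
  expect_lt(nrow(idx), (ceiling(236 / 8))^2)   # filter removed flat regions
  q <- describe_poi(img, 60, 60, S = 40)
  top <- db_search(q, idx, k = 5)
  hit2 <- sqrt((top$x_p - 180)^2 + (top$y_p - 196)^2)
  expect_equal(top$distance[1], 0)             # the query region itself
  expect_true(any(hit2 <= 8))                  # the twin particle retrieved
})
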