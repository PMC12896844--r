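# Labelme polygon reading, carcass-wise splitting, and mask PNG
# round-trips.

labelme_json <- function(shapes) {
  jsonlite::toJSON(list(version = "5.0.1", shapes = shapes,
                        imageHeight = 20, imageWidth = 20),
                   auto_unbox = TRUE)
}

square_shape <- function(label, x0, y0, x1, y1) {
  list(label = label,
       points = list(list(x0, y0), list(x1, y0), list(x1, y1),
                     list(x0, y1)))
}

test_that("an axis-aligned square rasterizes to exactly its pixel area", {
  js <- labelme_json(list(square_shape("torso", 0, 0, 10, 10)))
  mask <- read_labelme(js, canvas = c(20, 20))
  expect_equal(sum(unclass(mask) == 1L), 100)
  expect_equal(sum(unclass(mask) != 0L), 100)
  # the square occupies rows/cols 1..10 under the pixel-center convention
  expect_true(all(unclass(mask)[1:10, 1:10] == 1L))
})

test_that("empty shape lists give an all-background mask", {
  mask <- read_labelme(labelme_json(list()), canvas = c(8, 8))
  expect_true(all(unclass(mask) == 0L))
})

test_that("later polygons overwrite earlier ones (last wins)", {
  js <- labelme_json(list(square_shape("torso", 0, 0, 10, 10),
                          square_shape("head", 5, 5, 15, 15)))
  mask <- read_labelme(js, canvas = c(20, 20))
  expect_true(all(unclass(mask)[6:10, 6:10] == 2L))
  expect_true(all(unclass(mask)[1:5, 1:5] == 1L))
})

test_that("unknown labels and malformed JSON are rejected with context", {
  js <- labelme_json(list(square_shape("wing", 0, 0, 5, 5)))
  expect_error(read_labelme(js, canvas = c(10, 10)), "wing")
  expect_error(read_labelme(js, canvas = c(10, 10)), "torso")
  expect_error(read_labelme("{not json", canvas = c(10, 10)), "malformed")
})

test_that("polygon reader agrees with a convex point-in-polygon oracle", {
  set.seed(31)
  for (rep in 1:100) {
    poly <- random_convex_polygon(cx = runif(1, 8, 16),
                                  cy = runif(1, 8, 16),
                                  r = runif(1, 3, 7),
                                  n = sample(3:8, 1))
    js <- labelme_json(list(list(
      label = "torso",
      points = lapply(seq_along(poly$x), function(i)
        list(poly$x[i], poly$y[i])))))
    mask <- unclass(read_labelme(js, canvas = c(24, 24)))
    for (r in seq_len(24)) for (cc in seq_len(24)) {
      want <- convex_pip_oracle(cc - 0.5, r - 0.5, poly$x, poly$y)
      if ((mask[r, cc] == 1L) != want) {
        fail(sprintf("disagreement at (%d, %d), polygon %d", r, cc, rep))
      }
    }
  }
  succeed()
})

test_that("split sizes follow the floor-to-val/test rounding rule", {
  s10 <- build_split(sprintf("C%02d", 1:10), seed = 1)
  expect_equal(as.vector(table(s10$subset)[c("train", "val", "test")]),
               c(8L, 1L, 1L))
  s301 <- build_split(sprintf("C%03d", 1:301), seed = 1)
  expect_equal(as.vector(table(s301$subset)[c("train", "val", "test")]),
               c(241L, 30L, 30L))
})

test_that("split is a deterministic partition of the ids", {
  ids <- sprintf("C%03d", 1:57)
  a <- build_split(ids, seed = 5)
  b <- build_split(ids, seed = 5)
  expect_identical(a, b)
  expect_setequal(a$carcass_id, ids)
  expect_equal(anyDuplicated(a$carcass_id), 0L)
  d <- build_split(ids, seed = 6)
  expect_false(identical(a$subset, d$subset))
  expect_error(build_split(c("A", "A", "B")), "duplicate")
})

test_that("every image of a carcass lands in exactly one subset", {
  ds <- generate_dataset(40, seed = 2)
  sp <- build_split(unique(ds$manifest$carcass_id), seed = 2)
  joined <- sp$subset[match(ds$manifest$carcass_id, sp$carcass_id)]
  per_carcass <- tapply(joined, ds$manifest$carcass_id,
                        function(s) length(unique(s)))
  expect_true(all(per_carcass == 1L))
})

test_that("mask PNG round-trip is label-identical", {
  set.seed(13)
  m <- label_mask(matrix(sample(0:3, 32 * 32, TRUE), 32, 32))
  p <- withr::local_tempfile(fileext = ".png")
  write_mask(m, p)
  back <- read_mask(p)
  expect_identical(unclass(back), unclass(m))
  empty <- label_mask(matrix(0L, 8, 8))
  write_mask(empty, p)
  expect_identical(unclass(read_mask(p)), unclass(empty))
})

test_that("invalid masks and palettes are refused", {
  expect_error(label_mask(matrix(c(0L, 9L), 1, 2)), "absent")
  expect_error(label_mask(matrix(0L, 2, 2),
                          class_map = c(background = 0L, torso = 0L)),
               "palette collision")
  m <- label_mask(matrix(0L, 4, 4))
  attr(m, "class_map") <- c(background = 0L, torso = 1L, head = 1L)
  expect_error(write_mask(m, tempfile(fileext = ".png")),
               "palette collision")
  m2 <- label_mask(matrix(0L, 4, 4))
  m2[1, 1] <- 7L
  expect_error(write_mask(m2, tempfile(fileext = ".png")), "refused")
})

test_that("view image PNG round-trip preserves intensities", {
  set.seed(3)
  img <- array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3))
  p <- withr::local_tempfile(fileext = ".png")
  write_view_image(img, p)
  expect_identical(read_view_image(p), img)
})
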