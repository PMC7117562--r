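test_that("TIFF write/read round trip is pixel-identical at 8 and 16 bit", {
  set.seed(11)
  for (bd in c(8L, 16L)) {
    m <- matrix(sample.int(2L^bd, 300, replace = TRUE) - 1L, 15, 20)
    img <- image_plane(m, bit_depth = bd)
    path <- withr::local_tempfile(fileext = ".tif")
    write_image(img, path)
    back <- load_image(path)
    expect_identical(unclass(back)[, ], m)
    expect_identical(attr(back, "bit_depth"), bd)
    expect_equal(attr(back, "white_level"), 2^bd - 1)
  }
})

test_that("RGB images reduce to a named channel or ITU luminance", {
  set.seed(12)
  arr <- array(sample(0:255, 3 * 100, replace = TRUE), c(10, 10, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(arr / 255, path, bits.per.sample = 8L)
  g <- load_image(path, channel_policy = "green")
  expect_identical(unclass(g)[, ], matrix(as.integer(arr[, , 2]), 10, 10))
  lum <- load_image(path, channel_policy = "luminance")
  expect_identical(
    unclass(lum)[, ],
    matrix(as.integer(round(0.299 * arr[, , 1] + 0.587 * arr[, , 2] +
                              0.114 * arr[, , 3])), 10, 10))
})

test_that("PNG input reads identically to TIFF", {
  set.seed(13)
  m <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  img <- image_plane(m, 8L)
  ptif <- withr::local_tempfile(fileext = ".tif")
  ppng <- withr::local_tempfile(fileext = ".png")
  write_image(img, ptif)
  png::writePNG(m / 255, ppng)
  expect_identical(unclass(load_image(ppng))[, ],
                   unclass(load_image(ptif))[, ])
})

test_that("polygons rasterize by the pixel-center even-odd rule", {
  # axis-aligned square of side s covers exactly s^2 pixel centers
  for (s in c(3, 6, 10)) {
    roi <- nucleus_roi("sq", "control",
                       polygon = cbind(c(2, 2 + s, 2 + s, 2), c(2, 2, 2 + s, 2 + s)))
    px <- rasterize_roi(roi, c(30L, 30L))
    expect_equal(nrow(px), s^2)
    expect_true(all(px[, 1] >= 2 & px[, 1] < 2 + s))
  }
  # rasterization agrees with an independent per-pixel ray-casting oracle
  set.seed(14)
  for (k in 1:20) {
    poly <- random_polygon(c(32L, 32L))
    got <- rasterize_roi(nucleus_roi(paste0("p", k), "epithelial",
                                     polygon = poly), c(32L, 32L))
    want <- oracle_rasterize(poly, c(32L, 32L))
    expect_equal(unname(got), unname(want))
  }
})

test_that("a polygon ROI and its own rasterized mask measure identically", {
  set.seed(15)
  poly <- random_polygon(c(40L, 40L))
  r_poly <- nucleus_roi("a", "epithelial", polygon = poly)
  px <- rasterize_roi(r_poly, c(40L, 40L))
  r_mask <- nucleus_roi("a", "epithelial", pixels = px)
  expect_identical(rasterize_roi(r_mask, c(40L, 40L)), px)
})

test_that("ROI JSON round trip preserves geometry and classes", {
  rois <- list(
    nucleus_roi("c1", "control", polygon = cbind(c(1, 5, 5, 1), c(1, 1, 5, 5))),
    nucleus_roi("e1", "epithelial", polygon = cbind(c(8.5, 14, 11), c(2, 2, 8.25))))
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, path)
  back <- load_rois(path)
  expect_length(back, 2L)
  expect_identical(vapply(back, `[[`, "", "cell_class"),
                   c("control", "epithelial"))
  expect_equal(unname(back[[2]]$polygon), unname(rois[[2]]$polygon))
})

test_that("ROI validation rejects bad geometry and metadata", {
  bowtie <- cbind(c(0, 4, 0, 4), c(0, 4, 4, 0))
  expect_error(nucleus_roi("x", "control", polygon = bowtie),
               "self-intersecting")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(rois = list(list(id = "a", polygon = list(c(0, 0), c(4, 0), c(4, 4))))),
    path, auto_unbox = TRUE)
  expect_error(load_rois(path), "cell_class")
  rois <- list(nucleus_roi("a", "control",
                           polygon = cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))),
               nucleus_roi("a", "epithelial",
                           polygon = cbind(c(6, 9, 9, 6), c(6, 6, 9, 9))))
  write_rois(rois, path)
  expect_error(load_rois(path), "duplicate")
})

test_that("label masks with a class table load as ROIs", {
  mask <- matrix(0L, 12, 12)
  mask[2:4, 2:4] <- 1L
  mask[7:10, 7:9] <- 2L
  mpath <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(mask / 65535, mpath, bits.per.sample = 16L)
  cpath <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c(1L, 2L),
                       cell_class = c("control", "epithelial")),
            cpath, row.names = FALSE)
  rois <- load_rois(mpath, class_table = cpath)
  expect_length(rois, 2L)
  expect_equal(nrow(rasterize_roi(rois[[1]], c(12L, 12L))), 9L)
  expect_equal(rois[[2]]$cell_class, "epithelial")
})

test_that("overlap reporting equals a brute-force pixel-ownership count", {
  shape <- c(24L, 24L)
  mk <- function(id, x1, y1, s) nucleus_roi(id, "epithelial",
    polygon = cbind(c(x1, x1 + s, x1 + s, x1), c(y1, y1, y1 + s, y1 + s)))
  disjoint <- list(mk("a", 1, 1, 5), mk("b", 10, 10, 5))
  expect_true(check_nonoverlap(disjoint, shape)$ok)
  dup <- list(mk("a", 3, 3, 6), mk("b", 3, 3, 6))
  rep_dup <- check_nonoverlap(dup, shape)
  expect_false(rep_dup$ok)
  expect_equal(rep_dup$n_shared_pixels, 36L)
  set.seed(16)
  for (k in 1:10) {
    n <- 4L
    rois <- lapply(seq_len(n), function(i)
      mk(paste0("r", i), runif(1, 0, 16), runif(1, 0, 16), runif(1, 3, 7)))
    got <- check_nonoverlap(rois, shape)
    counts <- matrix(0L, shape[1], shape[2])
    for (r in rois) {
      px <- oracle_rasterize(r$polygon, shape)
      for (i in seq_len(nrow(px)))
        counts[px[i, 1] + 1L, px[i, 2] + 1L] <- counts[px[i, 1] + 1L, px[i, 2] + 1L] + 1L
    }
    expect_equal(got$n_shared_pixels, sum(counts >= 2L))
    expect_equal(got$ok, all(counts < 2L))
  }
})

test_that("study layout CSV validates and resolves relative paths", {
  dir <- withr::local_tempdir()
  lay <- data.frame(sample_id = c("s1", "s2"), condition = c("A", "B"),
                    image_path = c("s1.tif", "s2.tif"),
                    roi_path = c("s1.json", "s2.json"))
  path <- file.path(dir, "layout.csv")
  write.csv(lay, path, row.names = FALSE)
  got <- load_study_layout(path)
  expect_equal(got$image_path[1], file.path(normalizePath(dir), "s1.tif"))
  expect_identical(levels(got$condition), c("A", "B"))
  lay$sample_id <- c("s1", "s1")
  write.csv(lay, path, row.names = FALSE)
  expect_error(load_study_layout(path), "duplicate")
})
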