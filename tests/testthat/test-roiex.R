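test_that("hole filling and opening clean the mask as defined", {
  m <- matrix(0L, 20, 20)
  m[5:12, 5:12] <- 1L
  m[8, 8] <- 0L                      # 1-px interior hole
  m[17, 17] <- 1L; m[17, 18] <- 1L   # 2-px speck
  out <- postprocess_mask(m, radius = 3)
  expect_equal(out[8, 8], 1L)        # hole filled
  expect_equal(sum(out[16:19, 16:19]), 0)  # speck opened away
})

test_that("a large solid disc survives opening nearly unchanged", {
  m <- matrix(0L, 64, 64)
  cx <- 32; cy <- 32
  for (i in 1:64) for (j in 1:64)
    if ((i - cy)^2 + (j - cx)^2 <= 20^2) m[i, j] <- 1L
  out <- postprocess_mask(m, radius = 3)
  expect_lt(mean(out != m), 0.01)
})

test_that("empty masks yield no ROIs", {
  tile <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  expect_length(extract_rois(tile, matrix(0L, 64, 64)), 0)
})

test_that("a clump is centered on the canvas with computable margins", {
  tile <- array(200, c(200, 200, 3))
  m <- matrix(0L, 200, 200)
  m[51:150, 71:130] <- 1L            # 100 x 60 rectangle
  rois <- extract_rois(tile, m, min_area = 64, canvas = 512)
  expect_length(rois, 1)
  r <- rois[[1]]
  expect_equal(dim(r$canvas), c(512, 512, 3))
  expect_equal(unname(r$bbox), c(70, 50, 130, 150))
  expect_equal(r$area, 100 * 60)
  occ <- which(r$canvas[, , 1] > 0, arr.ind = TRUE)
  # (512-100)/2 = 206 rows and (512-60)/2 = 226 columns of zero margin
  expect_equal(min(occ[, 1]) - 1, 206)
  expect_equal(min(occ[, 2]) - 1, 226)
  expect_equal(max(occ[, 1]), 206 + 100)
  expect_equal(max(occ[, 2]), 226 + 60)
})

test_that("pixels outside the clump footprint are exactly zero", {
  rec <- generate_tile(small_spec(), seed = 23)
  rois <- extract_rois(rec$image, rec$mask, min_area = 64, canvas = 128)
  expect_gt(length(rois), 0)
  for (r in rois) {
    fg <- r$canvas[, , 1] + r$canvas[, , 2] + r$canvas[, , 3] > 0
    # foreground cannot exceed the component area (stain can hit 0 too)
    expect_lte(sum(fg), r$area)
  }
})

test_that("diagonally touching clumps merge under 8-connectivity", {
  tile <- array(100, c(32, 32, 3))
  m <- matrix(0L, 32, 32)
  m[5:10, 5:10] <- 1L
  m[11:16, 11:16] <- 1L              # touches only at the corner
  expect_equal(oracle_component_count(m, eight = TRUE), 1)
  rois <- extract_rois(tile, m, min_area = 10, canvas = 64)
  expect_length(rois, 1)
  expect_equal(rois[[1]]$area, 72)
})

test_that("min_area filters small components", {
  tile <- array(100, c(64, 64, 3))
  m <- matrix(0L, 64, 64)
  m[10:29, 10:29] <- 1L   # 400 px
  m[50:52, 50:52] <- 1L   # 9 px
  rois <- extract_rois(tile, m, min_area = 64, canvas = 64)
  expect_length(rois, 1)
  expect_equal(rois[[1]]$area, 400)
})

test_that("oversized components are downscaled, never cropped", {
  tile <- array(150, c(300, 300, 3))
  m <- matrix(0L, 300, 300)
  m[11:290, 51:250] <- 1L            # 280 x 200, larger than canvas 128
  rois <- extract_rois(tile, m, min_area = 64, canvas = 128)
  r <- rois[[1]]
  expect_equal(dim(r$canvas), c(128, 128, 3))
  occ <- which(r$canvas[, , 1] > 0, arr.ind = TRUE)
  h <- diff(range(occ[, 1])) + 1; w <- diff(range(occ[, 2])) + 1
  expect_lte(h, 128); expect_lte(w, 128)
  # aspect ratio 280/200 = 1.4 is preserved within rounding
  expect_equal(h / w, 280 / 200, tolerance = 0.05)
})

test_that("ROI areas conserve the mask foreground", {
  for (s in 1:5) {
    rec <- generate_tile(small_spec(), seed = 100 + s)
    rois <- extract_rois(rec$image, rec$mask, min_area = 1, canvas = 128)
    expect_equal(sum(vapply(rois, function(r) r$area, numeric(1))),
                 sum(rec$mask))
  }
})

test_that("ROI boxes re-project onto the tile without loss or overlap", {
  rec <- generate_tile(small_spec(), seed = 31)
  rois <- extract_rois(rec$image, rec$mask, min_area = 1, canvas = 128)
  cover <- matrix(0L, nrow(rec$mask), ncol(rec$mask))
  for (r in rois) {
    rows <- (r$bbox["y0"] + 1):r$bbox["y1"]
    cols <- (r$bbox["x0"] + 1):r$bbox["x1"]
    cover[rows, cols] <- cover[rows, cols] + 1L
  }
  # every foreground pixel lies inside exactly one box (clumps are
  # separated, so boxes do not overlap on foreground)
  expect_true(all(cover[rec$mask == 1] == 1L))
})

test_that("extracted ROI count equals the generator clump count", {
  spec <- small_spec()
  for (s in 1:20) {
    rec <- generate_tile(spec, seed = 200 + s)
    big <- sum(rec$clumps$area >= 64)
    rois <- extract_rois(rec$image, rec$mask, min_area = 64, canvas = 128)
    expect_equal(length(rois), big, info = paste("seed", 200 + s))
  }
})

test_that("write_rois emits PNGs and an aligned manifest", {
  dir <- withr::local_tempdir()
  rec <- generate_tile(small_spec(), seed = 40)
  rois <- extract_rois(rec$image, rec$mask, min_area = 64, canvas = 96,
                       source_tile = "t40")
  man <- write_rois(rois, dir)
  expect_equal(nrow(man), length(rois))
  expect_true(all(file.exists(file.path(dir, paste0(man$roi_id, ".png")))))
  expect_equal(man$area, vapply(rois, function(r) r$area, numeric(1)))
})
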