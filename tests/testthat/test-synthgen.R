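test_that("same spec and seed give byte-identical tiles", {
  spec <- small_spec()
  a <- generate_tile(spec, seed = 11)
  b <- generate_tile(spec, seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$clumps, b$clumps)
})

test_that("zero-clump spec yields an empty mask and clump list", {
  spec <- synth_spec(tile_size = 96, n_clumps = c(0, 0))
  rec <- generate_tile(spec, seed = 3)
  expect_equal(sum(rec$mask), 0)
  expect_equal(nrow(rec$clumps), 0)
})

test_that("requested clump count appears as connected components", {
  spec <- synth_spec(tile_size = 128, n_clumps = c(5, 5))
  rec <- generate_tile(spec, seed = 7)
  expect_equal(nrow(rec$clumps), 5)
  expect_equal(oracle_component_count(rec$mask), 5)
})

test_that("mask components match the clump list across seeds", {
  spec <- small_spec()
  for (s in 1:50) {
    rec <- generate_tile(spec, seed = s)
    expect_equal(oracle_component_count(rec$mask), nrow(rec$clumps),
                 info = paste("seed", s))
  }
})

test_that("every mask pixel belongs to exactly one listed clump", {
  rec <- generate_tile(small_spec(), seed = 19)
  expect_true(all(rec$clump_map[rec$mask == 1] %in% rec$clumps$clump_id))
  for (ci in rec$clumps$clump_id) {
    area <- sum(rec$clump_map == ci)
    expect_equal(area, rec$clumps$area[rec$clumps$clump_id == ci])
  }
  expect_equal(sum(rec$clumps$area), sum(rec$mask))
})

test_that("malignant boundaries are rougher than benign ones", {
  spec <- small_spec()
  rough <- NULL; lab <- NULL
  s <- 0
  while (is.null(rough) || length(rough) < 100) {
    s <- s + 1
    rec <- generate_tile(spec, seed = s)
    for (ci in rec$clumps$clump_id) {
      m <- rec$clump_map == ci
      interior <- rbind(m[-1, ], FALSE) & rbind(FALSE, m[-nrow(m), ]) &
        cbind(m[, -1], FALSE) & cbind(FALSE, m[, -ncol(m)])
      per <- sum(m & !interior)
      rough <- c(rough, per^2 / sum(m))
      lab <- c(lab, rec$clumps$label[rec$clumps$clump_id == ci])
    }
  }
  expect_gt(mean(rough[lab == "malignant"]), mean(rough[lab == "benign"]))
})

test_that("the mask is invariant to the staining palette", {
  spec <- small_spec()
  he <- generate_tile(spec, seed = 5, stain_style = "he")
  pap <- generate_tile(spec, seed = 5, stain_style = "pap")
  expect_identical(he$mask, pap$mask)
  expect_false(identical(he$image, pap$image))
})

test_that("stain palettes preserve luminance ordering of the base", {
  base <- matrix(runif(400), 20, 20)
  he <- render_stain("he", base)
  pap <- render_stain("pap", base)
  lum <- function(img) 0.299 * img[, , 1] + 0.587 * img[, , 2] +
    0.114 * img[, , 3]
  expect_gt(cor(as.vector(lum(he)), as.vector(lum(pap)),
                method = "spearman"), 0.999)
  # different palettes actually differ per pixel on non-trivial bases
  expect_gt(mean(he != pap), 0.9)
})

test_that("degenerate bases render as uniform tiles", {
  z <- render_stain("he", matrix(0, 4, 4))
  o <- render_stain("pap", matrix(1, 4, 4))
  for (ch in 1:3) {
    expect_equal(length(unique(as.vector(z[, , ch]))), 1)
    expect_equal(length(unique(as.vector(o[, , ch]))), 1)
  }
  expect_error(render_stain("giemsa", matrix(0, 2, 2)), "unknown")
})

test_that("invalid specs are rejected", {
  expect_error(synth_spec(tile_size = 64, clump_radius = c(30, 40)),
               "tile_size/2")
  expect_error(synth_spec(malignant_fraction = 1.5))
  expect_error(synth_spec(n_clumps = c(4, 2)))
})

test_that("generate_dataset writes a consistent manifest", {
  dir <- withr::local_tempdir()
  spec <- synth_spec(tile_size = 96, n_clumps = c(2, 4))
  man <- generate_dataset(spec, 10, dir, seed = 1, styles = c("he", "pap"))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_gte(nrow(man), 20)
  expect_lte(nrow(man), 40)
  expect_setequal(unique(man$stain_style), c("he", "pap"))
  expect_true(all(file.exists(file.path(dir, unique(man$image_path)))))
  expect_true(all(file.exists(file.path(dir, unique(man$mask_path)))))
  # masks on disk round-trip to the generated masks
  rec <- generate_tile(spec, seed = 1, stain_style = "he")
  m <- png::readPNG(file.path(dir, "masks", "tile_0001_mask.png"))
  expect_equal(matrix(as.integer(m > 0.5), nrow(m), ncol(m)), rec$mask)
})

test_that("an empty dataset still writes a header-only manifest", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(synth_spec(tile_size = 64), 0, dir)
  expect_equal(nrow(man), 0)
  onDisk <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(onDisk), 0)
  expect_true(all(c("tile_id", "image_path", "mask_path", "stain_style",
                    "clump_id", "x0", "y0", "x1", "y1", "label")
                  %in% names(onDisk)))
})
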