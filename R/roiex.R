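# Mask post-processing and ROI extraction: hole filling, morphological
# opening, 8-connected components, masked crop and centering on a fixed
# zero-padded canvas for the classifier.

#' Label 8-connected foreground components
#'
#' @param mask Binary matrix.
#' @return Integer matrix of component labels (1..n, background 0),
#'   numbered in raster order of first encounter.
#' @export
label_components <- function(mask) {
  .label_components8(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
}

#' Clean a predicted segmentation mask
#'
#' Fills interior holes, then applies a morphological opening with a disc
#' structuring element, removing specks smaller than the disc while
#' leaving large solid components essentially unchanged.
#'
#' @param mask Binary matrix.
#' @param radius Disc radius in pixels (default 3).
#' @return Binary integer matrix of the same shape.
#' @export
postprocess_mask <- function(mask, radius = 3) {
  m <- EBImage::Image(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
  m <- EBImage::fillHull(m)
  if (radius > 0)
    m <- EBImage::opening(m, EBImage::makeBrush(2 * radius + 1, "disc"))
  matrix(as.integer(m@.Data > 0.5), nrow(mask), ncol(mask))
}

#' Extract cell-clump ROIs from a tile and its mask
#'
#' Each 8-connected mask component with area at least `min_area` becomes
#' one ROI: the tile is cropped to the component's bounding box, pixels
#' outside the component are set to zero (unless `masked = FALSE`), and
#' the crop is centered on a square zero canvas. Components larger than
#' the canvas are downscaled preserving aspect ratio, never cropped.
#'
#' Boxes are 0-based, half-open, with x along image columns and y along
#' rows.
#'
#' @param tile H x W x 3 numeric array (0--255).
#' @param mask Binary H x W matrix aligned to the tile.
#' @param min_area Minimum component area in pixels (default 64).
#' @param canvas Canvas side length (default 512).
#' @param masked Zero out background pixels inside the box (default TRUE).
#' @param source_tile Identifier stored on each ROI.
#' @return List of `cell_clump_roi` objects: `canvas` (canvas x canvas x 3),
#'   `bbox` (`x0,y0,x1,y1`), `area`, `source_tile`, `label` (NA).
#' @export
extract_rois <- function(tile, mask, min_area = 64, canvas = 512,
                         masked = TRUE, source_tile = NA) {
  stopifnot(length(dim(tile)) == 3, all(dim(mask) == dim(tile)[1:2]))
  lab <- label_components(mask)
  n <- max(lab)
  out <- list()
  if (n == 0) return(out)
  areas <- tabulate(lab[lab > 0], nbins = n)
  for (ci in seq_len(n)) {
    if (areas[ci] < min_area) next
    idx <- which(lab == ci, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    h <- r1 - r0 + 1; w <- c1 - c0 + 1
    crop <- tile[r0:r1, c0:c1, , drop = FALSE]
    if (masked) {
      comp <- (lab[r0:r1, c0:c1, drop = FALSE] == ci)
      for (ch in 1:3) {
        sl <- crop[, , ch]; sl[!comp] <- 0; crop[, , ch] <- sl
      }
    }
    if (h > canvas || w > canvas) {
      f <- canvas / max(h, w)
      hn <- max(1, floor(h * f)); wn <- max(1, floor(w * f))
      sc <- array(0, c(hn, wn, 3))
      for (ch in 1:3)
        sc[, , ch] <- EBImage::resize(EBImage::Image(crop[, , ch]),
                                      w = hn, h = wn)@.Data
      crop <- sc; h <- hn; w <- wn
    }
    cv <- array(0, c(canvas, canvas, 3))
    oy <- floor((canvas - h) / 2); ox <- floor((canvas - w) / 2)
    cv[oy + seq_len(h), ox + seq_len(w), ] <- crop
    out[[length(out) + 1]] <- structure(
      list(canvas = cv,
           bbox = c(x0 = c0 - 1, y0 = r0 - 1, x1 = c1, y1 = r1),
           area = areas[ci],
           source_tile = source_tile,
           label = NA_character_),
      class = "cell_clump_roi")
  }
  out
}

#' Write ROIs as PNGs with a CSV manifest
#'
#' @param rois List of `cell_clump_roi` objects.
#' @param out_dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return The manifest data frame (`roi_id, tile_id, x0, y0, x1, y1,
#'   area, label`), invisibly; written as `rois.csv`.
#' @export
write_rois <- function(rois, out_dir, prefix = "roi") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    id <- sprintf("%s_%04d", prefix, i)
    png::writePNG(r$canvas / 255, file.path(out_dir, paste0(id, ".png")))
    data.frame(roi_id = id, tile_id = as.character(r$source_tile),
               x0 = r$bbox[1], y0 = r$bbox[2], x1 = r$bbox[3],
               y1 = r$bbox[4], area = r$area,
               label = if (is.na(r$label)) "" else r$label)
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write.csv(manifest, file.path(out_dir, "rois.csv"), row.names = FALSE)
  invisible(manifest)
}
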