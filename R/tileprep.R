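# Tile preparation: cropping large images into fixed-size tiles, rejecting
# uninformative background tiles by pooled intensity statistics, and the
# augmentation set used during training.

#' Background-filter rule
#'
#' Tiles are kept when their pooled pixel mean lies in
#' `[mean_lo, mean_hi]` (inclusive) and their pooled standard deviation is
#' strictly above `std_min`, all computed over every pixel and channel on
#' the 0--255 scale. The defaults (50, 230, 20) retain tiles that contain
#' actual cellular material and drop empty glass or saturated regions.
#'
#' @param mean_lo,mean_hi Inclusive bounds on the pooled mean intensity.
#' @param std_min Strict lower bound on the pooled standard deviation.
#' @return A `filter_rule` object.
#' @export
filter_rule <- function(mean_lo = 50, mean_hi = 230, std_min = 20) {
  stopifnot(mean_lo < mean_hi, std_min >= 0)
  structure(list(mean_lo = mean_lo, mean_hi = mean_hi, std_min = std_min),
            class = "filter_rule")
}

#' Crop an image into fixed-size tiles
#'
#' Slides a `tile_size` window with the given stride over the image;
#' windows that would overrun the image are dropped (edge remainders are
#' discarded rather than padded). Offsets are 0-based.
#'
#' @param image H x W x 3 numeric array (0--255) or H x W matrix.
#' @param tile_size Tile side length in pixels.
#' @param stride Step between tile origins; defaults to `tile_size`
#'   (non-overlapping grid).
#' @param source Identifier recorded in each tile's origin.
#' @return List of `image_tile` objects: `pixels`, `x`, `y` (0-based
#'   offsets) and `source`.
#' @export
tile_image <- function(image, tile_size, stride = tile_size,
                       source = "image") {
  if (tile_size <= 0) stop("tile_size must be positive")
  if (stride <= 0) stop("stride must be positive")
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 1))
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < tile_size || W < tile_size)
    stop("image smaller than tile_size in at least one dimension")
  ys <- seq(0, H - tile_size, by = stride)
  xs <- seq(0, W - tile_size, by = stride)
  tiles <- vector("list", length(ys) * length(xs))
  t <- 0
  for (y in ys) for (x in xs) {
    t <- t + 1
    tiles[[t]] <- structure(
      list(pixels = image[y + seq_len(tile_size), x + seq_len(tile_size), ,
                          drop = FALSE],
           x = x, y = y, source = source),
      class = "image_tile")
  }
  tiles
}

#' Decide whether a tile contains informative material
#'
#' @param tile An `image_tile` or a numeric pixel array (0--255).
#' @param rule A [filter_rule()].
#' @return `TRUE` iff pooled mean is within the rule's bounds and pooled
#'   standard deviation exceeds `std_min`.
#' @export
is_informative <- function(tile, rule = filter_rule()) {
  px <- if (inherits(tile, "image_tile")) tile$pixels else tile
  m <- mean(px)
  s <- stats::sd(as.numeric(px))
  m >= rule$mean_lo && m <= rule$mean_hi && s > rule$std_min
}

#' Tile statistics manifest
#'
#' Applies [is_informative()] to a list of tiles and returns the per-tile
#' bookkeeping (origin, pooled mean/std, kept flag).
#'
#' @param tiles List of `image_tile` objects.
#' @param rule A [filter_rule()].
#' @return Data frame with columns `tile_id, x, y, mean, std, kept`.
#' @export
tile_manifest <- function(tiles, rule = filter_rule()) {
  do.call(rbind, lapply(seq_along(tiles), function(i) {
    px <- tiles[[i]]$pixels
    m <- mean(px); s <- stats::sd(as.numeric(px))
    data.frame(tile_id = i, x = tiles[[i]]$x, y = tiles[[i]]$y,
               mean = m, std = s,
               kept = as.integer(m >= rule$mean_lo & m <= rule$mean_hi &
                                   s > rule$std_min))
  }))
}

.rot90 <- function(a) {
  # counter-clockwise quarter turn of an (H,W,C) array
  aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
}

#' Augment a tile (and optionally its mask) with one operation
#'
#' Supported operations: `vflip`, `hflip`, `rot90`, `rot180`, `rot270`,
#' `scale` (random or fixed factor, resized back to the original canvas by
#' center crop/pad) and `gray` (luminance replicated into all channels).
#' Geometric operations are applied identically to a paired mask.
#'
#' @param tile Numeric H x W x 3 array (0--255) or `image_tile`.
#' @param op Operation tag.
#' @param params Optional list; `scale` accepts `factor` (default drawn
#'   uniformly from `[0.8, 1.2]`).
#' @param mask Optional H x W matrix transformed alongside the pixels.
#' @return The augmented array, or `list(tile, mask)` when a mask is given.
#' @export
augment <- function(tile, op, params = list(), mask = NULL) {
  px <- if (inherits(tile, "image_tile")) tile$pixels else tile
  if (length(dim(px)) == 2) px <- array(px, c(dim(px), 1))
  geom <- function(a) {
    switch(op,
      vflip = a[dim(a)[1]:1, , , drop = FALSE],
      hflip = a[, dim(a)[2]:1, , drop = FALSE],
      rot90 = .rot90(a),
      rot180 = a[dim(a)[1]:1, dim(a)[2]:1, , drop = FALSE],
      rot270 = .rot90(.rot90(.rot90(a))),
      scale = .scale_back(a, params),
      stop("unsupported augmentation op: ", op))
  }
  if (op == "gray") {
    lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    out <- array(lum, c(dim(lum), 3))
    return(if (is.null(mask)) out else list(tile = out, mask = mask))
  }
  out <- geom(px)
  if (is.null(mask)) return(out)
  m3 <- geom(array(mask, c(dim(mask), 1)))
  list(tile = out, mask = matrix(m3[, , 1], dim(m3)[1], dim(m3)[2]))
}

.scale_back <- function(a, params) {
  f <- if (!is.null(params$factor)) params$factor else runif(1, 0.8, 1.2)
  H <- dim(a)[1]; W <- dim(a)[2]
  hs <- max(2, round(H * f)); ws <- max(2, round(W * f))
  sc <- array(0, c(hs, ws, dim(a)[3]))
  for (ch in seq_len(dim(a)[3]))
    sc[, , ch] <- EBImage::resize(EBImage::Image(a[, , ch]), w = hs, h = ws)@.Data
  out <- array(0, dim(a))
  if (f >= 1) {
    oy <- floor((hs - H) / 2); ox <- floor((ws - W) / 2)
    out <- sc[oy + seq_len(H), ox + seq_len(W), , drop = FALSE]
  } else {
    oy <- floor((H - hs) / 2); ox <- floor((W - ws) / 2)
    out[oy + seq_len(hs), ox + seq_len(ws), ] <- sc
  }
  out
}

#' Re-mosaic tiles onto a canvas by their recorded origins
#'
#' Inverse of [tile_image()] over the covered area; used to check that
#' tiling is lossless.
#'
#' @param tiles List of `image_tile` objects.
#' @param height,width Canvas dimensions.
#' @return Numeric array (height x width x channels).
#' @export
mosaic_tiles <- function(tiles, height, width) {
  C <- dim(tiles[[1]]$pixels)[3]
  out <- array(0, c(height, width, C))
  for (tl in tiles) {
    ts <- dim(tl$pixels)[1]
    out[tl$y + seq_len(ts), tl$x + seq_len(ts), ] <- tl$pixels
  }
  out
}
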