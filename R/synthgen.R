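# Synthetic cytology-tile generator.
#
# Emulates the screening setting end-to-end without real slides: each tile
# carries 0..n textured "cell clumps" (radially perturbed ellipses) over a
# background contaminated with small speckles standing in for single cells
# and leukocytes. Benign clumps have near-smooth boundaries, malignant
# clumps strongly irregular ones with protrusions, so the benign/malignant
# distinction is a measurable geometric property of the boundary. Tiles can
# be rendered in an H&E-like (pink/purple) or Papanicolaou-like
# (blue/green) palette over the same geometry, giving paired staining
# styles with identical ground truth.

#' Specification for the synthetic cytology-tile generator
#'
#' Collects every knob of the generator in one validated object. The same
#' spec plus the same seed always yields byte-identical tiles.
#'
#' @param tile_size Side length of the square tile in pixels.
#' @param n_clumps Integer range `c(lo, hi)`; the clump count of each tile
#'   is drawn uniformly from this range.
#' @param clump_radius Range of the nominal clump radius in pixels. Default
#'   scales with the tile: `tile_size * c(1/16, 1/7)`.
#' @param malignant_fraction Probability that a clump is malignant. The
#'   default 0.6 mirrors the roughly 60/40 positive/negative balance of
#'   typical screening collections.
#' @param boundary_irregularity Two-element list (`benign`, `malignant`),
#'   each with `amplitude` (total relative radial perturbation) and
#'   `harmonics` (angular frequencies of the radial Fourier perturbation).
#'   Malignant clumps additionally receive 1--3 narrow protrusions.
#' @param stain_style `"he"` or `"pap"`; the default palette used when a
#'   caller does not override the style per tile.
#' @param background_noise_density Expected background speckles per
#'   megapixel.
#' @param seed Default seed used by [generate_tile()] when none is given.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(tile_size = 1024,
                       n_clumps = c(0, 10),
                       clump_radius = NULL,
                       malignant_fraction = 0.6,
                       boundary_irregularity = list(
                         benign = list(amplitude = 0.04, harmonics = 2:4),
                         malignant = list(amplitude = 0.30, harmonics = 3:8)),
                       stain_style = "he",
                       background_noise_density = 150,
                       seed = 1L) {
  stopifnot(length(tile_size) == 1, tile_size > 0,
            length(n_clumps) == 2, n_clumps[1] >= 0,
            n_clumps[1] <= n_clumps[2],
            malignant_fraction >= 0, malignant_fraction <= 1,
            background_noise_density >= 0)
  if (is.null(clump_radius)) clump_radius <- tile_size * c(1 / 16, 1 / 7)
  stopifnot(length(clump_radius) == 2, clump_radius[1] > 0,
            clump_radius[1] <= clump_radius[2])
  if (max(clump_radius) >= tile_size / 2)
    stop("clump_radius must be below tile_size/2")
  stain_style <- match.arg(stain_style, c("he", "pap"))
  structure(list(tile_size = as.integer(tile_size),
                 n_clumps = as.integer(n_clumps),
                 clump_radius = clump_radius,
                 malignant_fraction = malignant_fraction,
                 boundary_irregularity = boundary_irregularity,
                 stain_style = stain_style,
                 background_noise_density = background_noise_density,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Multi-octave value noise in [0,1] (smoothstep-interpolated random grid);
# the multiplicative chromatin-like texture of the clump interiors.
.value_noise <- function(h, w, cell = 16, octaves = 3) {
  out <- matrix(0, h, w); amp <- 1; tot <- 0
  for (o in seq_len(octaves)) {
    gh <- ceiling(h / cell) + 2L
    gw <- ceiling(w / cell) + 2L
    g <- matrix(runif(gh * gw), gh, gw)
    ys <- (seq_len(h) - 1) / cell
    xs <- (seq_len(w) - 1) / cell
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    fy <- fy * fy * (3 - 2 * fy); fx <- fx * fx * (3 - 2 * fx)
    FY <- matrix(fy, h, w); FX <- matrix(fx, h, w, byrow = TRUE)
    v00 <- g[y0 + 1, x0 + 1]; v01 <- g[y0 + 1, x0 + 2]
    v10 <- g[y0 + 2, x0 + 1]; v11 <- g[y0 + 2, x0 + 2]
    out <- out + amp * ((1 - FY) * ((1 - FX) * v00 + FX * v01) +
                          FY * ((1 - FX) * v10 + FX * v11))
    tot <- tot + amp
    amp <- amp / 2; cell <- max(2, cell / 2)
  }
  out / tot
}

# Radial boundary of one clump: base ellipse times a low-order Fourier
# perturbation; malignant clumps add narrow Gaussian protrusions.
.clump_boundary <- function(r0, irr, malignant) {
  ecc <- runif(1, 0.65, 1)
  phi0 <- runif(1, 0, pi)
  nk <- length(irr$harmonics)
  A <- runif(nk); A <- A / sum(A) * irr$amplitude
  ph <- runif(nk, 0, 2 * pi)
  bumps <- NULL
  if (malignant) {
    nb <- sample(1:3, 1)
    bumps <- list(theta = runif(nb, 0, 2 * pi),
                  height = runif(nb, 0.15, 0.40),
                  width = runif(nb, 0.15, 0.30))
  }
  function(theta) {
    tr <- theta - phi0
    base <- ecc / sqrt((ecc * cos(tr))^2 + sin(tr)^2)
    pert <- rep(1, length(theta))
    for (k in seq_len(nk))
      pert <- pert + A[k] * cos(irr$harmonics[k] * theta + ph[k])
    if (!is.null(bumps))
      for (j in seq_along(bumps$theta)) {
        d <- (theta - bumps$theta[j]) %% (2 * pi)
        d <- pmin(d, 2 * pi - d)
        pert <- pert + bumps$height[j] * exp(-d^2 / (2 * bumps$width[j]^2))
      }
    r0 * base * pmax(pert, 0.05)
  }
}

#' Generate one synthetic cytology tile
#'
#' Draws the clump count, places non-overlapping clumps by rejection
#' sampling, rasterizes their perturbed boundaries, textures the interiors
#' with value noise, adds background speckles (image only, never the mask)
#' and renders the configured staining palette.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; defaults to `spec$seed`. All randomness is
#'   scoped to this call (the global RNG state is untouched).
#' @param stain_style Optional palette override (`"he"` or `"pap"`).
#' @return A `synth_record`: list with `image` (H x W x 3 integer array,
#'   0--255), `mask` (H x W integer matrix, 1 = clump), `clumps`
#'   (data frame with 0-based half-open boxes `x0,y0,x1,y1`, `label`,
#'   centroid `cx,cy` and `area`), `stain_style` and `seed`.
#' @export
generate_tile <- function(spec, seed = spec$seed, stain_style = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  style <- if (is.null(stain_style)) spec$stain_style else
    match.arg(stain_style, c("he", "pap"))
  ts <- spec$tile_size
  withr::with_seed(seed, {
    n <- if (spec$n_clumps[1] == spec$n_clumps[2]) spec$n_clumps[1] else
      sample(seq(spec$n_clumps[1], spec$n_clumps[2]), 1)
    mask <- matrix(0L, ts, ts)
    base <- matrix(0, ts, ts)
    placed <- list()
    rows <- list()
    for (ci in seq_len(n)) {
      malignant <- runif(1) < spec$malignant_fraction
      irr <- spec$boundary_irregularity[[if (malignant) "malignant" else "benign"]]
      r0 <- runif(1, spec$clump_radius[1], spec$clump_radius[2])
      ok <- FALSE
      # crowded tiles: progressively shrink the drawn radius rather than
      # fail, so the requested clump count is always honored
      while (!ok && r0 >= 1.5) {
        rmax <- r0 * (1 + irr$amplitude + if (malignant) 0.45 else 0)
        for (try in 1:200) {
          cx <- runif(1, rmax + 2, ts - rmax - 2)
          cy <- runif(1, rmax + 2, ts - rmax - 2)
          clear <- TRUE
          for (p in placed)
            if (sqrt((cx - p$cx)^2 + (cy - p$cy)^2) < rmax + p$rmax + 4) {
              clear <- FALSE; break
            }
          if (clear) { ok <- TRUE; break }
        }
        if (!ok) r0 <- r0 * 0.85
      }
      if (!ok) stop("could not place ", n, " non-overlapping clumps; ",
                    "reduce n_clumps or clump_radius")
      bound <- .clump_boundary(r0, irr, malignant)
      # rasterize within the clump's bounding window
      x0w <- max(1, floor(cx - rmax)); x1w <- min(ts, ceiling(cx + rmax))
      y0w <- max(1, floor(cy - rmax)); y1w <- min(ts, ceiling(cy + rmax))
      xs <- x0w:x1w; ys <- y0w:y1w
      DX <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
      DY <- matrix(ys - cy, length(ys), length(xs))
      theta <- atan2(DY, DX)
      inside <- sqrt(DX^2 + DY^2) <= matrix(bound(as.numeric(theta)),
                                            length(ys), length(xs))
      sub <- mask[ys, xs, drop = FALSE]
      sub[inside] <- ci
      mask[ys, xs] <- sub
      tex <- .value_noise(length(ys), length(xs),
                          cell = max(4, round(r0 / 4)), octaves = 3)
      bsub <- base[ys, xs, drop = FALSE]
      bsub[inside] <- 0.45 + 0.5 * tex[inside]
      base[ys, xs] <- bsub
      idx <- which(inside, arr.ind = TRUE)
      px_y <- ys[idx[, 1]]; px_x <- xs[idx[, 2]]
      rows[[ci]] <- data.frame(
        clump_id = ci,
        x0 = min(px_x) - 1L, y0 = min(px_y) - 1L,
        x1 = max(px_x), y1 = max(px_y),
        label = if (malignant) "malignant" else "benign",
        cx = mean(px_x - 1), cy = mean(px_y - 1),
        area = nrow(idx))
      placed[[ci]] <- list(cx = cx, cy = cy, rmax = rmax)
    }
    # background speckles: small discs (radius <= 3 px), image only
    nspeck <- stats::rpois(1, spec$background_noise_density * ts^2 / 1e6)
    if (nspeck > 0) {
      sx <- runif(nspeck, 1, ts); sy <- runif(nspeck, 1, ts)
      sr <- sample(1:3, nspeck, replace = TRUE)
      sv <- runif(nspeck, 0.3, 0.8)
      for (s in seq_len(nspeck)) {
        xs <- max(1, floor(sx[s] - sr[s])):min(ts, ceiling(sx[s] + sr[s]))
        ys <- max(1, floor(sy[s] - sr[s])):min(ts, ceiling(sy[s] + sr[s]))
        DX <- matrix(xs - sx[s], length(ys), length(xs), byrow = TRUE)
        DY <- matrix(ys - sy[s], length(ys), length(xs))
        hit <- (DX^2 + DY^2 <= sr[s]^2) & (mask[ys, xs, drop = FALSE] == 0L)
        bsub <- base[ys, xs, drop = FALSE]
        bsub[hit] <- pmax(bsub[hit], sv[s])
        base[ys, xs] <- bsub
      }
    }
    clumps <- if (length(rows)) do.call(rbind, rows) else
      data.frame(clump_id = integer(), x0 = integer(), y0 = integer(),
                 x1 = integer(), y1 = integer(), label = character(),
                 cx = numeric(), cy = numeric(), area = integer())
    structure(list(image = render_stain(style, base),
                   mask = matrix(as.integer(mask > 0), ts, ts),
                   clump_map = mask,
                   clumps = clumps,
                   stain_style = style,
                   seed = as.integer(seed)),
              class = "synth_record")
  })
}

#' Render a grayscale base raster in a staining palette
#'
#' Maps intensities in `[0, 1]` through a two-color palette: `"he"` uses a
#' pale-pink background running to a deep hematoxylin purple, `"pap"` a
#' pale-cyan background running to a dark blue-green. Both palettes are
#' strictly monotone in luminance, so the relative brightness ordering of
#' pixels is preserved across styles.
#'
#' @param style `"he"` or `"pap"`.
#' @param base Numeric matrix with values in `[0, 1]` (0 = background).
#' @return An H x W x 3 integer array with values in 0--255.
#' @export
render_stain <- function(style, base) {
  stopifnot(is.matrix(base), all(base >= 0), all(base <= 1))
  pal <- switch(style,
    he  = list(bg = c(246, 236, 243), fg = c(92, 38, 118)),
    pap = list(bg = c(235, 244, 240), fg = c(28, 88, 96)),
    stop("unknown stain style: ", style))
  out <- array(0L, c(nrow(base), ncol(base), 3))
  for (ch in 1:3)
    out[, , ch] <- as.integer(round(pal$bg[ch] +
                                      base * (pal$fg[ch] - pal$bg[ch])))
  out
}

#' Write a synthetic dataset to disk
#'
#' Generates `n_tiles` tiles (seeds `seed, seed+1, ...`), writes images and
#' masks as PNG and a clump-level CSV manifest. Mask PNGs store foreground
#' as 255. The manifest has one row per clump; zero-clump tiles contribute
#' no rows.
#'
#' @param spec A [synth_spec()].
#' @param n_tiles Number of tiles to generate.
#' @param out_dir Output directory (created if missing).
#' @param seed Base seed; tile i uses `seed + i - 1`.
#' @param styles Stain style per tile, recycled (default: `spec$stain_style`).
#' @return The manifest data frame, invisibly; also written as
#'   `manifest.csv` under `out_dir`.
#' @export
generate_dataset <- function(spec, n_tiles, out_dir, seed = spec$seed,
                             styles = spec$stain_style) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  styles <- rep_len(styles, max(n_tiles, 1L))
  empty <- data.frame(tile_id = character(), image_path = character(),
                      mask_path = character(), stain_style = character(),
                      clump_id = integer(), x0 = integer(), y0 = integer(),
                      x1 = integer(), y1 = integer(), label = character())
  rows <- list()
  for (i in seq_len(n_tiles)) {
    rec <- generate_tile(spec, seed = seed + i - 1L, stain_style = styles[i])
    tile_id <- sprintf("tile_%04d", i)
    ip <- file.path("images", paste0(tile_id, ".png"))
    mp <- file.path("masks", paste0(tile_id, "_mask.png"))
    png::writePNG(aperm(array(rec$image / 255,
                              dim = dim(rec$image)), c(1, 2, 3)),
                  file.path(out_dir, ip))
    png::writePNG(rec$mask * 1.0, file.path(out_dir, mp))
    if (nrow(rec$clumps))
      rows[[i]] <- data.frame(tile_id = tile_id, image_path = ip,
                              mask_path = mp, stain_style = rec$stain_style,
                              rec$clumps[, c("clump_id", "x0", "y0",
                                             "x1", "y1", "label")])
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(manifest) <- NULL
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Build an in-memory labeled ROI dataset from synthetic tiles
#'
#' Generates tiles (alternating over `styles`), extracts ROIs from the
#' ground-truth masks with [extract_rois()] and labels each ROI with the
#' class of the generator clump whose centroid falls inside its box.
#'
#' @param n_rois Minimum number of ROIs to accumulate.
#' @param spec A [synth_spec()]; small tiles are fine.
#' @param seed Base seed (tile i uses `seed + i - 1`).
#' @param styles Stain styles cycled over tiles.
#' @param canvas ROI canvas size passed to [extract_rois()].
#' @param min_area Minimum clump area in pixels.
#' @return List with `rois` (list of canvas arrays, 0--255), `labels`
#'   (character), `styles`, and `tile_ids` (generator seed of the source
#'   tile, usable as a grouping id).
#' @export
synth_roi_dataset <- function(n_rois, spec, seed = 1L,
                              styles = c("he", "pap"),
                              canvas = 128L, min_area = 64) {
  rois <- list(); labels <- character(); sty <- character()
  tile_ids <- integer(); i <- 0L
  while (length(rois) < n_rois) {
    i <- i + 1L
    if (i > 50L * max(n_rois, 1L)) stop("generator produced too few clumps")
    style <- styles[((i - 1L) %% length(styles)) + 1L]
    rec <- generate_tile(spec, seed = seed + i - 1L, stain_style = style)
    ex <- extract_rois(rec$image, rec$mask, min_area = min_area,
                       canvas = canvas)
    for (r in ex) {
      hit <- rec$clumps$cx >= r$bbox[1] & rec$clumps$cx < r$bbox[3] &
        rec$clumps$cy >= r$bbox[2] & rec$clumps$cy < r$bbox[4]
      if (sum(hit) != 1) next
      rois[[length(rois) + 1L]] <- r$canvas
      labels <- c(labels, rec$clumps$label[hit])
      sty <- c(sty, style)
      tile_ids <- c(tile_ids, rec$seed)
    }
  }
  list(rois = rois, labels = labels, styles = sty, tile_ids = tile_ids)
}
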