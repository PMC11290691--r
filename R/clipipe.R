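# Orchestration: end-to-end screening of a tile, grouped k-fold
# cross-validation, the two-stage vs one-stage comparison, and YAML
# run-configuration round-tripping.

#' Default run configuration
#'
#' One nested list holding every stage's configuration plus global seed,
#' fold count and output directory; round-trips unchanged through YAML.
#'
#' @param seed Global seed.
#' @param folds Cross-validation fold count (default 10).
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, folds = 10L, out_dir = "cytoscreen_out") {
  structure(list(
    seed = as.integer(seed), folds = as.integer(folds), out_dir = out_dir,
    tileprep = list(tile_size = 1024L, stride = 1024L,
                    mean_lo = 50, mean_hi = 230, std_min = 20),
    cmunet = list(depth = 4L, lr = 5e-3, batch_size = 32L, epochs = 20L,
                  ca_enabled = TRUE, mss_enabled = TRUE,
                  literal_eq6 = FALSE, threshold = 0.5),
    roiex = list(min_area = 64L, canvas = 512L, open_radius = 3L),
    ecrnet = list(input_size = 64L, embed_dim = 128L, tau = 0.07,
                  momentum = 0.9, beta_loss = 0.5, bank_capacity = 4096L,
                  lr = 5e-3, batch_size = 32L, epochs = 15L)),
    class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(utils::modifyList(unclass(default_config()), cfg),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Deterministic grouped fold assignment
#'
#' Shuffles the unique groups under the seed and deals them round-robin
#' into k folds, so all members of a group (e.g., all ROIs of one source
#' tile) land in the same fold.
#'
#' @param groups Vector of group ids, one per sample.
#' @param k Number of folds.
#' @param seed Seed controlling the shuffle.
#' @return Integer fold id (1..k) per sample.
#' @export
assign_folds <- function(groups, k = 10, seed = 1L) {
  ug <- unique(groups)
  if (k > length(ug))
    stop("k = ", k, " exceeds the number of groups (", length(ug), ")")
  withr::with_seed(seed, {
    ug <- sample(ug)
    fold_of <- setNames(rep_len(seq_len(k), length(ug)), ug)
    as.integer(fold_of[as.character(groups)])
  })
}

#' Grouped k-fold cross-validation
#'
#' Splits samples into k folds by group (no group straddles folds), calls
#' `trainer(train_idx, test_idx)` per fold and collects per-fold
#' evaluation reports plus their mean metrics.
#'
#' @param labels True labels, one per sample.
#' @param groups Group id per sample (samples of one source image share a
#'   group).
#' @param trainer Function of `(train_idx, test_idx)` returning
#'   `list(pred = labels, scores = numeric or NULL)` for the test
#'   samples.
#' @param k Fold count (default 10).
#' @param seed Seed for the fold shuffle.
#' @return List with `folds` (assignment), `reports` (per fold) and
#'   `mean` (metric means over folds, NA-dropped).
#' @export
crossval <- function(labels, groups, trainer, k = 10, seed = 1L) {
  folds <- assign_folds(groups, k, seed)
  reports <- lapply(seq_len(k), function(f) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    out <- trainer(train_idx, test_idx)
    eval_report(labels[test_idx], out$pred, scores = out$scores)
  })
  metric <- function(nm) {
    v <- vapply(reports, function(r)
      if (is.null(r[[nm]])) NA_real_ else r[[nm]], numeric(1))
    mean(v, na.rm = TRUE)
  }
  list(folds = folds, reports = reports,
       mean = list(accuracy = metric("accuracy"),
                   sensitivity = metric("sensitivity"),
                   precision = metric("precision"),
                   f1 = metric("f1"),
                   auc = metric("auc")))
}

#' Save a trained model with a JSON sidecar
#'
#' Writes the model in R's native serialized format plus a
#' `<path>.json` sidecar holding the configuration and seed, so any run
#' can be reproduced from its artifacts.
#'
#' @param model A `cmunet_model` or `ecrnet_model`.
#' @param path Destination file (conventionally `.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- model$config
  class(side) <- NULL
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path File written by [save_model()].
#' @return The model object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("missing model file: ", path)
  readRDS(path)
}

.draw_box <- function(img, bbox, color, lwd = 2) {
  H <- dim(img)[1]; W <- dim(img)[2]
  x0 <- max(1, bbox[1] + 1); y0 <- max(1, bbox[2] + 1)
  x1 <- min(W, bbox[3]); y1 <- min(H, bbox[4])
  for (t in seq_len(lwd) - 1) {
    rows <- c(min(y0 + t, H), max(y1 - t, 1))
    cols <- c(min(x0 + t, W), max(x1 - t, 1))
    for (ch in 1:3) {
      img[rows, x0:x1, ch] <- color[ch]
      img[y0:y1, cols, ch] <- color[ch]
    }
  }
  img
}

#' Screen one tile end-to-end
#'
#' Segments the tile, cleans the mask, extracts ROIs, classifies each and
#' assembles an annotated result: the tile is flagged positive if any ROI
#' is called malignant. The overlay colors benign boxes green and
#' malignant boxes red.
#'
#' @param models `list(segmenter = cmunet_model, classifier =
#'   ecrnet_model)`.
#' @param tile H x W x 3 array (0--255) or `image_tile`.
#' @param min_area,canvas,open_radius ROI-extraction settings.
#' @param threshold Segmentation threshold.
#' @return List: `mask` (post-processed), `rois` (data frame with boxes,
#'   probabilities and labels), `overlay` (annotated array),
#'   `tile_positive`, `n_rois`.
#' @export
run_screening <- function(models, tile, min_area = 64, canvas = 512,
                          open_radius = 3,
                          threshold = models$segmenter$config$threshold) {
  if (is.null(models$segmenter) || is.null(models$classifier))
    stop("both a segmenter and a classifier model are required")
  px <- if (inherits(tile, "image_tile")) tile$pixels else tile
  mask <- segment(models$segmenter, px, threshold)
  mask <- postprocess_mask(mask, open_radius)
  rois <- extract_rois(px, mask, min_area = min_area, canvas = canvas)
  overlay <- px
  rows <- list()
  for (i in seq_along(rois)) {
    res <- suppressWarnings(classify(models$classifier, rois[[i]]))
    rows[[i]] <- data.frame(
      roi_id = i,
      x0 = rois[[i]]$bbox[1], y0 = rois[[i]]$bbox[2],
      x1 = rois[[i]]$bbox[3], y1 = rois[[i]]$bbox[4],
      area = rois[[i]]$area,
      p_benign = res$probabilities["benign"],
      p_malignant = res$probabilities["malignant"],
      label = res$label)
    overlay <- .draw_box(overlay, rois[[i]]$bbox,
                         if (res$label == "malignant") c(220, 30, 30)
                         else c(30, 180, 60))
  }
  roi_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(roi_id = integer(), x0 = integer(), y0 = integer(),
               x1 = integer(), y1 = integer(), area = integer(),
               p_benign = numeric(), p_malignant = numeric(),
               label = character())
  rownames(roi_df) <- NULL
  list(mask = mask, rois = roi_df, overlay = overlay,
       n_rois = nrow(roi_df),
       tile_positive = any(roi_df$label == "malignant"))
}

#' Compare two-stage (ROI) against one-stage (whole-tile) classification
#'
#' Trains and evaluates the contrastive classifier twice under identical
#' seeds and splits: (a) on ROIs extracted from the ground-truth masks
#' and (b) on whole tiles resized to the classifier input, labeled
#' positive when they contain any malignant clump. The one-stage arm sees
#' the background noise the two-stage arm has removed.
#'
#' @param records List of `synth_record` tiles (see [generate_tile()]).
#' @param config An [ecrnet_config()] shared by both arms.
#' @param min_area,canvas ROI-extraction settings for the two-stage arm.
#' @param test_frac Fraction of tiles held out (split by tile).
#' @param seed Split seed.
#' @return `list(two_stage = eval_report, one_stage = eval_report)`.
#' @export
two_stage_vs_one_stage <- function(records, config = ecrnet_config(),
                                   min_area = 64, canvas = 128,
                                   test_frac = 0.3, seed = 1L) {
  rois <- list(); roi_labels <- character(); roi_tile <- integer()
  tiles <- list(); tile_labels <- character(); tile_ids <- integer()
  for (ti in seq_along(records)) {
    rec <- records[[ti]]
    if (nrow(rec$clumps) == 0) next
    ex <- extract_rois(rec$image, rec$mask, min_area = min_area,
                       canvas = canvas)
    for (r in ex) {
      hit <- rec$clumps$cx >= r$bbox[1] & rec$clumps$cx < r$bbox[3] &
        rec$clumps$cy >= r$bbox[2] & rec$clumps$cy < r$bbox[4]
      if (sum(hit) != 1) next
      rois[[length(rois) + 1]] <- r$canvas
      roi_labels <- c(roi_labels, rec$clumps$label[hit])
      roi_tile <- c(roi_tile, ti)
    }
    tiles[[length(tiles) + 1]] <- rec$image
    tile_ids <- c(tile_ids, ti)
    tile_labels <- c(tile_labels,
                     if (any(rec$clumps$label == "malignant"))
                       "malignant" else "benign")
  }
  used <- unique(roi_tile)
  test_tiles <- withr::with_seed(seed,
    sample(used, max(1, round(length(used) * test_frac))))
  arm <- function(x, labels, group) {
    te <- group %in% test_tiles
    if (length(unique(labels[!te])) < 2 || length(unique(labels[te])) < 2)
      stop("split left a single class in one arm; use more tiles")
    m <- train_classifier(x[!te], labels[!te], config)
    pr <- .classify_batch(m, x[te])
    eval_report(labels[te], pr$label,
                scores = pr$probs[, "malignant"])
  }
  list(two_stage = arm(rois, roi_labels, roi_tile),
       one_stage = arm(tiles, tile_labels, tile_ids))
}
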