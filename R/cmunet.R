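# Nested dense-skip segmentation network ("CM-UNet"-style): a UNet++-like
# node grid X^{i,j} (row i = depth, column j), a channel self-attention
# module at the bottleneck, multi-level semantic supervision through
# weighted side heads on the full-resolution row, and a hybrid
# cross-entropy + per-pixel Dice loss.
#
# Node rule: x[i,0] = H(D(x[i-1,0])) down the encoder spine, and for j>0
# x[i,j] = H([x[i,0..j-1], U(x[i+1,j-1])]), where H is a small convolution
# block, D max-pooling, U nearest upsampling and [.] channel concatenation.

#' Valid node coordinates of the nested grid
#'
#' @param depth Network depth `d`.
#' @return Data frame of all valid `(i, j)` with `i + j <= d`; row `i` has
#'   `d - i + 1` nodes, `(d+1)(d+2)/2` nodes in total.
#' @export
cmunet_topology <- function(depth) {
  stopifnot(depth >= 1)
  do.call(rbind, lapply(0:depth, function(i)
    data.frame(i = i, j = 0:(depth - i))))
}

#' Configuration of the segmentation network
#'
#' @param depth Grid depth `d` (default 4; spatial size halves per row).
#' @param widths Channel width per row, length `depth + 1`.
#' @param in_channels Input channels (3 for RGB).
#' @param n_classes Segmentation classes (2: background/foreground).
#' @param block_convs 3x3 convolutions per node block.
#' @param ca `list(enabled, literal_eq2)`: channel attention at the
#'   bottleneck. `literal_eq2` switches the affinity softmax to the
#'   degenerate self-similarity normalization kept for fidelity
#'   experiments (inference only).
#' @param mss `list(enabled, alphas)`: multi-level semantic supervision;
#'   `alphas` are per-level weights ordered from the earliest supervised
#'   column to the final one. Default: the last `depth` values of
#'   `(0.1, 0.3, 0.6, 0.9)` (for `depth = 4` exactly that sequence).
#' @param loss `list(literal_eq6, eps)`: `literal_eq6` multiplies the
#'   total loss by the depth (the printed d-fold summation); `eps` guards
#'   the Dice-term denominator.
#' @param lr,batch_size,epochs Adam learning rate (default 5e-3), batch
#'   size (default 32) and epoch budget.
#' @param augment Random flip/rotation/gray augmentation during training.
#' @param threshold Default probability threshold of [segment()].
#' @param early_stop_dice Optional validation Dice at which training stops
#'   early.
#' @param seed RNG seed for initialization and batching.
#' @return A `cmunet_config` list.
#' @export
cmunet_config <- function(depth = 4,
                          widths = c(16, 32, 64, 128, 256)[seq_len(depth + 1)],
                          in_channels = 3, n_classes = 2, block_convs = 2,
                          ca = list(enabled = TRUE, literal_eq2 = FALSE),
                          mss = list(enabled = TRUE, alphas = NULL),
                          loss = list(literal_eq6 = FALSE, eps = 1e-7),
                          lr = 5e-3, batch_size = 32, epochs = 20,
                          augment = TRUE, threshold = 0.5,
                          early_stop_dice = NULL, seed = 1L) {
  stopifnot(depth >= 1, length(widths) == depth + 1, all(widths > 0),
            n_classes >= 2, block_convs >= 1, lr > 0, batch_size >= 1)
  if (is.null(ca$literal_eq2)) ca$literal_eq2 <- FALSE
  if (is.null(mss$alphas)) {
    if (depth > 4) stop("supply mss$alphas explicitly for depth > 4")
    mss$alphas <- tail(c(0.1, 0.3, 0.6, 0.9), depth)
  }
  if (isTRUE(mss$enabled) && length(mss$alphas) != depth)
    stop("mss$alphas must have one weight per supervised level (depth)")
  if (any(mss$alphas < 0)) stop("alphas must be nonnegative")
  if (is.null(loss$eps)) loss$eps <- 1e-7
  structure(list(depth = depth, widths = widths, in_channels = in_channels,
                 n_classes = n_classes, block_convs = block_convs,
                 ca = ca, mss = mss, loss = loss, lr = lr,
                 batch_size = batch_size, epochs = epochs,
                 augment = augment, threshold = threshold,
                 early_stop_dice = early_stop_dice, seed = as.integer(seed)),
            class = "cmunet_config")
}

# ---- channel attention ----------------------------------------------------

#' Channel affinity matrix
#'
#' Flattens a feature map to K channel vectors and returns the K x K
#' matrix `M` whose row `b` is the softmax over `a` of the affinity
#' `x_a . x_b`; `M[b, a]` is the influence of channel `a` on channel `b`
#' and each row sums to 1. With `literal_eq2 = TRUE` the denominator uses
#' the self-similarity `x_b . x_b` instead (rows then no longer
#' normalize); this degenerate variant is retained only for fidelity
#' inspection.
#'
#' @param x Feature map, H x W x K array (or K x P matrix of flattened
#'   channels).
#' @param literal_eq2 Use the degenerate self-similarity normalization.
#' @return K x K affinity matrix.
#' @export
channel_affinity <- function(x, literal_eq2 = FALSE) {
  Xk <- if (is.matrix(x)) x else t(matrix(x, prod(dim(x)[1:2]), dim(x)[3]))
  K <- nrow(Xk)
  if (K == 0) stop("feature map has zero channels")
  S <- Xk %*% t(Xk)
  if (literal_eq2) {
    exp(S - diag(S)) / K      # exp(s_ab) / (K exp(s_bb)), row b
  } else {
    E <- exp(S - apply(S, 1, max))
    E / rowSums(E)
  }
}

#' Channel attention module
#'
#' `E_b = beta * sum_a M[b, a] x_a + x_b`: a residual reweighting of the
#' channels by their pairwise affinities. `beta` is a learned scalar
#' initialized at 0, so an untrained module is exactly the identity.
#'
#' @param x Feature map, H x W x K array or K x P matrix.
#' @param beta Scalar attention weight.
#' @param literal_eq2 See [channel_affinity()].
#' @return Feature map of the same shape as `x`.
#' @export
channel_attention <- function(x, beta = 0, literal_eq2 = FALSE) {
  Xk <- if (is.matrix(x)) x else t(matrix(x, prod(dim(x)[1:2]), dim(x)[3]))
  M <- channel_affinity(Xk, literal_eq2)
  E <- beta * (M %*% Xk) + Xk
  if (is.matrix(x)) E else array(t(E), dim(x))
}

# Batched CA forward/backward used inside the network (softmax form only).
.ca_fwd_batch <- function(x, beta) {
  d <- dim(x); P <- d[1] * d[2]; K <- d[3]; N <- d[4]
  y <- x
  cache <- vector("list", N)
  for (n in seq_len(N)) {
    Xk <- t(matrix(x[, , , n], P, K))
    S <- Xk %*% t(Xk)
    Em <- exp(S - apply(S, 1, max))
    M <- Em / rowSums(Em)
    MX <- M %*% Xk
    y[, , , n] <- array(t(beta * MX + Xk), d[1:3])
    cache[[n]] <- list(Xk = Xk, M = M, MX = MX)
  }
  list(y = y, cache = cache)
}

.ca_bwd_batch <- function(cache, dy, beta) {
  d <- dim(dy); P <- d[1] * d[2]; K <- d[3]; N <- d[4]
  dx <- dy
  dbeta <- 0
  for (n in seq_len(N)) {
    cn <- cache[[n]]
    dE <- t(matrix(dy[, , , n], P, K))
    dbeta <- dbeta + sum(dE * cn$MX)
    dM <- beta * (dE %*% t(cn$Xk))
    dXk <- dE + beta * (t(cn$M) %*% dE)
    dS <- cn$M * (dM - rowSums(dM * cn$M))
    dXk <- dXk + dS %*% cn$Xk + t(dS) %*% cn$Xk
    dx[, , , n] <- array(t(dXk), d[1:3])
  }
  list(dx = dx, dbeta = dbeta)
}

# ---- losses ---------------------------------------------------------------

#' Hybrid segmentation loss
#'
#' Per-pixel cross-entropy plus a per-pixel Dice-style overlap reward:
#' `-(1/N) * sum_c sum_n [ t log p + 2 t p / (t^2 + p^2 + eps) ]`, where N
#' is the number of pixels (not pixel-class pairs). The overlap term makes
#' the loss negative at perfect predictions (a single true pixel with
#' `p = 1` contributes exactly -1), and `eps` defines the 0/0 case at
#' `t = p = 0` as 0.
#'
#' @param t One-hot ground truth array.
#' @param p Predicted probabilities, same shape as `t`.
#' @param eps Stability constant in the overlap denominator.
#' @param n_classes Number of classes `C`; inferred from the third
#'   dimension when `t` has one, else 1.
#' @return Scalar loss (finite; possibly negative).
#' @export
hybrid_loss <- function(t, p, eps = 1e-7, n_classes = NULL) {
  if (!all(dim(t) == dim(p)) || length(t) != length(p))
    stop("shape mismatch between target and prediction")
  if (is.null(n_classes))
    n_classes <- if (length(dim(t)) >= 3) dim(t)[3] else 1
  N <- length(t) / n_classes
  pc <- .clamp(p)
  -sum(t * log(pc) + 2 * t * p / (t^2 + p^2 + eps)) / N
}

# Gradient of hybrid_loss with respect to p.
.hybrid_loss_grad <- function(t, p, eps = 1e-7, n_classes = NULL) {
  if (is.null(n_classes))
    n_classes <- if (length(dim(t)) >= 3) dim(t)[3] else 1
  N <- length(t) / n_classes
  pc <- .clamp(p)
  -(t / pc + 2 * t * (t^2 - p^2 + eps) / (t^2 + p^2 + eps)^2) / N
}

#' Multi-level side loss
#'
#' The weighted sum `sum_i alpha_i * hybrid_loss(target, S_i)` over the
#' side predictions of the supervised levels.
#'
#' @param side_probs List of per-level probability maps, already at the
#'   target resolution.
#' @param target One-hot ground truth.
#' @param alphas Per-level weights, same length as `side_probs`.
#' @param eps Passed to [hybrid_loss()].
#' @return Scalar side loss.
#' @export
side_loss <- function(side_probs, target, alphas, eps = 1e-7) {
  if (length(side_probs) != length(alphas))
    stop("number of side predictions must match number of alphas")
  sum(vapply(seq_along(alphas), function(i)
    alphas[i] * hybrid_loss(target, side_probs[[i]], eps = eps),
    numeric(1)))
}

#' Total segmentation loss
#'
#' Default: `L = L_TP + L_side` (final-output hybrid loss plus the
#' weighted side loss). With `literal_eq6 = TRUE` the printed d-fold
#' summation `sum_{i=1..d} (L_TP + L_side) = d (L_TP + L_side)` is
#' reproduced; neither term depends on the summation index, so this
#' rescales the loss without changing its minimizers.
#'
#' @param l_tp Final-output hybrid loss.
#' @param l_side Side loss.
#' @param depth Network depth `d` (used only by the literal form).
#' @param literal_eq6 Reproduce the printed summation.
#' @return Scalar total loss.
#' @export
total_seg_loss <- function(l_tp, l_side, depth = 4, literal_eq6 = FALSE) {
  if (literal_eq6) depth * (l_tp + l_side) else l_tp + l_side
}

# ---- model ----------------------------------------------------------------

#' Initialize a segmentation model
#'
#' He-initialized convolution blocks for every grid node, the bottleneck
#' attention scalar (at 0), and 1x1 side heads on the full-resolution row.
#'
#' @param config A [cmunet_config()].
#' @return A `cmunet_model` (untrained).
#' @export
cmunet_init <- function(config = cmunet_config()) {
  d <- config$depth
  topo <- cmunet_topology(d)
  withr::with_seed(config$seed, {
    nodes <- list()
    for (r in seq_len(nrow(topo))) {
      i <- topo$i[r]; j <- topo$j[r]
      wi <- config$widths[i + 1]
      cin <- if (j == 0) {
        if (i == 0) config$in_channels else config$widths[i]
      } else {
        j * wi + config$widths[i + 2]
      }
      convs <- list()
      for (t in seq_len(config$block_convs)) {
        convs[[paste0("c", t)]] <-
          nn_conv_init(3, if (t == 1) cin else wi, wi)
      }
      nodes[[paste0(i, "_", j)]] <- convs
    }
    heads <- list()
    head_js <- if (isTRUE(config$mss$enabled)) seq_len(d) else d
    for (j in head_js)
      heads[[paste0("h", j)]] <-
        nn_conv_init(1, config$widths[1], config$n_classes)
    params <- list(nodes = nodes, heads = heads,
                   ca = list(beta = 0))
    structure(list(params = params, config = config, history = NULL),
              class = "cmunet_model")
  })
}

.block_fwd <- function(x, bp) {
  cache <- list()
  a <- x
  for (t in seq_along(bp)) {
    z <- nn_conv_fwd(a, bp[[t]])
    cache[[t]] <- list(x = a, z = z)
    a <- nn_relu(z)
  }
  list(y = a, cache = cache)
}

.block_bwd <- function(bp, cache, dy) {
  grads <- vector("list", length(bp))
  names(grads) <- names(bp)
  for (t in rev(seq_along(bp))) {
    dz <- nn_relu_bwd(dy, cache[[t]]$z)
    bw <- nn_conv_bwd(cache[[t]]$x, bp[[t]], dz)
    grads[[t]] <- list(w = bw$dw, b = bw$db)
    dy <- bw$dx
  }
  list(dx = dy, grads = grads)
}

.grid_fwd <- function(params, cfg, x) {
  d <- cfg$depth
  nodes <- list(); pools <- list(); concat <- list(); blocks <- list()
  ca_cache <- NULL
  for (j in 0:d) for (i in 0:(d - j)) {
    key <- paste0(i, "_", j)
    if (j == 0) {
      if (i == 0) inp <- x else {
        pl <- nn_pool_fwd(nodes[[paste0(i - 1, "_0")]])
        pools[[key]] <- pl
        inp <- pl$y
      }
    } else {
      up <- nn_up_fwd(nodes[[paste0(i + 1, "_", j - 1)]])
      parts <- c(lapply(0:(j - 1), function(jj)
        nodes[[paste0(i, "_", jj)]]), list(up))
      concat[[key]] <- vapply(parts, function(a) dim(a)[3], numeric(1))
      inp <- nn_concat(parts)
    }
    bl <- .block_fwd(inp, params$nodes[[key]])
    blocks[[key]] <- bl$cache
    act <- bl$y
    if (i == d && j == 0 && isTRUE(cfg$ca$enabled)) {
      if (isTRUE(cfg$ca$literal_eq2))
        stop("the literal affinity variant supports inference only; ",
             "disable ca$literal_eq2 for training/forward passes")
      caf <- .ca_fwd_batch(act, params$ca$beta)
      ca_cache <- caf$cache
      act <- caf$y
    }
    nodes[[key]] <- act
  }
  list(nodes = nodes, pools = pools, concat = concat, blocks = blocks,
       ca = ca_cache)
}

.grid_bwd <- function(params, cfg, fw, g) {
  d <- cfg$depth
  node_grads <- list()
  dbeta <- 0
  add_g <- function(key, arr) {
    g[[key]] <<- if (is.null(g[[key]])) arr else g[[key]] + arr
  }
  # reverse topological order: later columns first; within column 0 the
  # pooled consumers (deeper rows) must precede their producers
  order <- cmunet_topology(d)
  order <- order[order(-order$j, -order$i), ]
  for (r in seq_len(nrow(order))) {
    i <- order$i[r]; j <- order$j[r]
    key <- paste0(i, "_", j)
    dy <- g[[key]]
    if (is.null(dy)) dy <- fw$nodes[[key]] * 0
    if (i == d && j == 0 && isTRUE(cfg$ca$enabled)) {
      cb <- .ca_bwd_batch(fw$ca, dy, params$ca$beta)
      dy <- cb$dx
      dbeta <- dbeta + cb$dbeta
    }
    bb <- .block_bwd(params$nodes[[key]], fw$blocks[[key]], dy)
    node_grads[[key]] <- bb$grads
    dinp <- bb$dx
    if (j == 0) {
      if (i > 0) add_g(paste0(i - 1, "_0"), nn_pool_bwd(fw$pools[[key]], dinp))
    } else {
      pieces <- nn_split(dinp, fw$concat[[key]])
      for (jj in 0:(j - 1)) add_g(paste0(i, "_", jj), pieces[[jj + 1]])
      add_g(paste0(i + 1, "_", j - 1), nn_up_bwd(pieces[[j + 1]]))
    }
  }
  list(node_grads = node_grads, dbeta = dbeta)
}

# Forward pass returning per-level probability maps (full resolution).
# x: (H,W,Cin,N) array, values in [0,1].
cmunet_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  fw <- .grid_fwd(model$params, cfg, x)
  head_js <- as.integer(sub("h", "", names(model$params$heads)))
  logits <- lapply(seq_along(head_js), function(t)
    nn_conv_fwd(fw$nodes[[paste0("0_", head_js[t])]],
                model$params$heads[[t]]))
  probs <- lapply(logits, nn_channel_softmax)
  names(probs) <- names(logits) <- paste0("h", head_js)
  out <- list(probs = probs, logits = logits, head_js = head_js)
  if (keep_cache) out$fw <- fw
  out
}

# One training step: forward, losses, full backward, gradient structure.
.cmunet_step <- function(model, x, t_onehot) {
  cfg <- model$config
  out <- cmunet_forward(model, x, keep_cache = TRUE)
  d <- cfg$depth
  final_key <- paste0("h", d)
  l_tp <- hybrid_loss(t_onehot, out$probs[[final_key]], eps = cfg$loss$eps)
  alphas <- if (isTRUE(cfg$mss$enabled)) cfg$mss$alphas else numeric(0)
  l_side <- if (length(alphas))
    side_loss(out$probs[paste0("h", seq_len(d))], t_onehot, alphas,
              eps = cfg$loss$eps) else 0
  scale <- if (isTRUE(cfg$loss$literal_eq6)) d else 1
  total <- total_seg_loss(l_tp, l_side, d, cfg$loss$literal_eq6)
  # per-level weights on the hybrid-loss gradient
  g <- list()
  head_grads <- list()
  for (idx in seq_along(out$head_js)) {
    j <- out$head_js[idx]
    w <- (if (j == d) 1 else 0) +
      (if (length(alphas)) alphas[j] else 0)
    if (w == 0) {
      head_grads[[idx]] <- list(w = model$params$heads[[idx]]$w * 0,
                                b = model$params$heads[[idx]]$b * 0)
      next
    }
    dp <- scale * w * .hybrid_loss_grad(t_onehot, out$probs[[idx]],
                                        eps = cfg$loss$eps)
    dz <- nn_channel_softmax_bwd(out$probs[[idx]], dp)
    hb <- nn_conv_bwd(out$fw$nodes[[paste0("0_", j)]],
                      model$params$heads[[idx]], dz)
    head_grads[[idx]] <- list(w = hb$dw, b = hb$db)
    key <- paste0("0_", j)
    g[[key]] <- if (is.null(g[[key]])) hb$dx else g[[key]] + hb$dx
  }
  names(head_grads) <- names(model$params$heads)
  gb <- .grid_bwd(model$params, cfg, out$fw, g)
  grads <- list(nodes = gb$node_grads, heads = head_grads,
                ca = list(beta = gb$dbeta))
  list(loss = total, l_tp = l_tp, l_side = l_side, grads = grads)
}

.to_batch <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d, length(lst)))
  for (n in seq_along(lst)) out[, , , n] <- lst[[n]]
  out
}

.mask_onehot <- function(masks) {
  d <- dim(masks[[1]])
  out <- array(0, c(d[1], d[2], 2, length(masks)))
  for (n in seq_along(masks)) {
    out[, , 1, n] <- 1 - masks[[n]]
    out[, , 2, n] <- masks[[n]]
  }
  out
}

.rand_augment <- function(img, mask) {
  op <- sample(c("none", "vflip", "hflip", "rot90", "rot180", "rot270",
                 "gray"), 1)
  if (op == "none") return(list(tile = img, mask = mask))
  if (op == "gray") return(list(tile = augment(img, "gray"), mask = mask))
  augment(img, op, mask = mask)
}

#' Train the segmentation network
#'
#' Adam optimization of the total loss (final-output hybrid loss plus
#' weighted side losses) on image/mask pairs, with optional on-the-fly
#' flip/rotation/gray augmentation. Fully reproducible given
#' `config$seed`.
#'
#' @param images List of H x W x 3 arrays (0--255), H and W divisible by
#'   `2^depth`.
#' @param masks List of binary H x W matrices.
#' @param config A [cmunet_config()].
#' @param val_images,val_masks Optional held-out pairs; validation Dice is
#'   recorded per epoch (and drives `early_stop_dice`).
#' @param verbose Print per-epoch progress.
#' @return A trained `cmunet_model` with a `history` data frame
#'   (epoch, loss, l_tp, l_side, val_dice).
#' @export
train_segmenter <- function(images, masks, config = cmunet_config(),
                            val_images = NULL, val_masks = NULL,
                            verbose = FALSE) {
  if (length(images) == 0) stop("empty training manifest")
  stopifnot(length(images) == length(masks))
  model <- cmunet_init(config)
  state <- adam_init(model$params)
  hist <- list()
  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(images))
      ep_loss <- ep_tp <- ep_side <- 0; nb <- 0
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        sel <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        xs <- vector("list", length(sel)); ms <- xs
        for (s in seq_along(sel)) {
          img <- images[[sel[s]]]; msk <- masks[[sel[s]]]
          if (isTRUE(config$augment)) {
            au <- .rand_augment(img, msk)
            img <- au$tile; msk <- au$mask
          }
          xs[[s]] <- img / 255; ms[[s]] <- msk
        }
        st <- .cmunet_step(model, .to_batch(xs), .mask_onehot(ms))
        up <- adam_step(model$params, st$grads, state, lr = config$lr)
        model$params <- up$params; state <- up$state
        ep_loss <- ep_loss + st$loss; ep_tp <- ep_tp + st$l_tp
        ep_side <- ep_side + st$l_side; nb <- nb + 1
      }
      vd <- NA_real_
      if (!is.null(val_images)) {
        vd <- mean(vapply(seq_along(val_images), function(v)
          dice(val_masks[[v]],
               segment(model, val_images[[v]], config$threshold)),
          numeric(1)))
      }
      hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / nb,
                               l_tp = ep_tp / nb, l_side = ep_side / nb,
                               val_dice = vd)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val_dice %.4f",
                        ep, ep_loss / nb, vd))
      if (!is.null(config$early_stop_dice) && !is.na(vd) &&
          vd >= config$early_stop_dice) break
    }
  })
  model$history <- do.call(rbind, hist)
  model
}

#' Segment a tile into a binary clump mask
#'
#' Runs the network and thresholds the foreground probability. Inputs
#' whose sides are not divisible by `2^depth` are reflect-padded and the
#' output cropped back.
#'
#' @param model A trained `cmunet_model`.
#' @param tile H x W x 3 array (0--255) or `image_tile`.
#' @param threshold Foreground probability threshold in `[0, 1]`; 0 maps
#'   everything to foreground, 1 everything to background.
#' @param prob Return the probability map instead of the binary mask.
#' @return Binary integer H x W matrix (or probability matrix).
#' @export
segment <- function(model, tile, threshold = model$config$threshold,
                    prob = FALSE) {
  px <- if (inherits(tile, "image_tile")) tile$pixels else tile
  if (length(dim(px)) == 2) px <- array(px, c(dim(px), 1))
  H <- dim(px)[1]; W <- dim(px)[2]
  mod <- 2^model$config$depth
  Hp <- ceiling(H / mod) * mod; Wp <- ceiling(W / mod) * mod
  xp <- array(0, c(Hp, Wp, dim(px)[3]))
  ridx <- c(seq_len(H), rev(seq_len(H)))[seq_len(Hp)]
  cidx <- c(seq_len(W), rev(seq_len(W)))[seq_len(Wp)]
  xp[] <- (px / 255)[ridx, cidx, ]
  x <- array(xp, c(Hp, Wp, dim(px)[3], 1))
  out <- cmunet_forward(model, x)
  pfg <- out$probs[[paste0("h", model$config$depth)]][, , 2, 1]
  pfg <- pfg[seq_len(H), seq_len(W), drop = FALSE]
  if (prob) return(pfg)
  if (threshold <= 0) return(matrix(1L, H, W))
  if (threshold >= 1) return(matrix(0L, H, W))
  matrix(as.integer(pfg > threshold), H, W)
}
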