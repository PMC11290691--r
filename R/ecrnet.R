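# Contrastive ROI classifier ("ECRNet"-style): a convolutional query
# encoder with a softmax classifier head and an L2-normalized projection
# head, a gradient-free momentum key encoder, and a FIFO labeled memory
# bank backing a label-supervised contrastive loss. Keys with the query's
# label are positives regardless of staining style, so representations of
# the same class are pulled together across palettes.

#' Configuration of the contrastive classifier
#'
#' @param input_size Side length the encoder sees; ROI canvases are
#'   resized to this before encoding.
#' @param encoder `"compact"` (three conv/pool stages, desk-scale) or
#'   `"vgg16"` (the 16-layer configuration); `stages` overrides both.
#' @param stages List of per-stage convolution widths, each stage followed
#'   by 2x2 max pooling.
#' @param embed_dim Dimension D of the L2-normalized projection
#'   embeddings.
#' @param n_classes Number of classes.
#' @param tau Contrastive temperature (default 0.07).
#' @param momentum Momentum coefficient m of the key encoder (default
#'   0.9).
#' @param beta_loss Weight of the contrastive term in the total loss
#'   (default 0.5).
#' @param bank_capacity FIFO memory-bank capacity (default 4096).
#' @param canvas Expected ROI canvas side (default 512); other sizes are
#'   resized with a warning.
#' @param lr,batch_size,epochs Adam learning rate (default 5e-3), batch
#'   size (default 32), epoch budget.
#' @param augment Random flip/rotation/gray augmentation during training.
#' @param seed RNG seed.
#' @return An `ecrnet_config` list.
#' @export
ecrnet_config <- function(input_size = 64, encoder = "compact",
                          stages = NULL, embed_dim = 128, n_classes = 2,
                          tau = 0.07, momentum = 0.9, beta_loss = 0.5,
                          bank_capacity = 4096, canvas = 512,
                          lr = 5e-3, batch_size = 32, epochs = 15,
                          augment = TRUE, seed = 1L) {
  stopifnot(tau > 0, momentum >= 0, momentum < 1, beta_loss >= 0,
            bank_capacity >= 1, input_size >= 8, lr > 0)
  if (is.null(stages))
    stages <- switch(match.arg(encoder, c("compact", "vgg16")),
      compact = list(8, 16, 32),
      vgg16 = list(c(64, 64), c(128, 128), c(256, 256, 256),
                   c(512, 512, 512), c(512, 512, 512)))
  if (input_size %% 2^length(stages) != 0)
    stop("input_size must be divisible by 2^number of stages")
  structure(list(input_size = as.integer(input_size), stages = stages,
                 embed_dim = as.integer(embed_dim),
                 n_classes = as.integer(n_classes), tau = tau,
                 momentum = momentum, beta_loss = beta_loss,
                 bank_capacity = as.integer(bank_capacity),
                 canvas = as.integer(canvas), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "ecrnet_config")
}

# ---- memory bank ----------------------------------------------------------

#' Create an empty labeled memory bank
#'
#' A fixed-capacity FIFO of (embedding, label) pairs; enqueueing past the
#' capacity evicts the oldest entries, and labels stay aligned with their
#' embeddings.
#'
#' @param capacity Maximum number of keys held.
#' @return A `memory_bank` object.
#' @export
memory_bank <- function(capacity = 4096) {
  stopifnot(capacity >= 1)
  structure(list(capacity = as.integer(capacity),
                 embeddings = NULL, labels = character(0)),
            class = "memory_bank")
}

#' Append labeled keys to a memory bank
#'
#' @param bank A [memory_bank()].
#' @param embeddings Matrix (n x D) of key embeddings; rows are expected
#'   unit-norm and are renormalized with a warning otherwise.
#' @param labels Character vector of length n.
#' @return The updated bank (FIFO semantics).
#' @export
enqueue <- function(bank, embeddings, labels) {
  stopifnot(inherits(bank, "memory_bank"))
  if (is.null(embeddings) || NROW(embeddings) == 0) return(bank)
  embeddings <- rbind(embeddings)
  stopifnot(nrow(embeddings) == length(labels))
  rn <- sqrt(rowSums(embeddings^2))
  if (any(abs(rn - 1) > 1e-6)) {
    warning("non-normalized keys enqueued; renormalizing")
    embeddings <- embeddings / rn
  }
  emb <- rbind(bank$embeddings, embeddings)
  lab <- c(bank$labels, as.character(labels))
  if (nrow(emb) > bank$capacity) {
    keep <- (nrow(emb) - bank$capacity + 1):nrow(emb)
    emb <- emb[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  bank$embeddings <- emb
  bank$labels <- lab
  bank
}

#' @export
length.memory_bank <- function(x) length(x$labels)

# ---- losses and updates ---------------------------------------------------

#' Momentum update of the key-encoder parameters
#'
#' `theta_k <- m * theta_k + (1 - m) * theta_q`, applied elementwise to
#' numeric vectors/arrays or recursively over nested parameter lists. The
#' query parameters are never modified; repeated updates under a fixed
#' `theta_q` converge to it geometrically at rate `m`.
#'
#' @param theta_k Key parameters (numeric or nested list).
#' @param theta_q Query parameters of identical structure.
#' @param m Momentum coefficient in `[0, 1)`.
#' @return Updated key parameters.
#' @export
momentum_update <- function(theta_k, theta_q, m) {
  stopifnot(m >= 0, m < 1)
  if (is.list(theta_k)) {
    stopifnot(is.list(theta_q), length(theta_k) == length(theta_q))
    for (i in seq_along(theta_k))
      theta_k[[i]] <- momentum_update(theta_k[[i]], theta_q[[i]], m)
    return(theta_k)
  }
  if (!is.numeric(theta_k)) return(theta_k)
  if (length(theta_k) != length(theta_q)) stop("parameter shape mismatch")
  m * theta_k + (1 - m) * theta_q
}

.logsumexp <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }

#' Label-supervised contrastive loss against a memory bank
#'
#' `-log [ sum_{i: y_i = y} exp(sim(q, k_i)/tau) / sum_i exp(sim(q,
#' k_i)/tau) ]` with cosine similarity (dot product of unit-norm
#' embeddings). Nonnegative; exactly 0 when every key shares the query's
#' label, and `-log(n_pos/n)` whenever all similarities are equal.
#'
#' @param q Query embedding (unit-norm numeric vector).
#' @param y Query label.
#' @param bank A non-empty [memory_bank()].
#' @param tau Temperature.
#' @return Scalar loss. If the bank holds no key with label `y`, a
#'   condition of class `cytoscreen_no_positive` is signalled (callers
#'   treat it as a skip-sample signal, not infinity).
#' @export
label_contrastive_loss <- function(q, y, bank, tau = 0.07) {
  stopifnot(inherits(bank, "memory_bank"))
  if (length(bank) == 0) stop("memory bank is empty")
  pos <- bank$labels == y
  if (!any(pos))
    stop(structure(class = c("cytoscreen_no_positive", "error", "condition"),
                   list(message = paste0("no key with label '", y,
                                         "' in the bank"),
                        call = sys.call())))
  l <- as.vector(bank$embeddings %*% q) / tau
  .logsumexp(l) - .logsumexp(l[pos])
}

# Gradient of the contrastive loss with respect to q.
.contrastive_grad <- function(q, y, bank, tau) {
  l <- as.vector(bank$embeddings %*% q) / tau
  p_all <- exp(l - .logsumexp(l))
  pos <- bank$labels == y
  p_pos <- numeric(length(l))
  p_pos[pos] <- exp(l[pos] - .logsumexp(l[pos]))
  as.vector(crossprod(bank$embeddings, p_all - p_pos)) / tau
}

#' Cross-entropy classifier loss
#'
#' `-(1/|Q|) sum_i log p_i[true class]`, with the true-class probability
#' clamped away from zero.
#'
#' @param probs Matrix (n x C) of class probabilities with class names as
#'   column names.
#' @param labels Character vector of true labels.
#' @return Scalar loss (0 for perfect one-hot predictions).
#' @export
classifier_loss <- function(probs, labels) {
  probs <- rbind(probs)
  stopifnot(nrow(probs) == length(labels),
            all(labels %in% colnames(probs)))
  pt <- probs[cbind(seq_len(nrow(probs)),
                    match(labels, colnames(probs)))]
  -mean(log(.clamp(pt)))
}

#' Combined classifier objective
#'
#' `L_total = L_cla + beta_loss * L_con`.
#'
#' @param l_cla Cross-entropy loss.
#' @param l_con Contrastive loss.
#' @param beta_loss Contrastive weight (default 0.5).
#' @return Scalar.
#' @export
total_cls_loss <- function(l_cla, l_con, beta_loss = 0.5) {
  l_cla + beta_loss * l_con
}

# ---- encoder --------------------------------------------------------------

.ecr_init_params <- function(cfg) {
  stages <- list()
  cin <- 3
  for (s in seq_along(cfg$stages)) {
    convs <- list()
    for (t in seq_along(cfg$stages[[s]])) {
      cout <- cfg$stages[[s]][t]
      convs[[paste0("c", t)]] <- nn_conv_init(3, cin, cout)
      cin <- cout
    }
    stages[[paste0("s", s)]] <- convs
  }
  list(stages = stages,
       cls = list(w = matrix(rnorm(cin * cfg$n_classes, sd = sqrt(2 / cin)),
                             cin, cfg$n_classes),
                  b = numeric(cfg$n_classes)),
       proj = list(w = matrix(rnorm(cin * cfg$embed_dim, sd = sqrt(2 / cin)),
                              cin, cfg$embed_dim),
                   b = numeric(cfg$embed_dim)))
}

# Forward pass of the encoder; x is (H,W,3,N) in [0,1].
.ecr_fwd <- function(params, x, keep_cache = FALSE) {
  cache <- list()
  a <- x
  for (s in seq_along(params$stages)) {
    bl <- .block_fwd(a, params$stages[[s]])
    pl <- nn_pool_fwd(bl$y)
    if (keep_cache) cache[[s]] <- list(block = bl$cache, pool = pl)
    a <- pl$y
  }
  d <- dim(a)
  f <- t(apply(a, c(3, 4), mean))          # N x C global average pool
  logits <- sweep(f %*% params$cls$w, 2, params$cls$b, "+")
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)
  z <- sweep(f %*% params$proj$w, 2, params$proj$b, "+")
  zn <- sqrt(rowSums(z^2))
  q <- z / pmax(zn, 1e-12)
  out <- list(f = f, probs = probs, q = q, z = z, zn = zn, feat_dim = d)
  if (keep_cache) out$cache <- cache
  out
}

# Backward from dlogits (N x C) and dq (N x D) to parameter gradients.
.ecr_bwd <- function(params, fw, dlogits, dq) {
  f <- fw$f
  dWc <- crossprod(f, dlogits); dbc <- colSums(dlogits)
  df <- dlogits %*% t(params$cls$w)
  if (!is.null(dq)) {
    # through L2 normalization: dz = (dq - q * <dq, q>) / ||z||
    s <- rowSums(dq * fw$q)
    dz <- (dq - fw$q * s) / pmax(fw$zn, 1e-12)
    dWp <- crossprod(f, dz); dbp <- colSums(dz)
    df <- df + dz %*% t(params$proj$w)
  } else {
    dWp <- params$proj$w * 0; dbp <- params$proj$b * 0
  }
  d <- fw$feat_dim
  # GAP backward: spread df uniformly over the final feature raster
  da <- aperm(array(t(df) / (d[1] * d[2]), c(d[3], d[4], d[1], d[2])),
              c(3, 4, 1, 2))
  stage_grads <- vector("list", length(params$stages))
  names(stage_grads) <- names(params$stages)
  for (s in rev(seq_along(params$stages))) {
    da <- nn_pool_bwd(fw$cache[[s]]$pool, da)
    bb <- .block_bwd(params$stages[[s]], fw$cache[[s]]$block, da)
    stage_grads[[s]] <- bb$grads
    da <- bb$dx
  }
  list(stages = stage_grads,
       cls = list(w = dWc, b = dbc),
       proj = list(w = dWp, b = dbp))
}

.prep_roi <- function(roi, size) {
  px <- if (inherits(roi, "cell_clump_roi")) roi$canvas else roi
  if (length(dim(px)) == 2) px <- array(px, c(dim(px), 3))
  if (dim(px)[1] != size || dim(px)[2] != size) {
    out <- array(0, c(size, size, 3))
    for (ch in 1:3)
      out[, , ch] <- EBImage::resize(EBImage::Image(px[, , ch]),
                                     w = size, h = size)@.Data
    px <- out
  }
  px / 255
}

#' Train the contrastive classifier
#'
#' Each step encodes the batch with the query network (classifier
#' probabilities and normalized embeddings), encodes the same images with
#' the gradient-free momentum network, evaluates cross-entropy plus the
#' `beta_loss`-weighted contrastive loss against the memory bank, updates
#' the query network by Adam and the key network by the momentum rule,
#' then enqueues the keys. The contrastive term stays off until the bank
#' holds at least one key of every class.
#'
#' @param rois List of ROI canvases (H x W x 3 arrays, 0--255) or
#'   `cell_clump_roi` objects.
#' @param labels Character labels, one per ROI; at least two classes.
#' @param config An [ecrnet_config()].
#' @param val_rois,val_labels Optional held-out set; accuracy recorded per
#'   epoch.
#' @param verbose Print per-epoch progress.
#' @return An `ecrnet_model`: query and key parameters, the memory bank,
#'   class levels and a training history.
#' @export
train_classifier <- function(rois, labels, config = ecrnet_config(),
                             val_rois = NULL, val_labels = NULL,
                             verbose = FALSE) {
  if (length(rois) == 0) stop("empty ROI manifest")
  labels <- as.character(labels)
  stopifnot(length(rois) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("training data contains a single class; the contrastive loss ",
         "needs at least two")
  xs <- lapply(rois, .prep_roi, size = config$input_size)
  model <- NULL
  withr::with_seed(config$seed, {
    params <- .ecr_init_params(config)
    key_params <- params
    state <- adam_init(params)
    bank <- memory_bank(config$bank_capacity)
    hist <- list()
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(xs))
      ep_cla <- ep_con <- 0; nb <- 0
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        sel <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        xb <- xs[sel]
        if (isTRUE(config$augment))
          xb <- lapply(xb, function(a) {
            op <- sample(c("none", "vflip", "hflip", "rot90", "rot180",
                           "rot270", "gray"), 1)
            if (op == "none") a else augment(a, op)
          })
        x <- .to_batch(xb)
        lab <- labels[sel]
        fw <- .ecr_fwd(params, x, keep_cache = TRUE)
        colnames(fw$probs) <- classes
        l_cla <- classifier_loss(fw$probs, lab)
        onehot <- outer(lab, classes, "==") * 1
        dlogits <- (fw$probs - onehot) / length(sel)
        # keys from the momentum encoder, gradient-free
        kfw <- .ecr_fwd(key_params, x)
        dq <- NULL; l_con <- 0
        if (all(classes %in% bank$labels)) {
          dq <- fw$q * 0
          used <- 0
          for (s in seq_along(sel)) {
            if (!any(bank$labels == lab[s])) next
            l_con <- l_con +
              label_contrastive_loss(fw$q[s, ], lab[s], bank, config$tau)
            dq[s, ] <- .contrastive_grad(fw$q[s, ], lab[s], bank,
                                         config$tau)
            used <- used + 1
          }
          if (used > 0) {
            l_con <- l_con / used
            dq <- dq * (config$beta_loss / used)
          } else dq <- NULL
        }
        grads <- .ecr_bwd(params, fw, dlogits, dq)
        up <- adam_step(params, grads, state, lr = config$lr)
        params <- up$params; state <- up$state
        key_params <- momentum_update(key_params, params, config$momentum)
        bank <- enqueue(bank, kfw$q, lab)
        ep_cla <- ep_cla + l_cla; ep_con <- ep_con + l_con; nb <- nb + 1
      }
      acc <- NA_real_
      if (!is.null(val_rois)) {
        m <- list(params = params, config = config, classes = classes)
        class(m) <- "ecrnet_model"
        pr <- .classify_batch(m, val_rois)
        acc <- mean(pr$label == as.character(val_labels))
      }
      hist[[ep]] <- data.frame(epoch = ep, l_cla = ep_cla / nb,
                               l_con = ep_con / nb,
                               total = total_cls_loss(ep_cla / nb,
                                                      ep_con / nb,
                                                      config$beta_loss),
                               bank_size = length(bank), val_acc = acc)
      if (verbose)
        message(sprintf("epoch %d: cla %.4f con %.4f acc %.4f",
                        ep, ep_cla / nb, ep_con / nb, acc))
    }
    model <- structure(list(params = params, key_params = key_params,
                            bank = bank, config = config,
                            classes = classes,
                            history = do.call(rbind, hist)),
                       class = "ecrnet_model")
  })
  model
}

.classify_batch <- function(model, rois) {
  xs <- lapply(rois, .prep_roi, size = model$config$input_size)
  probs <- matrix(0, length(xs), length(model$classes))
  bs <- 64
  for (b0 in seq(1, length(xs), by = bs)) {
    sel <- b0:min(b0 + bs - 1, length(xs))
    fw <- .ecr_fwd(model$params, .to_batch(xs[sel]))
    probs[sel, ] <- fw$probs
  }
  colnames(probs) <- model$classes
  # argmax with ties broken toward the malignant class: screening favors
  # sensitivity over specificity
  lab <- apply(probs, 1, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1 && "malignant" %in% model$classes[top])
      "malignant" else model$classes[top[1]]
  })
  list(probs = probs, label = lab)
}

#' Classify one ROI
#'
#' @param model A trained `ecrnet_model`.
#' @param roi A `cell_clump_roi` or H x W x 3 array (0--255). Canvases of
#'   unexpected size are resized with a warning.
#' @return List with `probabilities` (named, summing to 1) and `label`
#'   (ties broken toward `"malignant"`).
#' @export
classify <- function(model, roi) {
  px <- if (inherits(roi, "cell_clump_roi")) roi$canvas else roi
  if (dim(px)[1] != model$config$canvas ||
      dim(px)[2] != model$config$canvas)
    warning("ROI canvas is ", dim(px)[1], "x", dim(px)[2],
            ", expected ", model$config$canvas, "; resizing")
  out <- .classify_batch(model, list(px))
  list(probabilities = setNames(as.vector(out$probs), model$classes),
       label = out$label[1])
}
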