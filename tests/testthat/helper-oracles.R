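# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations: plain-R scalar loops and a BFS flood
# fill, so agreement is a genuine cross-check.

# Connected-component count by BFS flood fill.
oracle_component_count <- function(mask, eight = TRUE) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  nb <- if (eight)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  count <- 0
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1
    queue <- matrix(c(i, j), 1)
    seen[i, j] <- TRUE
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (t in seq_len(nrow(nb))) {
        ni <- cur[1] + nb[t, 1]; nj <- cur[2] + nb[t, 2]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  count
}

# Scalar-loop hybrid segmentation loss (cross-entropy + per-pixel overlap).
oracle_hybrid_loss <- function(t, p, eps = 1e-7, n_classes = 1) {
  acc <- 0
  for (i in seq_along(t)) {
    pc <- min(max(p[i], 1e-7), 1 - 1e-7)
    acc <- acc + t[i] * log(pc) + 2 * t[i] * p[i] / (t[i]^2 + p[i]^2 + eps)
  }
  -acc / (length(t) / n_classes)
}

# Scalar-loop label-contrastive loss against explicit keys.
oracle_contrastive <- function(q, y, keys, key_labels, tau) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(keys))) {
    e <- exp(sum(q * keys[i, ]) / tau)
    den <- den + e
    if (key_labels[i] == y) num <- num + e
  }
  -log(num / den)
}

# Scalar-loop cross-entropy over a probability matrix.
oracle_cross_entropy <- function(probs, labels, classes) {
  acc <- 0
  for (i in seq_len(nrow(probs))) {
    for (j in seq_along(classes)) {
      if (labels[i] == classes[j])
        acc <- acc + log(min(max(probs[i, j], 1e-7), 1 - 1e-7))
    }
  }
  -acc / nrow(probs)
}

# Dense-loop channel attention (affinity softmax + residual mix).
oracle_channel_attention <- function(Xk, beta) {
  K <- nrow(Xk); P <- ncol(Xk)
  E <- matrix(0, K, P)
  M <- matrix(0, K, K)
  for (b in seq_len(K)) {
    s <- numeric(K)
    for (a in seq_len(K)) s[a] <- sum(Xk[a, ] * Xk[b, ])
    e <- exp(s - max(s))
    M[b, ] <- e / sum(e)
  }
  for (b in seq_len(K)) {
    mix <- numeric(P)
    for (a in seq_len(K)) mix <- mix + M[b, a] * Xk[a, ]
    E[b, ] <- beta * mix + Xk[b, ]
  }
  list(E = E, M = M)
}

# Normalized Mann-Whitney U statistic (rank-based AUC oracle).
oracle_auc_rank <- function(scores, labels) {
  r <- rank(scores)
  np <- sum(labels); nn <- sum(!labels)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# Small random binary mask with at least one foreground pixel.
random_mask <- function(h = 16, w = 16, p = 0.3) {
  m <- matrix(rbinom(h * w, 1, p), h, w)
  if (sum(m) == 0) m[sample(h * w, 1)] <- 1
  m
}

# Tiny tile spec shared by pipeline tests.
small_spec <- function(...) synth_spec(tile_size = 128, n_clumps = c(1, 4), ...)
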