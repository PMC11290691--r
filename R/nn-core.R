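# Minimal CPU neural-network core shared by the segmentation and
# classification networks: same-padding convolutions (im2col + GEMM in
# compiled code), ReLU, 2x2 max pooling, nearest-neighbour x2 upsampling,
# channel softmax and an Adam optimizer over nested parameter lists.
#
# Array convention: activations are numeric arrays dim (H, W, C, N);
# weights of a k x k convolution are stored as a (k*k*Cin) x Cout matrix
# whose row order matches an R array dim (k, k, Cin) flattened column-major.

nn_conv_init <- function(k, cin, cout) {
  list(w = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout), k = k)
}

nn_conv_fwd <- function(x, p) .conv2d_fwd(x, p$w, p$b, p$k)

nn_conv_bwd <- function(x, p, dy) .conv2d_bwd(x, p$w, dy, p$k)

nn_relu <- function(y) { y[y < 0] <- 0; y }

nn_relu_bwd <- function(dy, y_pre) { dy[y_pre <= 0] <- 0; dy }

nn_pool_fwd <- function(x) {
  out <- .maxpool2_fwd(x)
  out$xdim <- dim(x)
  out
}

nn_pool_bwd <- function(cache, dy) .maxpool2_bwd(cache$idx, dy, cache$xdim)

nn_up_fwd <- function(x) .upsample2_fwd(x)

nn_up_bwd <- function(dy) .upsample2_bwd(dy)

# Concatenate (H,W,C,N) arrays along the channel axis.
nn_concat <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(a) dim(a)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  ofs <- 0
  for (a in xs) {
    out[, , ofs + seq_len(dim(a)[3]), ] <- a
    ofs <- ofs + dim(a)[3]
  }
  out
}

# Split a channel-axis gradient back into the concatenated pieces.
nn_split <- function(dy, sizes) {
  ofs <- 0
  lapply(sizes, function(cz) {
    sl <- dy[, , ofs + seq_len(cz), , drop = FALSE]
    ofs <<- ofs + cz
    sl
  })
}

# Softmax over the channel (3rd) axis of an (H,W,C,N) array (vectorized;
# channel loop only, so cheap for the small class counts used here).
nn_channel_softmax <- function(z) {
  C <- dim(z)[3]
  m <- z[, , 1, , drop = FALSE]
  if (C > 1) for (cc in 2:C) m <- pmax(m, z[, , cc, , drop = FALSE])
  e <- exp(z - m[, , rep(1, C), , drop = FALSE])
  s <- e[, , 1, , drop = FALSE]
  if (C > 1) for (cc in 2:C) s <- s + e[, , cc, , drop = FALSE]
  e / s[, , rep(1, C), , drop = FALSE]
}

# Jacobian-vector product of the channel softmax: given probabilities p and
# dL/dp, return dL/dlogits.
nn_channel_softmax_bwd <- function(p, dp) {
  C <- dim(p)[3]
  pd <- p * dp
  s <- pd[, , 1, , drop = FALSE]
  if (C > 1) for (cc in 2:C) s <- s + pd[, , cc, , drop = FALSE]
  p * (dp - s[, , rep(1, C), , drop = FALSE])
}

# ---- Adam over nested parameter lists -------------------------------------

.walk_grads <- function(params, grads, m, v, f) {
  for (i in seq_along(params)) {
    nm <- if (is.null(names(params))) "" else names(params)[i]
    el <- params[[i]]
    # gradient containers may order their elements differently; match by
    # name whenever both sides are named
    gi <- if (nzchar(nm) && !is.null(names(grads))) grads[[nm]] else grads[[i]]
    if (is.list(el)) {
      if (is.null(gi)) next
      res <- .walk_grads(el, gi, m[[i]], v[[i]], f)
      params[[i]] <- res$p; m[[i]] <- res$m; v[[i]] <- res$v
    } else if (is.numeric(el) && nm %in% c("w", "b", "beta") &&
               !is.null(gi)) {
      res <- f(el, gi, m[[i]], v[[i]])
      params[[i]] <- res$p; m[[i]] <- res$m; v[[i]] <- res$v
    }
  }
  list(p = params, m = m, v = v)
}

.zeros_like <- function(params) {
  rapply(params, function(x) if (is.numeric(x)) x * 0 else x, how = "replace")
}

adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 5e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  res <- .walk_grads(params, grads, state$m, state$v, function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  })
  state$m <- res$m; state$v <- res$v
  list(params = res$p, state = state)
}
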