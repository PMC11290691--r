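# The nested-grid segmenter: topology, attention module, losses, and a
# desk-scale training smoke test. Loss agreement with scalar-loop oracles
# is exercised at acceptance depth in test-acceptance.R.

test_that("grid topology enumerates the nested nodes", {
  topo <- cmunet_topology(4)
  expect_equal(nrow(topo), (4 + 1) * (4 + 2) / 2)
  expect_equal(as.vector(table(topo$i)), c(5, 4, 3, 2, 1))
  for (d in 1:5)
    expect_equal(nrow(cmunet_topology(d)), (d + 1) * (d + 2) / 2)
})

test_that("a node consumes all same-row predecessors plus one upsample", {
  cfg <- cmunet_config(depth = 3, widths = c(4, 6, 8, 10), block_convs = 1,
                       seed = 2)
  model <- cmunet_init(cfg)
  # input channels of node (0, j): j same-row maps of width 4 plus the
  # upsampled width-6 map from the row below
  for (j in 1:3) {
    w <- model$params$nodes[[paste0("0_", j)]]$c1$w
    expect_equal(nrow(w), 9 * (j * 4 + 6))
  }
  # encoder spine nodes see only the pooled parent
  expect_equal(nrow(model$params$nodes[["1_0"]]$c1$w), 9 * 4)
})

test_that("channel attention at beta 0 is the exact identity", {
  set.seed(1)
  x <- array(rnorm(6 * 5 * 8), c(6, 5, 8))
  expect_identical(max(abs(channel_attention(x, beta = 0) - x)), 0)
})

test_that("affinity rows are a softmax: each sums to one", {
  set.seed(2)
  for (K in c(1, 2, 7, 64)) {
    M <- channel_affinity(matrix(rnorm(K * 12), K, 12))
    expect_equal(rowSums(M), rep(1, K), tolerance = 1e-6)
  }
  expect_equal(channel_affinity(matrix(rnorm(4), 1, 4)),
               matrix(1, 1, 1))
})

test_that("channel attention matches a dense-loop oracle", {
  set.seed(3)
  Xk <- matrix(rnorm(2 * 4), 2, 4)
  or <- oracle_channel_attention(Xk, beta = 1)
  expect_lt(max(abs(channel_attention(Xk, beta = 1) - or$E)), 1e-6)
  expect_lt(max(abs(channel_affinity(Xk) - or$M)), 1e-6)
  # array in, array out
  x <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  E <- channel_attention(x, beta = 0.7)
  expect_equal(dim(E), dim(x))
})

test_that("the literal affinity variant differs and is inference-only", {
  set.seed(4)
  Xk <- matrix(rnorm(3 * 6), 3, 6)
  Ml <- channel_affinity(Xk, literal_eq2 = TRUE)
  expect_false(isTRUE(all.equal(rowSums(Ml), rep(1, 3))))
  cfg <- cmunet_config(depth = 1, widths = c(3, 4),
                       ca = list(enabled = TRUE, literal_eq2 = TRUE),
                       block_convs = 1)
  model <- cmunet_init(cfg)
  x <- array(runif(8 * 8 * 3 * 1), c(8, 8, 3, 1))
  expect_error(cytoscreen:::cmunet_forward(model, x), "inference only")
})

test_that("hybrid loss reproduces its closed-form corner cases", {
  # a single true pixel predicted perfectly: -(log 1 + 2/(2)) = -1
  # (up to the documented epsilon guard on the probability and the
  # overlap denominator)
  expect_equal(hybrid_loss(1, 1), -1, tolerance = 1e-6)
  # absent class with vanishing probability contributes nothing
  expect_equal(hybrid_loss(0, 1e-12), 0, tolerance = 1e-9)
  expect_error(hybrid_loss(matrix(1, 2, 2), matrix(1, 3, 3)), "mismatch")
})

test_that("side loss reduces, scales linearly, and validates lengths", {
  set.seed(5)
  t1 <- array(0, c(4, 4, 2, 1)); t1[, , 1, ] <- 1
  p <- array(runif(32), c(4, 4, 2, 1))
  expect_equal(side_loss(list(p), t1, 1), hybrid_loss(t1, p))
  a <- c(0.1, 0.3, 0.6, 0.9)
  preds <- replicate(4, array(runif(32), c(4, 4, 2, 1)), simplify = FALSE)
  expect_equal(side_loss(preds, t1, 2 * a), 2 * side_loss(preds, t1, a))
  expect_error(side_loss(preds, t1, c(0.5, 0.5)), "match")
  # all levels perfect: each contributes alpha * (perfect-loss value)
  perfect <- side_loss(replicate(4, t1, simplify = FALSE), t1, a)
  expect_equal(perfect, sum(a) * hybrid_loss(t1, t1))
})

test_that("total loss honors both the default and literal combinations", {
  expect_equal(total_seg_loss(0.4, 0.25), 0.65)
  expect_equal(total_seg_loss(0.4, 0.25, depth = 4, literal_eq6 = TRUE),
               4 * 0.65)
  # disabling supervision reduces the total to the final-layer loss
  expect_equal(total_seg_loss(0.4, 0), 0.4)
})

test_that("perturbing a perfect prediction never decreases the loss", {
  set.seed(6)
  t1 <- array(0, c(6, 6, 2, 1))
  msk <- matrix(rbinom(36, 1, 0.5), 6, 6)
  t1[, , 1, ] <- 1 - msk; t1[, , 2, ] <- msk
  base <- hybrid_loss(t1, t1)
  for (k in 1:20) {
    delta <- array(runif(72, 0, 0.2), c(6, 6, 2, 1))
    p <- t1 * (1 - delta) + (1 - t1) * delta   # move away from target
    expect_gte(hybrid_loss(t1, p), base)
  }
})

test_that("a short training run decreases the loss and is reproducible", {
  spec <- synth_spec(tile_size = 32, n_clumps = c(1, 2))
  imgs <- list(); msks <- list()
  for (i in 1:8) {
    rec <- generate_tile(spec, seed = i)
    imgs[[i]] <- rec$image; msks[[i]] <- rec$mask
  }
  cfg <- cmunet_config(depth = 1, widths = c(6, 10), block_convs = 1,
                       batch_size = 4, epochs = 4, seed = 9,
                       augment = FALSE)
  m1 <- train_segmenter(imgs, msks, cfg)
  expect_true(all(is.finite(m1$history$loss)))
  expect_lt(tail(m1$history$loss, 1), m1$history$loss[1])
  m2 <- train_segmenter(imgs, msks, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_error(train_segmenter(list(), list(), cfg), "empty")
})

test_that("segment returns tile-shaped masks with threshold bounds", {
  spec <- synth_spec(tile_size = 32, n_clumps = c(1, 2))
  rec <- generate_tile(spec, seed = 1)
  cfg <- cmunet_config(depth = 1, widths = c(4, 6), block_convs = 1,
                       batch_size = 2, epochs = 1, seed = 1,
                       augment = FALSE)
  m <- train_segmenter(list(rec$image), list(rec$mask), cfg)
  out <- segment(m, rec$image)
  expect_equal(dim(out), dim(rec$mask))
  expect_true(all(out %in% c(0L, 1L)))
  expect_true(all(segment(m, rec$image, threshold = 0) == 1))
  expect_true(all(segment(m, rec$image, threshold = 1) == 0))
  # non-divisible shapes are reflect-padded, then cropped back
  odd <- rec$image[1:30, 1:27, , drop = FALSE]
  expect_equal(dim(segment(m, odd)), c(30, 27))
})
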