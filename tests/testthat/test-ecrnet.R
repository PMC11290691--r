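test_that("momentum update follows its closed forms", {
  expect_equal(momentum_update(1.0, 2.0, 0.9), 1.1)
  # m = 0 copies the query parameters exactly
  q <- list(a = list(w = matrix(rnorm(4), 2), b = rnorm(2)))
  k <- list(a = list(w = matrix(0, 2, 2), b = c(0, 0)))
  expect_equal(momentum_update(k, q, 0), q)
  # repeated updates converge geometrically at rate m
  th_k <- 0; th_q <- 1; m <- 0.9
  for (t in 1:25) th_k <- momentum_update(th_k, th_q, m)
  expect_equal(th_k, 1 - m^25, tolerance = 1e-12)
  expect_error(momentum_update(c(1, 2), c(1, 2, 3), 0.5), "mismatch")
  expect_error(momentum_update(1, 2, 1))
})

test_that("memory bank is a FIFO with aligned labels", {
  bank <- memory_bank(4)
  e <- diag(6)[, 1:6]                # 6 unit-norm rows
  bank <- enqueue(bank, e[1:3, ], c("a", "b", "c"))
  bank <- enqueue(bank, e[4:6, ], c("d", "e", "f"))
  expect_equal(length(bank), 4)
  expect_equal(bank$labels, c("c", "d", "e", "f"))
  # embeddings stay aligned with their labels after eviction
  expect_equal(bank$embeddings, e[3:6, ], ignore_attr = TRUE)
  expect_equal(length(enqueue(bank, NULL, character(0))), 4)
  expect_warning(enqueue(memory_bank(4), matrix(c(3, 4), 1), "a"),
                 "renormalizing")
})

test_that("interleaved labels survive repeated eviction", {
  set.seed(8)
  bank <- memory_bank(8)
  ref <- list()
  for (t in 1:10) {
    e <- matrix(rnorm(2 * 5), 2, 5)
    e <- e / sqrt(rowSums(e^2))
    lab <- paste0("k", t, "_", 1:2)
    bank <- enqueue(bank, e, lab)
    ref[[t]] <- list(e = e, lab = lab)
  }
  # last 8 keys, in order
  want_lab <- unlist(lapply(ref[7:10], `[[`, "lab"))
  want_e <- do.call(rbind, lapply(ref[7:10], `[[`, "e"))
  expect_equal(bank$labels, want_lab)
  expect_equal(bank$embeddings, want_e, ignore_attr = TRUE)
})

test_that("contrastive loss attains its analytic limits", {
  q <- c(1, 0, 0)
  same <- memory_bank(8)
  e <- matrix(rnorm(5 * 3), 5, 3); e <- e / sqrt(rowSums(e^2))
  same <- enqueue(same, e, rep("pos", 5))
  expect_equal(label_contrastive_loss(q, "pos", same), 0)
  # equal similarities: loss = -log(n_pos / n) = log 2 for 2 of 4
  eq <- memory_bank(8)
  k <- rbind(c(0, 1, 0), c(0, 0, 1), c(0, 1, 0), c(0, 0, 1))
  eq <- enqueue(eq, k, c("pos", "neg", "pos", "neg"))
  expect_equal(label_contrastive_loss(q, "pos", eq), log(2),
               tolerance = 1e-12)
  # no positive key: a typed skip-sample condition, not infinity
  expect_error(label_contrastive_loss(q, "absent", eq),
               class = "cytoscreen_no_positive")
  expect_error(label_contrastive_loss(q, "pos", memory_bank(4)), "empty")
})

test_that("contrastive loss is nonnegative and matches the key oracle", {
  set.seed(9)
  for (rep in 1:25) {
    D <- 8; n <- 16
    keys <- matrix(rnorm(n * D), n, D)
    keys <- keys / sqrt(rowSums(keys^2))
    labs <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (!"malignant" %in% labs) labs[1] <- "malignant"
    q <- rnorm(D); q <- q / sqrt(sum(q^2))
    bank <- enqueue(memory_bank(n), keys, labs)
    got <- label_contrastive_loss(q, "malignant", bank, tau = 0.07)
    expect_gte(got, 0)
    expect_equal(got, oracle_contrastive(q, "malignant", keys, labs, 0.07),
                 tolerance = 1e-6)
  }
})

test_that("classifier loss covers its corner cases and the oracle", {
  perfect <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                    dimnames = list(NULL, c("benign", "malignant")))
  expect_equal(classifier_loss(perfect, c("benign", "malignant")), 0,
               tolerance = 1e-6)
  unif <- matrix(0.5, 4, 2, dimnames = list(NULL, c("benign", "malignant")))
  expect_equal(classifier_loss(unif, rep("benign", 4)), log(2))
  set.seed(10)
  p <- matrix(runif(8 * 2), 8, 2); p <- p / rowSums(p)
  colnames(p) <- c("benign", "malignant")
  lab <- sample(colnames(p), 8, replace = TRUE)
  expect_equal(classifier_loss(p, lab),
               oracle_cross_entropy(p, lab, colnames(p)),
               tolerance = 1e-6)
})

test_that("the combined objective weights its terms", {
  expect_equal(total_cls_loss(0.3, 0.8, 0.5), 0.7)
  expect_equal(total_cls_loss(0.3, 0.8, 0), 0.3)
  expect_equal(formals(total_cls_loss)$beta_loss, 0.5)
  expect_equal(formals(ecrnet_config)$tau, 0.07)
  expect_equal(formals(ecrnet_config)$momentum, 0.9)
})

test_that("training smoke: finite losses, growing bank, determinism", {
  spec <- synth_spec(tile_size = 96, n_clumps = c(1, 2))
  ds <- synth_roi_dataset(16, spec, seed = 1, canvas = 48, min_area = 32)
  cfg <- ecrnet_config(input_size = 16, stages = list(4, 8), embed_dim = 16,
                       bank_capacity = 64, batch_size = 8, epochs = 2,
                       canvas = 48, seed = 5)
  m1 <- train_classifier(ds$rois, ds$labels, cfg)
  expect_true(all(is.finite(m1$history$l_cla)))
  steps <- ceiling(length(ds$rois) / cfg$batch_size) * cfg$epochs
  expect_equal(length(m1$bank),
               min(steps * cfg$batch_size, cfg$bank_capacity,
                   length(ds$rois) * cfg$epochs))
  m2 <- train_classifier(ds$rois, ds$labels, cfg)
  expect_identical(m1$history, m2$history)
  expect_error(train_classifier(ds$rois, rep("benign", length(ds$rois)),
                                cfg), "single class")
})

test_that("the momentum encoder never receives gradients", {
  spec <- synth_spec(tile_size = 96, n_clumps = c(1, 2))
  ds <- synth_roi_dataset(12, spec, seed = 3, canvas = 48, min_area = 32)
  cfg <- ecrnet_config(input_size = 16, stages = list(4), embed_dim = 8,
                       bank_capacity = 32, batch_size = 6, epochs = 1,
                       canvas = 48, seed = 6, momentum = 0.9)
  m <- train_classifier(ds$rois, ds$labels, cfg)
  # after training, key params are an exponential average of query-param
  # trajectories: they differ from the query params but lie between the
  # initialization and the final query parameters
  init <- withr::with_seed(cfg$seed, cytoscreen:::.ecr_init_params(cfg))
  w_init <- init$stages$s1$c1$w
  w_q <- m$params$stages$s1$c1$w
  w_k <- m$key_params$stages$s1$c1$w
  expect_false(isTRUE(all.equal(w_k, w_q)))
  # the key weights moved strictly less than the query weights
  expect_lt(sum((w_k - w_init)^2), sum((w_q - w_init)^2))
  # bank embeddings remain unit norm after arbitrary training
  expect_equal(sqrt(rowSums(m$bank$embeddings^2)),
               rep(1, length(m$bank)), tolerance = 1e-6)
})

test_that("classification output is a proper distribution with tie rule", {
  spec <- synth_spec(tile_size = 96, n_clumps = c(1, 2))
  ds <- synth_roi_dataset(10, spec, seed = 4, canvas = 48, min_area = 32)
  cfg <- ecrnet_config(input_size = 16, stages = list(4), embed_dim = 8,
                       bank_capacity = 32, batch_size = 5, epochs = 1,
                       canvas = 48, seed = 7)
  m <- train_classifier(ds$rois, ds$labels, cfg)
  res <- classify(m, ds$rois[[1]])
  expect_equal(sum(res$probabilities), 1, tolerance = 1e-9)
  expect_true(res$label %in% c("benign", "malignant"))
  # degenerate all-zero canvas still classifies without error
  z <- suppressWarnings(classify(m, array(0, c(48, 48, 3))))
  expect_equal(sum(z$probabilities), 1, tolerance = 1e-9)
  # deterministic given fixed weights and input
  expect_identical(res, classify(m, ds$rois[[1]]))
  # wrong canvas size warns
  expect_warning(classify(m, array(0, c(20, 20, 3))), "resizing")
})
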