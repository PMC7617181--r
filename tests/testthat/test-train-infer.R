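test_that("Dice follows its closed form and symmetry", {
  a <- array(0L, dim = c(4, 4, 4)); b <- a
  a[1:2, 1, 1] <- 1L; b[1:2, 1, 1] <- 1L
  expect_equal(dice_score(a, b, 1), 1)
  b[] <- 0L; b[3:4, 4, 4] <- 1L
  expect_equal(dice_score(a, b, 1), 0)           # disjoint
  a[] <- 0L; a[1:4, 1, 1] <- 1L
  b[] <- 0L; b[3:4, 1, 1] <- 1L; b[1:2, 2, 1] <- 1L
  expect_equal(dice_score(a, b, 1), 0.5)          # |A|=4,|B|=4,|A^B|=2
  expect_equal(dice_score(a, b, 7), 1)            # both empty
  expect_error(dice_score(a, array(0L, dim = c(2, 2, 2)), 1), "shape")
  # symmetry and joint voxel permutation invariance
  set.seed(40)
  x <- array(sample(0:2, 64, TRUE), dim = c(4, 4, 4))
  y <- array(sample(0:2, 64, TRUE), dim = c(4, 4, 4))
  expect_equal(dice_score(x, y, 2), dice_score(y, x, 2))
  p <- sample(64)
  expect_equal(dice_score(array(x[p], dim(x)), array(y[p], dim(y)), 1),
               dice_score(x, y, 1))
})

test_that("early stopping halts exactly patience epochs after the best", {
  losses <- c(1.0, 0.8, 0.7, 0.75, 0.72, 0.74, 0.9)   # best at epoch 3
  st <- early_stop_state(patience = 3)
  stopped_at <- NA
  for (e in seq_along(losses)) {
    st <- early_stop_update(st, losses[e])
    if (st$stop) { stopped_at <- e; break }
  }
  expect_identical(st$best_epoch, 3L)
  expect_identical(stopped_at, 6L)                    # 3 + patience
  expect_equal(st$best, 0.7)
})

test_that("softmax cross-entropy loss and gradient are consistent", {
  set.seed(41)
  logits <- array(rnorm(3 * 4^3), dim = c(3, 4, 4, 4))
  labels <- array(sample(0:2, 4^3, TRUE), dim = c(4, 4, 4))
  ce <- softmax_cross_entropy(logits, labels)
  for (i in sample(length(logits), 5)) {
    eps <- 1e-6
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    fd <- (softmax_cross_entropy(lp, labels)$loss -
             softmax_cross_entropy(lm, labels)$loss) / (2 * eps)
    expect_equal(ce$grad[i], fd, tolerance = 1e-5)
  }
  # weighted version reweights voxel contributions
  cw <- c(2, 1, 1)
  cew <- softmax_cross_entropy(logits, labels, cw)
  expect_false(isTRUE(all.equal(ce$loss, cew$loss)))
})

test_that("single-patch prediction equals a direct forward pass", {
  set.seed(42)
  cfg <- unet_config(base_irreps = "2x0+1x1", levels = 2, kernel_size = 3,
                     in_channels = 1, n_classes = 3, l_max = 2)
  m <- build_equivariant_unet(cfg)
  x <- array(rnorm(12^3), dim = c(1, 12, 12, 12))
  pred <- predict_patchwise(m, x, patch_size = 12)
  logits <- unet_forward(m, x)$logits
  L <- matrix(logits, 3)
  P <- exp(sweep(L, 2, apply(L, 2, max)))
  P <- sweep(P, 2, colSums(P), "/")
  expect_equal(pred$probs, array(P, dim = dim(logits)), tolerance = 1e-12)
  expect_equal(as.vector(pred$labels),
               max.col(t(L), ties.method = "first") - 1L)
})

test_that("overlapping patches blend to valid, covering probabilities", {
  set.seed(43)
  cfg <- unet_config(base_irreps = "2x0+1x1", levels = 1, kernel_size = 3,
                     in_channels = 1, n_classes = 3, l_max = 2)
  m <- build_equivariant_unet(cfg)
  x <- array(rnorm(14 * 12 * 10), dim = c(1, 14, 12, 10))
  pred <- predict_patchwise(m, x, patch_size = 8, stride = 4)
  expect_true(all(is.finite(pred$probs)))        # weight coverage positive
  sums <- colSums(matrix(pred$probs, 3))
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-10)
  expect_equal(dim(pred$labels), c(14, 12, 10))
  # a model with zero weights emits constant logits -> uniform probabilities
  mz <- build_equivariant_unet(cfg, init = FALSE)
  pz <- predict_patchwise(mz, x, patch_size = 8, stride = 4)
  expect_equal(max(abs(pz$probs - 1 / 3)), 0, tolerance = 1e-12)
  # volume smaller than the patch: padded then cropped
  small <- array(rnorm(6^3), dim = c(1, 6, 6, 6))
  ps <- predict_patchwise(m, small, patch_size = 8)
  expect_equal(dim(ps$labels), c(6, 6, 6))
})

test_that("training reduces the loss and is seed-reproducible", {
  set.seed(44)
  spec <- phantom_spec(size = 24)
  ds <- generate_dataset(spec, 3, 1, 0, seed = 8)
  cfg <- unet_config(base_irreps = "2x0+1x1", levels = 2, kernel_size = 3,
                     in_channels = 1, n_classes = 6, l_max = 2)
  m <- build_equivariant_unet(cfg)
  theta0 <- model_parameters(m)
  r1 <- train_unet(m, ds$train, ds$val, epochs = 4, patience = 10,
                   class_weights = "balanced", seed = 3)
  expect_lt(r1$history$train_loss[4], r1$history$train_loss[1])
  m2 <- model_set_parameters(m, theta0)
  r2 <- train_unet(m2, ds$train, ds$val, epochs = 4, patience = 10,
                   class_weights = "balanced", seed = 3)
  expect_identical(r1$history, r2$history)
})
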