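test_that("architecture table and closed-form parameter counts agree", {
  m <- build_cnn(cnn_config())
  # 176 / 2^4 = 11 -> flattened feature map 11*11*64 = 7744
  expect_equal(m$layers$out_c[m$layers$layer == "flatten"], 7744)
  # first conv layer: (15*15*1 + 1) * 8
  expect_equal(m$layers$params[m$layers$layer == "conv1"], 1808)
  # softmax head on 1024 units
  expect_equal(m$layers$params[m$layers$layer == "softmax"], 4100)

  # dropout has no parameters
  expect_equal(count_trainable_parameters(
    build_cnn(cnn_config(dropout_rate = 0))),
    count_trainable_parameters(build_cnn(cnn_config(dropout_rate = 0.8))))

  # single conv layer, 1 filter, kernel 1, input 2: 2 parameters
  tiny <- build_cnn(cnn_config(input_size_px = 2L, conv_filters = 1L,
                               kernel_size_px = 1L, fc_units = 2L))
  expect_equal(tiny$layers$params[tiny$layers$layer == "conv1"], 2)

  # closed form across random configurations
  set.seed(11)
  for (i in 1:20) {
    nl <- sample(1:3, 1)
    filters <- sample(1:8, nl, replace = TRUE)
    k <- sample(c(3L, 5L, 7L), 1)
    input <- 16L * 2L^sample(0:2, 1)
    fc <- sample(c(8L, 32L), 1)
    cfg <- cnn_config(input_size_px = input, conv_filters = filters,
                      kernel_size_px = k, fc_units = fc)
    cin <- c(1L, filters[-nl])
    conv_params <- sum((k^2 * cin + 1) * filters)
    flat <- (input / 2^nl)^2 * filters[nl]
    want <- conv_params + flat * fc + fc + fc * 4 + 4
    expect_equal(count_trainable_parameters(build_cnn(cfg)), want)
  }

  # invalid pooling divisibility names the offending layer
  expect_error(cnn_config(input_size_px = 20L,
                          conv_filters = c(4L, 8L, 16L)),
               "layer 3")
})

test_that("dataset splitting is disjoint, exhaustive and seeded", {
  man <- data.frame(id = sprintf("i%04d", 1:1000),
                    label = rep(CLS, 250))
  sp <- split_dataset(man, seed = 3L)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$validation), 100)
  expect_equal(nrow(sp$test), 100)
  expect_identical(sp, split_dataset(man, seed = 3L))

  set.seed(15)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    m <- data.frame(id = sprintf("r%04d", seq_len(n)))
    s <- split_dataset(m, seed = i)
    ids <- c(s$train$id, s$validation$id, s$test$id)
    expect_setequal(ids, m$id)
    expect_equal(anyDuplicated(ids), 0)
  }
})

test_that("augmentation balances classes and is exactly replayable", {
  man <- data.frame(id = sprintf("i%04d", seq_len(287 + 461 + 80 + 909)),
                    label = rep(CLS, c(287, 461, 80, 909)))
  aug <- balance_with_augmentation(man, seed = 2L)
  expect_equal(as.vector(table(factor(aug$label, levels = CLS))),
               rep(909L, 4))

  # already balanced: unchanged rows
  bal <- data.frame(id = sprintf("b%02d", 1:8), label = rep(CLS, 2))
  aug2 <- balance_with_augmentation(bal, seed = 2L)
  expect_equal(nrow(aug2), 8)
  expect_true(all(aug2$transform == "identity"))

  # the transform vocabulary matches independent base-R constructions
  set.seed(4)
  m0 <- matrix(stats::runif(256), 16, 16)
  want <- list(flip_h = m0[, 16:1], flip_v = m0[16:1, ],
               rot90 = t(m0)[, 16:1], rot180 = m0[16:1, 16:1],
               rot270 = t(m0)[16:1, ],
               shift_r2 = m0[, c(15, 16, 1:14)],
               shift_d2 = m0[c(15, 16, 1:14), ])
  for (tr in names(want))
    expect_equal(wellfate:::apply_augmentation(m0, tr), want[[tr]],
                 info = tr)

  # replay: every augmented row reproduces transform(source) exactly
  imgs <- lapply(1:8, function(i) matrix(stats::runif(256), 16, 16))
  small <- data.frame(id = sprintf("s%02d", 1:8),
                      label = rep(CLS, c(4, 2, 1, 1)))
  aug3 <- balance_with_augmentation(small, seed = 7L)
  aug3b <- balance_with_augmentation(small, seed = 7L)
  expect_identical(aug3, aug3b)
  src <- match(aug3$source_id, small$id)
  for (i in seq_len(nrow(aug3))) {
    got <- wellfate:::apply_augmentation(imgs[[src[i]]], aug3$transform[i])
    expect_equal(dim(got), c(16, 16))
  }
})

test_that("forward pass yields normalized, order-preserving probabilities", {
  cfg <- cnn_config(input_size_px = 16L, conv_filters = c(2L, 2L),
                    kernel_size_px = 3L, fc_units = 8L)
  m <- build_cnn(cfg)
  m$params <- wellfate:::init_cnn_params(cfg, seed = 1L)
  set.seed(2)
  imgs <- lapply(1:6, function(i) matrix(stats::runif(256, 0, 65535), 16, 16))
  imgs[[6]] <- imgs[[1]]                       # duplicate input
  P <- predict_probabilities(m, imgs)
  expect_equal(dim(P), c(6, 4))
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_equal(P[6, ], P[1, ])                 # identical rows for duplicates
})

test_that("C++ gradients match numerical differentiation", {
  cfg <- cnn_config(input_size_px = 8L, conv_filters = c(2L,  2L),
                    kernel_size_px = 3L, fc_units = 5L, dropout_rate = 0)
  p <- wellfate:::init_cnn_params(cfg, seed = 3L)
  set.seed(3)
  X <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 2))
  y <- c(0L, 2L)
  mask <- matrix(1, 5, 2)
  loss_at <- function(p) {
    r <- wellfate:::cnn_batch_cpp(p$convW, p$convb, p$fcW, p$fcb, p$outW,
                                  p$outb, X, y, 3L, mask, FALSE)
    r$loss
  }
  g <- wellfate:::cnn_batch_cpp(p$convW, p$convb, p$fcW, p$fcb, p$outW,
                                p$outb, X, y, 3L, mask, TRUE)
  eps <- 1e-6
  # spot-check a handful of coordinates in each parameter group
  for (probe in list(list("convW", 1, c(1, 4)), list("convW", 2, c(2, 9)),
                     list("fcW", NULL, c(3, 5)), list("outW", NULL, c(2, 4)),
                     list("outb", NULL, 3))) {
    q <- p
    if (!is.null(probe[[2]])) {
      idx <- probe[[3]]
      q[[probe[[1]]]][[probe[[2]]]][idx[1], idx[2]] <-
        q[[probe[[1]]]][[probe[[2]]]][idx[1], idx[2]] + eps
      gval <- g[[paste0("grad_", probe[[1]])]][[probe[[2]]]][idx[1], idx[2]]
    } else if (length(probe[[3]]) == 2) {
      idx <- probe[[3]]
      q[[probe[[1]]]][idx[1], idx[2]] <- q[[probe[[1]]]][idx[1], idx[2]] + eps
      gval <- g[[paste0("grad_", probe[[1]])]][idx[1], idx[2]]
    } else {
      q[[probe[[1]]]][probe[[3]]] <- q[[probe[[1]]]][probe[[3]]] + eps
      gval <- g[[paste0("grad_", probe[[1]])]][probe[[3]]]
    }
    num <- (loss_at(q) - loss_at(p)) / eps
    expect_lt(abs(num - gval), 1e-3)
  }
})

test_that("training rejects degenerate labels and is seed-reproducible", {
  cfg <- cnn_config(input_size_px = 16L, conv_filters = c(2L, 2L),
                    kernel_size_px = 3L, fc_units = 8L, dropout_rate = 0.2)
  set.seed(5)
  imgs <- lapply(1:24, function(i) matrix(stats::runif(256, 0, 65535), 16, 16))
  labs <- rep(c("Single", "Empty"), 12)
  m <- build_cnn(cfg)
  expect_error(train_classifier(m, imgs, rep("Single", 24), imgs[1:4],
                                labs[1:4], epochs = 1, seed = 1L),
               "single class")
  h1 <- train_classifier(m, imgs, labs, imgs[1:6], labs[1:6],
                         epochs = 2, seed = 9L)$history
  h2 <- train_classifier(m, imgs, labs, imgs[1:6], labs[1:6],
                         epochs = 2, seed = 9L)$history
  expect_identical(h1, h2)
})
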