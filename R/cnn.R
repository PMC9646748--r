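#' Configuration of the 4-class microwell CNN
#'
#' The optimized architecture: four convolution layers of 8, 16, 32 and 64
#' filters with 15 x 15 kernels (same padding), each followed by ReLU and a
#' 2 x 2 max-pool, then one fully connected layer of 1024 units with an 80%
#' dropout rate, and a 4-way softmax head.  At the default 176 x 176
#' grayscale input this network has exactly 8,541,700 trainable parameters.
#'
#' @param input_size_px square input side; must survive
#'   `length(conv_filters)` halvings (even size before every pool).
#' @param conv_filters filter counts per convolution layer.
#' @param kernel_size_px odd convolution kernel side.
#' @param pool_size pooling factor (fixed at 2).
#' @param fc_units units in the fully connected layer.
#' @param dropout_rate dropout after the fully connected layer, in [0, 1).
#' @param n_classes number of output classes (4).
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(input_size_px = 176L,
                       conv_filters = c(8L, 16L, 32L, 64L),
                       kernel_size_px = 15L,
                       pool_size = 2L,
                       fc_units = 1024L,
                       dropout_rate = 0.8,
                       n_classes = 4L) {
  check(pool_size == 2L, "only 2x2 pooling is supported")
  check(kernel_size_px %% 2 == 1, "kernel size must be odd (same padding)")
  check(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate must be in [0, 1)")
  check(length(conv_filters) >= 1 && all(conv_filters >= 1),
        "conv_filters must be positive counts")
  size <- as.integer(input_size_px)
  for (l in seq_along(conv_filters)) {
    check(size %% 2L == 0L,
          sprintf("input_size_px %d: size %d entering pooling of conv layer %d is odd",
                  input_size_px, size, l))
    size <- size %/% 2L
  }
  structure(list(input_size_px = as.integer(input_size_px),
                 conv_filters = as.integer(conv_filters),
                 kernel_size_px = as.integer(kernel_size_px),
                 pool_size = 2L,
                 fc_units = as.integer(fc_units),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 flat_side = size),
            class = "cnn_config")
}

#' Build the CNN (architecture description; weights lazily initialized)
#'
#' @param config a [cnn_config()].
#' @return Object of class `wellfate_cnn` with a per-layer summary table
#'   (`$layers`: output shapes and parameter counts) and empty parameters.
#' @export
build_cnn <- function(config = cnn_config()) {
  check(inherits(config, "cnn_config"), "need a cnn_config")
  k <- config$kernel_size_px
  cin <- 1L
  size <- config$input_size_px
  rows <- list()
  for (l in seq_along(config$conv_filters)) {
    f <- config$conv_filters[l]
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("conv%d", l), out_h = size, out_w = size, out_c = f,
      params = (k * k * cin + 1) * f)
    size <- size %/% 2L
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("pool%d", l), out_h = size, out_w = size, out_c = f,
      params = 0)
    cin <- f
  }
  flat <- size * size * cin
  rows[[length(rows) + 1]] <- data.frame(layer = "flatten", out_h = 1,
                                         out_w = 1, out_c = flat, params = 0)
  rows[[length(rows) + 1]] <- data.frame(layer = "fc", out_h = 1, out_w = 1,
                                         out_c = config$fc_units,
                                         params = flat * config$fc_units +
                                           config$fc_units)
  rows[[length(rows) + 1]] <- data.frame(layer = "softmax", out_h = 1,
                                         out_w = 1, out_c = config$n_classes,
                                         params = config$fc_units *
                                           config$n_classes + config$n_classes)
  structure(list(config = config,
                 layers = do.call(rbind, rows),
                 params = NULL,
                 history = NULL),
            class = "wellfate_cnn")
}

#' Count trainable parameters
#'
#' Sum of all convolution, fully connected and softmax-head weights and
#' biases (dropout contributes none).  Computed from the architecture, or
#' from the materialized weight arrays when the model has been initialized
#' (the two always agree).
#'
#' @param model a `wellfate_cnn` from [build_cnn()].
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  check(inherits(model, "wellfate_cnn"), "need a wellfate_cnn")
  if (!is.null(model$params)) {
    p <- model$params
    sum(vapply(c(p$convW, p$convb, list(p$fcW, p$fcb, p$outW, p$outb)),
               length, numeric(1)))
  } else {
    sum(model$layers$params)
  }
}

# He/Glorot-style seeded initialization of all weight arrays.
init_cnn_params <- function(config, seed) {
  with_seed(seed, {
    k <- config$kernel_size_px
    cin <- 1L
    convW <- list(); convb <- list()
    for (f in config$conv_filters) {
      fan_in <- k * k * cin
      convW[[length(convW) + 1]] <-
        matrix(stats::rnorm(f * fan_in, 0, sqrt(2 / fan_in)), f, fan_in)
      convb[[length(convb) + 1]] <- numeric(f)
      cin <- f
    }
    flat <- config$flat_side^2 * cin
    list(convW = convW, convb = convb,
         fcW = matrix(stats::rnorm(config$fc_units * flat, 0, sqrt(2 / flat)),
                      config$fc_units, flat),
         fcb = numeric(config$fc_units),
         outW = matrix(stats::rnorm(config$n_classes * config$fc_units, 0,
                                    sqrt(1 / config$fc_units)),
                       config$n_classes, config$fc_units),
         outb = numeric(config$n_classes))
  })
}

#' Split a dataset manifest 80/10/10
#'
#' Random disjoint partition into training, validation and test sets (10%
#' validation, 10% test, rounded down; remainder trains), sampled without
#' replacement under the given seed.  Every row appears in exactly one
#' split.
#'
#' @param manifest data frame with one row per image (any columns).
#' @param seed integer seed.
#' @param val_frac,test_frac held-out fractions.
#' @return `list(train, validation, test)` of row-subsets of `manifest`.
#' @export
split_dataset <- function(manifest, seed = 1L, val_frac = 0.1,
                          test_frac = 0.1) {
  n <- nrow(manifest)
  check(n >= 10, "need at least 10 rows to split")
  n_val <- floor(n * val_frac)
  n_test <- floor(n * test_frac)
  idx <- with_seed(seed, sample.int(n))
  val_i <- idx[seq_len(n_val)]
  test_i <- idx[n_val + seq_len(n_test)]
  train_i <- idx[-seq_len(n_val + n_test)]
  list(train = manifest[sort(train_i), , drop = FALSE],
       validation = manifest[sort(val_i), , drop = FALSE],
       test = manifest[sort(test_i), , drop = FALSE])
}

# The label-preserving transform vocabulary used for augmentation.
apply_augmentation <- function(img, transform) {
  m <- unclass(img)
  switch(transform,
         identity = m,
         flip_h = m[, rev(seq_len(ncol(m))), drop = FALSE],
         flip_v = m[rev(seq_len(nrow(m))), , drop = FALSE],
         rot90 = t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
         rot180 = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
         rot270 = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
         shift_r2 = m[, c(ncol(m) - 1, ncol(m), seq_len(ncol(m) - 2)),
                      drop = FALSE],
         shift_d2 = m[c(nrow(m) - 1, nrow(m), seq_len(nrow(m) - 2)), ,
                      drop = FALSE],
         stop("unknown transform: ", transform))
}

augmentation_transforms <- function() {
  c("flip_h", "flip_v", "rot90", "rot180", "rot270", "shift_r2", "shift_d2")
}

#' Balance a training manifest by augmentation
#'
#' Brings every class up to the size of the largest class by adding
#' label-preserving transforms (flips, 90-degree rotations, 2 px cyclic
#' translations) of randomly chosen source images of that class.  Each
#' added row records its source row and transform so the augmentation can
#' be replayed exactly.
#'
#' @param manifest training manifest with a `label` column.
#' @param seed integer seed.
#' @return The augmented manifest: original rows (with
#'   `transform = "identity"`, `source_id = id`) plus augmentation rows.
#' @export
balance_with_augmentation <- function(manifest, seed = 1L) {
  check("label" %in% names(manifest), "manifest needs a 'label' column")
  counts <- table(factor(manifest$label, levels = well_classes()))
  check(all(counts > 0), "every class must be nonempty")
  target <- max(counts)
  if (!"id" %in% names(manifest))
    manifest$id <- sprintf("row_%05d", seq_len(nrow(manifest)))
  out <- manifest
  out$source_id <- manifest$id
  out$transform <- "identity"
  trs <- augmentation_transforms()
  with_seed(seed, {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0) next
      src_rows <- which(manifest$label == cl)
      pick <- sample(src_rows, need, replace = need > length(src_rows))
      tr <- sample(trs, need, replace = TRUE)
      add <- manifest[pick, , drop = FALSE]
      add$source_id <- manifest$id[pick]
      add$id <- sprintf("%s_aug%04d", cl, seq_len(need))
      add$transform <- tr
      out <- rbind(out, add)
    }
  })
  rownames(out) <- NULL
  out
}

# Resize to the network input and standardize per image (z-score; a flat
# image maps to zeros).  Returns an H x W x N array.
preprocess_images <- function(images, input_size_px) {
  n <- length(images)
  X <- array(0, c(input_size_px, input_size_px, n))
  for (i in seq_len(n)) {
    m <- unclass(images[[i]])
    if (nrow(m) != input_size_px || ncol(m) != input_size_px)
      m <- resize_bilinear(m, input_size_px)
    s <- stats::sd(m)
    X[, , i] <- if (s > 0) (m - mean(m)) / s else m * 0
  }
  X
}

#' Train the microwell classifier
#'
#' Minimizes categorical cross-entropy with Adam (default learning rate
#' 2e-3: in short, few-hundred-step training budgets 1e-3 visibly
#' underfits while 3e-3 is unstable; see the methods vignette), batch
#' size 32, with inverted dropout after the fully connected
#' layer.  The returned model carries the weights of the epoch with the
#' best validation accuracy and a per-epoch history.  Weight
#' initialization, shuffling and dropout masks are all driven by `seed`;
#' runs are reproducible within one numerical configuration (BLAS build
#' and thread count).
#'
#' @param model a `wellfate_cnn` from [build_cnn()].
#' @param train_images,val_images lists of grayscale matrices (resized to
#'   the configured input with bilinear interpolation, then per-image
#'   z-scored).
#' @param train_labels,val_labels character/factor labels from
#'   [well_classes()].
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @return The model with `$params` (best-validation weights) and
#'   `$history` (data frame: epoch, train_loss, train_acc, val_acc).
#' @export
train_classifier <- function(model, train_images, train_labels,
                             val_images, val_labels,
                             epochs = 5L, batch_size = 32L, lr = 2e-3,
                             seed = 1L) {
  check(inherits(model, "wellfate_cnn"), "need a wellfate_cnn")
  cfg <- model$config
  cls <- well_classes()
  y_tr <- match(as.character(train_labels), cls) - 1L
  y_va <- match(as.character(val_labels), cls) - 1L
  check(!anyNA(y_tr) && !anyNA(y_va), "labels must be among well_classes()")
  check(length(unique(y_tr)) >= 2,
        "degenerate label set: training data contain a single class")
  check(length(train_images) == length(y_tr) &&
          length(val_images) == length(y_va),
        "images and labels must have equal lengths")

  Xtr <- preprocess_images(train_images, cfg$input_size_px)
  Xva <- preprocess_images(val_images, cfg$input_size_px)
  params <- init_cnn_params(cfg, seed)
  flat_params <- function(p) c(p$convW, p$convb,
                               list(p$fcW, p$fcb, p$outW, p$outb))
  unflat <- function(v, p) {
    L <- length(p$convW)
    list(convW = v[seq_len(L)], convb = v[L + seq_len(L)],
         fcW = v[[2 * L + 1]], fcb = v[[2 * L + 2]],
         outW = v[[2 * L + 3]], outb = v[[2 * L + 4]])
  }
  m_st <- lapply(flat_params(params), function(x) x * 0)
  v_st <- m_st
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n_tr <- length(y_tr)
  keep <- 1 - cfg$dropout_rate
  history <- NULL
  best <- list(acc = -Inf, params = params)

  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1, n_tr, by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1, n_tr)]
        nb <- length(bi)
        mask <- matrix(stats::rbinom(cfg$fc_units * nb, 1, keep) / keep,
                       cfg$fc_units, nb)
        res <- cnn_batch_cpp(params$convW, params$convb, params$fcW,
                             params$fcb, params$outW, params$outb,
                             Xtr[, , bi, drop = FALSE], y_tr[bi],
                             cfg$kernel_size_px, mask, TRUE)
        if (!is.finite(res$loss))
          stop(sprintf("non-finite loss at epoch %d (batch starting %d); ",
                       ep, b0),
               "lower the learning rate or check input scaling",
               call. = FALSE)
        ep_loss <- ep_loss + res$loss * nb
        ep_correct <- ep_correct + res$n_correct
        g <- c(res$grad_convW, res$grad_convb,
               list(res$grad_fcW, res$grad_fcb, res$grad_outW, res$grad_outb))
        p <- flat_params(params)
        step <- step + 1L
        corr <- lr * sqrt(1 - b2^step) / (1 - b1^step)
        for (j in seq_along(p)) {
          m_st[[j]] <- b1 * m_st[[j]] + (1 - b1) * g[[j]]
          v_st[[j]] <- b2 * v_st[[j]] + (1 - b2) * g[[j]]^2
          p[[j]] <- p[[j]] - corr * m_st[[j]] / (sqrt(v_st[[j]]) + eps)
        }
        params <- unflat(p, params)
      }
      pv <- cnn_forward_probs_cpp(params$convW, params$convb, params$fcW,
                                  params$fcb, params$outW, params$outb,
                                  Xva, cfg$kernel_size_px)
      val_acc <- mean(max.col(pv, ties.method = "first") - 1L == y_va)
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = ep_loss / n_tr,
                                  train_acc = ep_correct / n_tr,
                                  val_acc = val_acc))
      if (val_acc > best$acc) best <- list(acc = val_acc, params = params)
    }
  })
  model$params <- best$params
  model$history <- history
  model
}

#' Per-frame class probabilities from a trained model
#'
#' One softmax-normalized 4-vector per input image, in input order.
#'
#' @param model trained `wellfate_cnn`.
#' @param images list of grayscale matrices.
#' @return Numeric matrix `n x 4`, columns [well_classes()], rows summing
#'   to 1.
#' @export
predict_probabilities <- function(model, images) {
  check(inherits(model, "wellfate_cnn") && !is.null(model$params),
        "model must be trained (or have initialized parameters)")
  cfg <- model$config
  X <- preprocess_images(images, cfg$input_size_px)
  P <- cnn_forward_probs_cpp(model$params$convW, model$params$convb,
                             model$params$fcW, model$params$fcb,
                             model$params$outW, model$params$outb,
                             X, cfg$kernel_size_px)
  colnames(P) <- well_classes()
  P
}

#' @export
print.wellfate_cnn <- function(x, ...) {
  cat(sprintf("<wellfate_cnn> input %dx%d, %s trainable parameters%s\n",
              x$config$input_size_px, x$config$input_size_px,
              format(count_trainable_parameters(x), big.mark = ","),
              if (is.null(x$params)) " (untrained)" else " (trained)"))
  print(x$layers, row.names = FALSE)
  invisible(x)
}
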