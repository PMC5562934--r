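#' Desk-scale convolutional embedding backbone
#'
#' A frozen convolutional feature extractor playing the role of the pretrained
#' image network in the transfer-learning route: the image is converted to an
#' ink-intensity grayscale map, block-averaged to about 47x47, passed through
#' two convolution + ReLU + mean-pool stages whose filters are drawn once from
#' a seeded Gaussian and then fixed, and flattened into an L2-normalised
#' embedding ("bottleneck"). The backbone is never trained: for fixed weights,
#' `embed` is a deterministic function of the pixel values, and only the final
#' softmax layer is learned downstream ([retrain_final_layer()]).
#'
#' @param seed Seed for the one-off filter draw (part of the backbone
#'   identity; two backbones with the same seed are identical).
#' @param n_filters1,n_filters2 Filters in the two convolution stages.
#' @return Object of class `imu_backbone` with fields `name`, `embed_dim` and
#'   `embed(pixels)`.
#' @export
tiny_cnn_backbone <- function(seed = 42L, n_filters1 = 8L, n_filters2 = 8L) {
  w <- .with_seed(as.integer(seed), list(
    f1 = array(stats::rnorm(5 * 5 * n_filters1, sd = 0.4), c(5, 5, n_filters1)),
    f2 = array(stats::rnorm(3 * 3 * n_filters1 * n_filters2, sd = 0.4),
               c(3, 3, n_filters1, n_filters2))))
  embed <- function(pixels) .tiny_cnn_embed(pixels, w$f1, w$f2)
  dim0 <- length(embed(array(0, c(470, 470, 3))))
  structure(list(name = sprintf("tiny-cnn-%d", as.integer(seed)),
                 weights = w, embed = embed, embed_dim = dim0),
            class = "imu_backbone")
}

## mean-pool a matrix by k x k blocks (trailing remainder rows/cols dropped)
.block_pool <- function(m, k) {
  nr <- nrow(m) %/% k; nc <- ncol(m) %/% k
  m <- m[seq_len(nr * k), seq_len(nc * k), drop = FALSE]
  P <- function(n) {
    p <- matrix(0, n, n * k)
    p[cbind(rep(seq_len(n), each = k), seq_len(n * k))] <- 1 / k
    p
  }
  P(nr) %*% m %*% t(P(nc))
}

## valid 2-D convolution of a stack of feature maps (list of matrices) with a
## filter bank, via im2col
.conv_valid <- function(maps, bank) {
  kh <- dim(bank)[1L]; kw <- dim(bank)[2L]
  n_in <- length(maps); n_out <- dim(bank)[length(dim(bank))]
  nr <- nrow(maps[[1L]]) - kh + 1L; nc <- ncol(maps[[1L]]) - kw + 1L
  cols <- matrix(0, nr * nc, kh * kw * n_in)
  j <- 0L
  for (ci in seq_len(n_in)) for (dc in seq_len(kw)) for (dr in seq_len(kh)) {
    j <- j + 1L
    cols[, j] <- as.vector(maps[[ci]][dr:(dr + nr - 1L), dc:(dc + nc - 1L)])
  }
  W <- matrix(bank, nrow = kh * kw * n_in, ncol = n_out)
  out <- cols %*% W
  lapply(seq_len(n_out), function(f) matrix(out[, f], nr, nc))
}

.tiny_cnn_embed <- function(pixels, f1, f2) {
  stopifnot(length(dim(pixels)) == 3L)
  g <- 1 - (pixels[, , 1L] + pixels[, , 2L] + pixels[, , 3L]) / 3  # ink map
  k <- max(1L, nrow(g) %/% 47L)
  g <- .block_pool(g, k)
  h1 <- lapply(.conv_valid(list(g), f1), function(m) pmax(m, 0))
  h1 <- lapply(h1, .block_pool, k = 4L)
  h2 <- lapply(.conv_valid(h1, f2), function(m) pmax(m, 0))
  h2 <- lapply(h2, .block_pool, k = 2L)
  v <- unlist(h2)
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v
}

#' Compute and cache bottleneck embeddings for an image folder tree
#'
#' Walks a folder-per-label image dataset (the layout written by
#' [write_image_dataset()]), embeds every image with the backbone, and caches
#' each embedding on disk keyed by backbone name and image content hash, so a
#' warm re-run recomputes nothing.
#'
#' @param image_dir Root directory with one subfolder per class label.
#' @param backbone An `imu_backbone`.
#' @param cache_dir Cache directory (default `<image_dir>/.bottlenecks`);
#'   `NULL` disables caching.
#' @return List with `embeddings` (n x embed_dim matrix), `labels` (character),
#'   `files`, `cache_hits` (count of embeddings served from cache).
#' @export
compute_bottlenecks <- function(image_dir, backbone,
                                cache_dir = file.path(image_dir, ".bottlenecks")) {
  stopifnot(inherits(backbone, "imu_backbone"))
  classes <- sort(list.dirs(image_dir, recursive = FALSE, full.names = FALSE))
  classes <- setdiff(classes, ".bottlenecks")
  if (!length(classes)) stop("no class folders under ", image_dir, call. = FALSE)
  if (!is.null(cache_dir)) dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  emb <- list(); labels <- character(0); files <- character(0); hits <- 0L
  for (cl in classes) {
    imgs <- sort(list.files(file.path(image_dir, cl),
                            pattern = "\\.(png|jpe?g)$", full.names = TRUE))
    if (!length(imgs))
      stop("empty class folder: ", file.path(image_dir, cl), call. = FALSE)
    for (f in imgs) {
      key <- if (is.null(cache_dir)) NULL else
        file.path(cache_dir, sprintf("%s-%s.csv", backbone$name,
                                     unname(tools::md5sum(f))))
      if (!is.null(key) && file.exists(key)) {
        v <- as.numeric(utils::read.csv(key)$value)
        hits <- hits + 1L
      } else {
        v <- backbone$embed(read_image(f))
        if (!is.null(key))
          utils::write.csv(data.frame(value = v), key, row.names = FALSE)
      }
      emb[[length(emb) + 1L]] <- v
      labels <- c(labels, cl); files <- c(files, f)
    }
  }
  list(embeddings = do.call(rbind, emb), labels = labels,
       files = files, cache_hits = hits)
}

#' Final-layer training configuration
#'
#' Hyperparameters for retraining the softmax output layer on cached
#' bottleneck embeddings. The desk-scale default is 1,000 steps; the
#' `"study"` preset keeps the 96,000-step schedule used at full scale.
#'
#' @param steps Gradient steps (default 1000).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Step size (default 0.5).
#' @param validation_fraction Fraction held out for the validation curve,
#'   in (0, 1) (default 0.1).
#' @param log_every Log the training curves every this many steps (default 25;
#'   step 1 and the final step are always logged).
#' @param seed Seed for the validation split and batch order.
#' @param preset `"desk"` (default) or `"study"` (96,000 steps).
#' @return Object of class `train_config`.
#' @export
train_config <- function(steps = 1000L, batch_size = 32L, learning_rate = 0.5,
                         validation_fraction = 0.1, log_every = 25L, seed = 1L,
                         preset = c("desk", "study")) {
  preset <- match.arg(preset)
  if (preset == "study") steps <- 96000L
  stopifnot(steps >= 1, batch_size >= 1, learning_rate > 0,
            validation_fraction > 0, validation_fraction < 1, log_every >= 1)
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 log_every = as.integer(log_every), seed = as.integer(seed)),
            class = "train_config")
}

#' Retrain the final softmax layer on bottleneck embeddings
#'
#' Multinomial softmax classifier over fixed embeddings, trained by
#' mini-batch gradient descent on the cross-entropy loss. The
#' validation split (stratified, at least one training example per class) and
#' the batch order are fully determined by `config$seed`, so a fixed seed
#' yields identical training curves. Curves record training accuracy,
#' validation accuracy and training cross entropy at each logged step.
#'
#' @param embeddings n x d numeric matrix of bottleneck embeddings.
#' @param labels Class label per row.
#' @param config A [train_config()].
#' @param backbone_name Recorded in the model for provenance.
#' @return List with `model` (class `softmax_model`: weight matrix and ordered
#'   label list) and `curves` (`data.frame`: step, train_accuracy,
#'   validation_accuracy, cross_entropy).
#' @export
retrain_final_layer <- function(embeddings, labels, config = train_config(),
                                backbone_name = "tiny-cnn") {
  embeddings <- as.matrix(embeddings)
  labels <- factor(labels)
  n <- nrow(embeddings)
  stopifnot(n == length(labels))
  if (nlevels(labels) < 2L)
    stop("need at least 2 classes to retrain the classifier", call. = FALSE)

  .with_seed(config$seed, {
    ## stratified validation split, keeping >= 1 training example per class
    val <- unlist(lapply(split(seq_len(n), labels), function(idx) {
      k <- floor(length(idx) * config$validation_fraction)
      if (length(idx) - k < 1L)
        stop("degenerate split: a class would lose all training examples",
             call. = FALSE)
      if (k > 0L) sample(idx, k) else integer(0)
    }))
    tr <- setdiff(seq_len(n), val)
    if (!length(val)) val <- tr   # tiny datasets: validate on train

    X <- cbind(1, embeddings)     # bias column
    Y <- diag(nlevels(labels))[as.integer(labels), , drop = FALSE]
    W <- matrix(0, ncol(X), nlevels(labels))

    softmax <- function(Z) {
      Z <- exp(Z - apply(Z, 1L, max))
      Z / rowSums(Z)
    }
    metrics <- function(step) {
      Ptr <- softmax(X[tr, , drop = FALSE] %*% W)
      Pva <- softmax(X[val, , drop = FALSE] %*% W)
      yt <- as.integer(labels)
      data.frame(
        step = step,
        train_accuracy = mean(max.col(Ptr, ties.method = "first") == yt[tr]),
        validation_accuracy = mean(max.col(Pva, ties.method = "first") == yt[val]),
        cross_entropy = -mean(log(pmax(Ptr[cbind(seq_along(tr), yt[tr])], 1e-12))))
    }

    curves <- list()
    for (step in seq_len(config$steps)) {
      b <- sample(tr, min(config$batch_size, length(tr)))
      Xb <- X[b, , drop = FALSE]
      P <- softmax(Xb %*% W)
      grad <- crossprod(Xb, P - Y[b, , drop = FALSE]) / length(b)
      W <- W - config$learning_rate * grad
      if (step == 1L || step %% config$log_every == 0L || step == config$steps)
        curves[[length(curves) + 1L]] <- metrics(step)
    }
    model <- structure(
      list(backbone = backbone_name, weights = W, labels = levels(labels)),
      class = "softmax_model")
    list(model = model, curves = do.call(rbind, curves))
  })
}

#' Predict classes from bottleneck embeddings
#'
#' @param object A `softmax_model` from [retrain_final_layer()].
#' @param newdata n x d embedding matrix (or a single embedding vector).
#' @param ... Unused.
#' @return List with `labels` (argmax class, ties broken by label order) and
#'   `probs` (matrix of class probabilities, rows summing to 1).
#' @export
predict.softmax_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  Z <- cbind(1, as.matrix(newdata)) %*% object$weights
  Z <- exp(Z - apply(Z, 1L, max))
  P <- Z / rowSums(Z)
  colnames(P) <- object$labels
  list(labels = object$labels[max.col(P, ties.method = "first")], probs = P)
}

#' Classify an image file or pixel array
#'
#' Embeds the image with the backbone and applies the retrained softmax layer.
#'
#' @param model A `softmax_model`.
#' @param backbone The `imu_backbone` the model was trained over.
#' @param image Image path or `h x w x 3` pixel array.
#' @return List with `label` and named `probs`.
#' @export
classify_image <- function(model, backbone, image) {
  stopifnot(inherits(model, "softmax_model"), inherits(backbone, "imu_backbone"))
  px <- if (is.character(image)) read_image(image) else image
  p <- predict(model, backbone$embed(px))
  list(label = p$labels[1L], probs = p$probs[1L, ])
}

#' Save / load a trained model
#'
#' The on-disk artifact mirrors the two-file convention of image-retraining
#' workflows: a plain-text weights table (`weights.csv`) and a label list
#' (`labels.txt`, one label per line), plus the backbone name.
#'
#' @param model A `softmax_model`.
#' @param dir Output directory.
#' @return `write_model()` returns `dir` invisibly; `read_model()` the model.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "softmax_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(model$weights),
                   file.path(dir, "weights.csv"), row.names = FALSE)
  writeLines(model$labels, file.path(dir, "labels.txt"))
  writeLines(model$backbone, file.path(dir, "backbone.txt"))
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  w <- as.matrix(utils::read.csv(file.path(dir, "weights.csv")))
  dimnames(w) <- NULL
  structure(list(backbone = readLines(file.path(dir, "backbone.txt"))[1L],
                 weights = w,
                 labels = readLines(file.path(dir, "labels.txt"))),
            class = "softmax_model")
}
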