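# A small labeled image tree: `per_class` images in each of `classes`, with
# strongly class-distinct waveforms and mild per-repetition variation.
make_image_tree <- function(dir, classes = exercise_labels(), per_class = 2,
                            side = 96) {
  reps <- list()
  for (cl in classes) for (k in seq_len(per_class)) {
    r <- make_toy_repetition(label = cl, subject = "S01", rep_index = k)
    ci <- match(cl, exercise_labels())
    tau <- seq(0, 1, length.out = length(r$channels$gyro_x))
    jit <- 1 + 0.05 * k
    r$channels$gyro_x <- 200 * jit * sin(pi * tau * ci)
    r$channels$gyro_y <- 80 * jit * cos(pi * tau * ci)
    r$channels$gyro_z <- 60 * jit * sin(2 * pi * tau + ci)
    r$channels$acc_y <- -10 * jit * sin(pi * tau)^ci
    reps[[length(reps) + 1L]] <- r
  }
  write_image_dataset(reps, dir, plot_spec(image_side = side, format = "png"))
}

test_that("bottleneck computation counts images and labels correctly", {
  dir <- withr::local_tempdir()
  make_image_tree(dir, per_class = 2)
  bb <- tiny_cnn_backbone(seed = 1)
  b <- compute_bottlenecks(dir, bb)
  expect_equal(nrow(b$embeddings), 10L)
  expect_equal(ncol(b$embeddings), bb$embed_dim)
  expect_setequal(unique(b$labels), exercise_labels())
  expect_equal(b$cache_hits, 0L)
  # warm cache: everything served from disk, values unchanged
  b2 <- compute_bottlenecks(dir, bb)
  expect_equal(b2$cache_hits, 10L)
  expect_equal(b2$embeddings, b$embeddings, tolerance = 1e-12)
})

test_that("identical image bytes give identical embeddings across classes", {
  dir <- withr::local_tempdir()
  make_image_tree(dir, classes = c("SQ", "DL"), per_class = 1)
  f_sq <- list.files(file.path(dir, "SQ"), full.names = TRUE)[1]
  file.copy(f_sq, file.path(dir, "DL", basename(f_sq)), overwrite = TRUE)
  b <- compute_bottlenecks(dir, tiny_cnn_backbone(seed = 1), cache_dir = NULL)
  dup <- which(basename(b$files) == basename(f_sq))
  expect_length(dup, 2L)
  expect_identical(b$embeddings[dup[1], ], b$embeddings[dup[2], ])
})

test_that("an empty class folder is a dataset error naming the folder", {
  dir <- withr::local_tempdir()
  make_image_tree(dir, classes = c("SQ", "DL"), per_class = 1)
  dir.create(file.path(dir, "TJ"))
  expect_error(compute_bottlenecks(dir, tiny_cnn_backbone(seed = 1)), "TJ")
})

test_that("the backbone is deterministic and seed-identified", {
  px <- render_repetition(make_toy_repetition(), plot_spec(image_side = 96))$pixels
  b1 <- tiny_cnn_backbone(seed = 7)
  b2 <- tiny_cnn_backbone(seed = 7)
  b3 <- tiny_cnn_backbone(seed = 8)
  expect_identical(b1$embed(px), b2$embed(px))
  expect_false(identical(b1$embed(px), b3$embed(px)))
  expect_equal(sum(b1$embed(px)^2), 1, tolerance = 1e-9)  # L2-normalised
})

separable_embeddings <- function(n_per = 30, d = 8, gap = 6, seed = 3) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * d), n_per),
             matrix(stats::rnorm(n_per * d, mean = gap), n_per))
  list(X = X, y = rep(c("A", "B"), each = n_per))
}

test_that("the retrained softmax layer fits separable embeddings", {
  se <- separable_embeddings()
  fit <- retrain_final_layer(se$X, se$y, train_config(steps = 200, seed = 1))
  last <- fit$curves[nrow(fit$curves), ]
  expect_equal(last$train_accuracy, 1.0)
  p <- predict(fit$model, se$X)
  expect_true(all(abs(rowSums(p$probs) - 1) < 1e-6))
  expect_true(all(p$probs >= 0 & p$probs <= 1))
  expect_equal(p$labels, se$y)
})

test_that("cross entropy falls from first to final step across 5 seeds", {
  se <- separable_embeddings()
  for (s in 1:5) {
    fit <- retrain_final_layer(se$X, se$y, train_config(steps = 150, seed = s))
    expect_lt(fit$curves$cross_entropy[nrow(fit$curves)],
              fit$curves$cross_entropy[1], label = sprintf("seed %d", s))
  }
})

test_that("fixed seeds give identical training curves", {
  se <- separable_embeddings()
  f1 <- retrain_final_layer(se$X, se$y, train_config(steps = 100, seed = 9))
  f2 <- retrain_final_layer(se$X, se$y, train_config(steps = 100, seed = 9))
  expect_identical(f1$curves, f2$curves)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_true(all(f1$curves$train_accuracy >= 0 & f1$curves$train_accuracy <= 1))
  expect_true(all(f1$curves$cross_entropy >= 0))
})

test_that("degenerate configurations are rejected", {
  se <- separable_embeddings(n_per = 2)
  expect_error(retrain_final_layer(se$X, rep("A", 4), train_config(steps = 5)),
               "2 classes")
  expect_error(train_config(validation_fraction = 0))
  expect_error(train_config(steps = 0))
})

test_that("batch prediction equals per-image prediction", {
  dir <- withr::local_tempdir()
  make_image_tree(dir, per_class = 2)
  bb <- tiny_cnn_backbone(seed = 1)
  b <- compute_bottlenecks(dir, bb, cache_dir = NULL)
  fit <- retrain_final_layer(b$embeddings, b$labels,
                             train_config(steps = 150, seed = 2))
  batch <- predict(fit$model, b$embeddings)
  for (i in seq_along(b$files)) {
    single <- classify_image(fit$model, bb, b$files[i])
    expect_equal(single$label, batch$labels[i])
    expect_equal(unname(single$probs), unname(batch$probs[i, ]), tolerance = 1e-9)
  }
  # training images of well-separated classes get their own label back
  expect_gt(mean(batch$labels == b$labels), 0.9)
})

test_that("models round-trip through the two-file artifact", {
  se <- separable_embeddings()
  fit <- retrain_final_layer(se$X, se$y, train_config(steps = 50, seed = 4))
  dir <- withr::local_tempdir()
  write_model(fit$model, dir)
  expect_true(file.exists(file.path(dir, "labels.txt")))
  back <- read_model(dir)
  expect_equal(back$labels, fit$model$labels)
  expect_equal(back$weights, fit$model$weights, tolerance = 1e-12)
  p1 <- predict(fit$model, se$X)
  p2 <- predict(back, se$X)
  expect_equal(p1$labels, p2$labels)
})
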