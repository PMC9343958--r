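test_that("model configuration enforces the three-branch topology", {
  expect_error(model_config(branches = list(branch_spec(), branch_spec())),
               "3 branches")
  expect_error(model_config(branches = list(branch_spec(kernel_len = 300),
                                            branch_spec(), branch_spec()),
                            input_shape = c(256, 2)), "longer than input")
  expect_error(branch_spec(dropout = 1), "dropout")
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("forward pass emits valid probability distributions", {
  m <- build_model(tiny_model_config(), seed = 2)
  wm <- structure(list(windows = array(0, c(3, 256, 2)),
                       labels = rep("a", 3), groups = rep("g", 3),
                       class_order = letters[1:4], fs = 512),
                  class = "window_matrix")
  pr <- predict(m, wm)
  expect_equal(rowSums(pr$probs), rep(1, 3), tolerance = 1e-6)
  # random and extreme inputs stay valid distributions
  set.seed(9)
  wm$windows <- array(rnorm(3 * 256 * 2, sd = 100), c(3, 256, 2))
  pr <- predict(m, wm)
  expect_true(all(pr$probs >= 0))
  expect_equal(rowSums(pr$probs), rep(1, 3), tolerance = 1e-6)
  # empty input -> empty output, no error
  pr0 <- predict(m, subset_windows(wm, integer(0)))
  expect_length(pr0$labels, 0)
  expect_equal(nrow(pr0$probs), 0)
  # shape mismatch is a labelled error
  bad <- structure(list(windows = array(0, c(2, 128, 2)), labels = c("a", "a"),
                        groups = c("g", "g"), class_order = letters[1:4],
                        fs = 512), class = "window_matrix")
  expect_error(predict(m, bad), "does not match")
})

test_that("parameter count equals the closed-form oracle", {
  expect_equal(n_parameters(build_model(model_config(), seed = 1)),
               oracle_param_count(model_config()))
  set.seed(55)
  for (i in 1:5) {
    cfg <- model_config(
      branches = lapply(sample(3:40, 3), function(k)
        branch_spec(n_filters = sample(4:24, 1), kernel_len = k,
                    pool_len = sample(2:6, 1))),
      dense_sizes = sample(4:48, sample(2:4, 1)),
      n_classes = sample(2:6, 1),
      input_shape = c(sample(c(128, 200, 256), 1), sample(1:3, 1)))
    expect_equal(n_parameters(build_model(cfg, seed = i)),
                 oracle_param_count(cfg))
  }
})

test_that("branch convolution agrees with a direct R implementation", {
  set.seed(7)
  x <- array(rnorm(2 * 20 * 2), c(20, 2, 2))      # (len, ch, items)
  w <- array(rnorm(3 * 2 * 4), c(3, 2, 4))        # (klen, ch, filters)
  b <- rnorm(4)
  out <- sweetEEG:::cpp_branch_forward(x, w, b, 1L, FALSE)$feat
  out_len <- 20 - 3 + 1
  for (item in 1:2)
    for (f in 1:4)
      for (t in 1:out_len) {
        acc <- b[f]
        for (ch in 1:2) acc <- acc + sum(x[t:(t + 2), ch, item] * w[, ch, f])
        expect_equal(out[item, t + (f - 1) * out_len], max(0, acc),
                     tolerance = 1e-12)
      }
})

test_that("training learns separable classes and keeps honest books", {
  m <- tiny_trained()
  expect_true(m$trained)
  expect_equal(nrow(m$history), 35)
  # learnable data: final training loss below initial
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  expect_gt(tail(m$history$train_acc, 1), 0.9)
  # predictions on the training set agree with the recorded final accuracy
  # (history metrics are computed with dropout off)
  sp <- tiny_split()
  pred <- predict(m, sp$train)
  expect_equal(mean(pred$labels == sp$train$labels),
               tail(m$history$train_acc, 1), tolerance = 0.02)
  # epochs = 1 -> exactly one history row
  m1 <- train_cnn(build_model(tiny_model_config(), seed = 1), tiny_split(),
                  train_config(epochs = 1, seed = 3))
  expect_equal(nrow(m1$history), 1)
  # empty training set is a labelled error
  empty <- list(train = subset_windows(sp$train, integer(0)), test = sp$test)
  expect_error(train_cnn(build_model(tiny_model_config()), empty), "empty")
})

test_that("training is reproducible under a fixed seed", {
  tc <- train_config(epochs = 2, seed = 21)
  m1 <- train_cnn(build_model(tiny_model_config(), seed = 1), tiny_split(), tc)
  m2 <- train_cnn(build_model(tiny_model_config(), seed = 99), tiny_split(), tc)
  # tc$seed drives re-initialization, so the build seed must not matter
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$dense[[1]]$W, m2$params$dense[[1]]$W)
})

test_that("training is label-permutation invariant up to loose tolerance", {
  sp <- tiny_split()
  perm <- c(water = "sucrose", sucrose = "water",
            aspartame = "sucralose", sucralose = "aspartame")
  relabel <- function(wm) {
    wm$labels <- unname(perm[wm$labels])
    wm$class_order <- unname(perm[wm$class_order])
    wm
  }
  sp2 <- sp
  sp2$train <- relabel(sp2$train)
  sp2$test <- relabel(sp2$test)
  tc <- train_config(epochs = 12, seed = 33)
  a1 <- tail(train_cnn(build_model(tiny_model_config()), sp, tc)$history$val_acc, 1)
  a2 <- tail(train_cnn(build_model(tiny_model_config()), sp2, tc)$history$val_acc, 1)
  expect_lt(abs(a1 - a2), 0.2)
})

test_that("band-power baseline separates band-coded classes, not chance data", {
  rep <- bandpower_baseline(tiny_split())
  acc <- attr(rep, "micro_accuracy")
  expect_gt(acc, 0.9)
  # a single 8-40 Hz band cannot separate classes of equal total band power
  rep1 <- bandpower_baseline(tiny_split(), bands = list(c(8, 40)))
  expect_lt(attr(rep1, "micro_accuracy"), 0.5)
  # null data: accuracy within the binomial 99% CI of chance
  null_split <- memo("tiny_null_split", {
    rs <- generate_dataset(tiny_synth_config(effect_size = 0, seed = 77))
    pp <- preprocess(rs, tiny_preprocess_config(), screen = FALSE)
    split_windows(pp$wm, 0.7, "group", seed = 5)
  })
  # at this tiny scale (5 test recordings) window-level CIs are invalid
  # because windows cluster by recording; the calibrated CI check lives in
  # the acceptance suite at the 132-recording scale. Sanity bound only:
  rep0 <- bandpower_baseline(null_split)
  expect_lt(attr(rep0, "micro_accuracy"), 0.5)
  expect_error(bandpower_baseline(tiny_split(), bands = list()), "empty band")
  expect_error(bandpower_baseline(tiny_split(), bands = list(c(8, 400))),
               "outside")
})
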