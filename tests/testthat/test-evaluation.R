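test_that("confusion counts true-by-predicted cells", {
  cm <- confusion(c("w", "w", "s"), c("w", "s", "s"), c("w", "s"))
  expect_equal(unclass(cm),
               matrix(c(1L, 0L, 1L, 1L), 2, 2,
                      dimnames = list(true = c("w", "s"),
                                      predicted = c("w", "s"))))
  # perfect predictions -> diagonal with row totals
  y <- rep(c("a", "b", "c"), times = c(5, 2, 3))
  cmd <- confusion(y, y, c("a", "b", "c"))
  expect_equal(diag(cmd), c(a = 5L, b = 2L, c = 3L))
  expect_equal(sum(cmd) - sum(diag(cmd)), 0L)
  # degenerate and invalid inputs
  expect_equal(sum(confusion(character(0), character(0), c("a", "b"))), 0L)
  expect_error(confusion("a", "z", c("a", "b")), "unknown label")
  expect_error(confusion(c("a", "a"), "a", c("a")), "length")
})

test_that("binarize recovers one-vs-rest counts from the reference matrix", {
  cm <- reconstruct_paper_cm()
  w <- binarize(cm, "water")
  expect_equal(w, list(TP = 104L, FP = 8L, TN = 519L, FN = 51L))
  expect_equal(binarize(cm, "sucralose")$FN, 0L)
  expect_equal(with(w, TP + FP + TN + FN), sum(cm))
  # diagonal matrix: no confusion
  d <- confusion(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(binarize(d, "a")[c("FP", "FN")], list(FP = 0L, FN = 0L))
  expect_error(binarize(cm, "stevia"), "unknown class")
})

test_that("reference matrix satisfies the published row structure", {
  cm <- reconstruct_paper_cm()
  expect_equal(unname(rowSums(cm)), c(155, 155, 186, 186))
  expect_equal(sum(cm), 682)
  expect_equal(sum(diag(cm)), 440)
  # counting identities: sum of per-class TP = trace; TP+FN sums to total
  tps <- vapply(rownames(cm), function(cl) binarize(cm, cl)$TP, integer(1))
  expect_equal(sum(tps), sum(diag(cm)))
  poss <- vapply(rownames(cm), function(cl) {
    b <- binarize(cm, cl); b$TP + b$FN
  }, integer(1))
  expect_equal(sum(poss), sum(cm))
})

test_that("metrics reproduce the published per-class table and macros", {
  rep <- cm_metrics(reconstruct_paper_cm())
  published <- rbind(
    water = c(0.9135, 0.9286, 0.6710, 0.7790),
    sucrose = c(0.8123, 0.8857, 0.2000, 0.3263),
    aspartame = c(0.8138, 0.6648, 0.6398, 0.6521),
    sucralose = c(0.7507, 0.5225, 1.0000, 0.6863))
  got <- as.matrix(as.data.frame(rep)[, c("accuracy", "precision", "recall", "f1")])
  expect_equal(unname(round(got, 4)), unname(published))
  macro <- attr(rep, "macro")
  expect_equal(unname(round(macro, 3)),
               c(0.823, 0.750, 0.628, 0.611))
  # micro accuracy is trace/total and differs from the one-vs-rest mean
  expect_equal(attr(rep, "micro_accuracy"), 440 / 682)
  expect_false(isTRUE(all.equal(attr(rep, "micro_accuracy"),
                                unname(macro["accuracy"]))))
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(202)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 8), k, k,
                 dimnames = list(true = letters[1:k], predicted = letters[1:k]))
    rep <- cm_metrics(cm)
    expect_true(all(as.data.frame(rep)[, 2:5] >= 0 &
                    as.data.frame(rep)[, 2:5] <= 1))
    for (j in seq_len(k)) {
      p <- rep$precision[j]; r <- rep$recall[j]
      if (p + r > 0) expect_equal(rep$f1[j], 2 * p * r / (p + r))
      else expect_equal(rep$f1[j], 0)
    }
    expect_equal(unname(attr(rep, "macro")["f1"]), mean(rep$f1))
  }
  # all-correct matrix: every metric 1
  perf <- cm_metrics(confusion(c("a", "b"), c("a", "b"), c("a", "b")))
  expect_true(all(as.data.frame(perf)[, 2:5] == 1))
  # never-predicted class: precision 0 by convention, f1 0
  cm0 <- confusion(c("a", "b", "b"), c("b", "b", "b"), c("a", "b"))
  expect_equal(cm_metrics(cm0)$precision[1], 0)
  expect_equal(cm_metrics(cm0)$f1[1], 0)
  expect_error(cm_metrics(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "zero total")
})

test_that("grand averages reflect the onset envelope and class symmetry", {
  cfg <- synth_config(n_subjects = 6, n_sessions_per_subject = 1,
                      effect_size = 4, seed = 53)
  rs <- generate_dataset(cfg)
  ga <- grand_average(rs)
  expect_equal(names(ga), c("time", cfg$classes))
  expect_equal(nrow(ga), 8192)
  # activity rises after onset then decays
  early <- colMeans(ga[ga$time >= 1 & ga$time < 2, cfg$classes])
  late <- colMeans(ga[ga$time >= 15, cfg$classes])
  expect_true(all(early > late))
  # a class of identical recordings averages to that recording's trace
  rs1 <- rs
  rs1$recordings <- rs$recordings[c(1, 1, 1)]
  ga1 <- grand_average(rs1, classes = rs$recordings[[1]]$stimulus)
  filt <- bandpass(rs$recordings[[1]])
  expect_equal(ga1[[2]], colMeans(abs(filt$samples)))
  expect_error(grand_average(rs, classes = "stevia"), "no recordings")
})

test_that("identically generated classes give equal traces within tolerance", {
  # same spectral profile for two labels: exchangeable by construction
  prof <- list(water = cbind(16, 4, 1), sucrose = cbind(16, 4, 1),
               aspartame = cbind(16, 4, 1), sucralose = cbind(16, 4, 1))
  cfg <- synth_config(n_subjects = 40, n_sessions_per_subject = 1,
                      duration_s = 4, class_profiles = prof,
                      effect_size = 2, seed = 59)
  rs <- generate_dataset(cfg)
  ga <- grand_average(rs, classes = c("water", "sucrose"))
  rel <- abs(mean(ga$water) - mean(ga$sucrose)) / mean(ga$water)
  expect_lt(rel, 0.05)
})
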