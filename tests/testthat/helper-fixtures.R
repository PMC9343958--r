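# Shared fixtures, built once per test run and memoized.
#
# `tiny_*` objects use 4-s recordings and 256-sample windows so that model
# tests run in seconds; they exercise the same code paths as the full-size
# defaults (and deliberately use non-default shapes).

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

tiny_synth_config <- function(effect_size = 6, seed = 42) {
  synth_config(n_subjects = 2, n_sessions_per_subject = 2,
               duration_s = 4, effect_size = effect_size, seed = seed)
}

tiny_preprocess_config <- function() {
  preprocess_config(window_len = 256, stride_s = 0.25)
}

tiny_model_config <- function() {
  model_config(input_shape = c(256, 2))
}

# 16 recordings, 240 windows of 256 x 2, strongly separable classes.
# Screening is off: at effect size 6 the legitimate oscillation itself can
# exceed the 100-uV artifact threshold.
tiny_split <- function() {
  memo("tiny_split", {
    rs <- generate_dataset(tiny_synth_config())
    pp <- preprocess(rs, tiny_preprocess_config(), screen = FALSE)
    split_windows(pp$wm, 0.7, "group", seed = 5)
  })
}

tiny_trained <- function() {
  memo("tiny_trained", {
    m <- build_model(tiny_model_config(), seed = 1)
    train_cnn(m, tiny_split(), train_config(epochs = 35, seed = 9))
  })
}

# Independent brute-force window-count oracle: accumulate start positions
# one by one (never uses the package's vectorized closed form).
oracle_window_count <- function(n, window_len, stride_samples) {
  k <- 0; count <- 0
  repeat {
    s <- floor(k * stride_samples + 1e-9)
    if (s + window_len <= n) { count <- count + 1; k <- k + 1 } else break
  }
  count
}

# Independent closed-form parameter-count oracle, written layer by layer
# from the topology description (kept free of the package's own helpers).
oracle_param_count <- function(cfg) {
  len <- cfg$input_shape[1]; nch <- cfg$input_shape[2]
  conv <- sum(vapply(cfg$branches, function(b)
    (b$kernel_len * nch + 1) * b$n_filters, numeric(1)))
  d0 <- sum(vapply(cfg$branches, function(b)
    ((len - b$kernel_len + 1) %/% b$pool_len) * b$n_filters, numeric(1)))
  sizes <- c(d0, cfg$dense_sizes, cfg$n_classes)
  dense <- sum((sizes[-length(sizes)] + 1) * sizes[-1])
  conv + dense
}
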