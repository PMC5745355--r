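# Shared fixtures built in code. The full-size corpus and model are
# trained once per test run and reused by every test that needs them.

.fixture_cache <- new.env(parent = emptyenv())

full_corpus <- function() {
  if (is.null(.fixture_cache$corpus)) {
    .fixture_cache$corpus <-
      simulate_training_windows(10000, sim_config(), seed = 11)
  }
  .fixture_cache$corpus
}

full_model <- function() {
  if (is.null(.fixture_cache$model)) {
    .fixture_cache$model <- train_gesture_model(full_corpus(), seed = 3)
  }
  .fixture_cache$model
}

# tiny linearly separable corpus: class 1 offset by +5 m/s^2 on the
# y-axis block; n_in features (multiple of 3)
separable_corpus <- function(n = 200, n_in = 30, seed = 5) {
  withr::with_seed(seed, {
    w <- n_in / 3
    base <- matrix(rnorm(n * n_in, sd = 0.5), n, n_in)
    base[, 2 * w + 1:w] <- base[, 2 * w + 1:w] + 9.81
    label <- rep(c(0L, 1L), length.out = n)
    base[label == 1L, w + 1:w] <- base[label == 1L, w + 1:w] + 5
    tibble::tibble(features = base, label = label)
  })
}

# hand-assembled model whose forward pass can be verified by arithmetic
toy_model <- function(w1, b1, w2, b2, threshold = 0.85) {
  structure(
    list(
      w1 = w1, b1 = b1, w2 = w2, b2 = b2, threshold = threshold,
      seed = 0L, scaling = NULL, n_in = nrow(w1), hidden = ncol(w1),
      loss = NA_real_, convergence = 0L, n_train = 0L, n_holdout = 0L,
      holdout_accuracy = NA_real_
    ),
    class = "gesture_model"
  )
}

# model with 300 inputs whose output is pinned by the output bias
constant_model <- function(bias, threshold = 0.85) {
  toy_model(matrix(0, 300, 10), numeric(10), numeric(10), bias, threshold)
}
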