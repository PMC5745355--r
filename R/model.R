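#' Train the two-layer gesture classifier
#'
#' Fits a 300-10-1 feed-forward network (logistic sigmoid on both layers)
#' that scores a 5-second accelerometer window for the hand-to-mouth puff
#' gesture. Training minimises L2-regularised cross-entropy by full-batch
#' L-BFGS from a seeded random initialisation, so the fitted weights are
#' reproducible given the same data and seed. A stratified holdout split
#' is carved off before fitting and its per-window accuracy stored on the
#' model. Features are standardised per axis (x, y, z blocks) using
#' training-split statistics kept in the model, since raw magnitudes
#' differ with gravity orientation.
#'
#' @param windows Tibble of labelled windows: a `features` matrix column
#'   (one row per window, `3 * window_samples` columns) and a `label`
#'   column of 0/1 (1 = smoking gesture). Both labels must be present.
#' @param seed Integer seed controlling the holdout split and weight
#'   initialisation.
#' @param hidden Number of hidden neurons.
#' @param threshold Score threshold in (0, 1) above which a window is
#'   called a smoking gesture when classifying streams.
#' @param holdout Fraction of windows held out (stratified) for the
#'   accuracy estimate.
#' @param max_iter Maximum L-BFGS iterations.
#' @param decay L2 penalty on the weights.
#' @param standardize Standardise features per axis before fitting.
#' @return A `gesture_model` object; see [glance.gesture_model()].
#' @export
train_gesture_model <- function(windows, seed = 1, hidden = 10,
                                threshold = 0.85, holdout = 0.2,
                                max_iter = 400, decay = 1e-4,
                                standardize = TRUE) {
  x <- windows$features
  y <- as.numeric(windows$label)
  if (!is.matrix(x)) abort("windows$features must be a matrix column")
  if (any(!y %in% c(0, 1))) abort("labels must be 0 or 1")
  if (length(unique(y)) < 2) abort("training data must contain both labels")
  if (ncol(x) %% 3 != 0) abort("feature count must be a multiple of 3 (x, y, z blocks)")
  n_in <- ncol(x)

  withr::with_seed(as.integer(seed), {
    test_idx <- stratified_holdout(y, holdout)
    train_idx <- setdiff(seq_along(y), test_idx)

    scaling <- if (standardize) axis_scaling(x[train_idx, , drop = FALSE]) else NULL
    xs <- apply_scaling(x, scaling)

    r1 <- sqrt(6 / (n_in + hidden))
    r2 <- sqrt(6 / (hidden + 1))
    theta0 <- c(
      runif(n_in * hidden, -r1, r1), numeric(hidden),
      runif(hidden, -r2, r2), 0
    )

    xtr <- xs[train_idx, , drop = FALSE]
    ytr <- y[train_idx]
    fit <- optim(
      theta0,
      fn = function(th) mlp_loss(th, xtr, ytr, n_in, hidden, decay),
      gr = function(th) mlp_grad(th, xtr, ytr, n_in, hidden, decay),
      method = "L-BFGS-B",
      control = list(maxit = max_iter, factr = 1e7)
    )
    wts <- unpack_weights(fit$par, n_in, hidden)
  })

  model <- structure(
    list(
      w1 = wts$w1, b1 = wts$b1, w2 = wts$w2, b2 = wts$b2,
      threshold = threshold, seed = as.integer(seed),
      scaling = scaling, n_in = n_in, hidden = hidden,
      loss = fit$value, convergence = fit$convergence,
      n_train = length(train_idx), n_holdout = length(test_idx),
      holdout_accuracy = NA_real_
    ),
    class = "gesture_model"
  )
  pr <- score_matrix(model, x[test_idx, , drop = FALSE])
  model$holdout_accuracy <- mean((pr > 0.5) == (y[test_idx] == 1))
  model
}

# indices of a stratified holdout: round(frac) of each class
stratified_holdout <- function(y, frac) {
  unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(frac * length(idx))))
  }), use.names = FALSE)
}

# pooled mean/sd per axis block, applied blockwise
axis_scaling <- function(x) {
  w <- ncol(x) / 3
  blocks <- list(1:w, w + 1:w, 2 * w + 1:w)
  list(
    center = vapply(blocks, function(b) mean(x[, b]), numeric(1)),
    scale = vapply(blocks, function(b) max(stats::sd(as.numeric(x[, b])), 1e-8),
                   numeric(1))
  )
}

apply_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  w <- ncol(x) / 3
  for (k in 1:3) {
    cols <- (k - 1) * w + 1:w
    x[, cols] <- (x[, cols] - scaling$center[k]) / scaling$scale[k]
  }
  x
}

unpack_weights <- function(theta, n_in, hidden) {
  i <- 0
  w1 <- matrix(theta[i + seq_len(n_in * hidden)], n_in, hidden); i <- i + n_in * hidden
  b1 <- theta[i + seq_len(hidden)]; i <- i + hidden
  w2 <- theta[i + seq_len(hidden)]; i <- i + hidden
  b2 <- theta[i + 1]
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_forward <- function(theta, x, n_in, hidden) {
  w <- unpack_weights(theta, n_in, hidden)
  h <- sigmoid(sweep(x %*% w$w1, 2, w$b1, `+`))
  p <- sigmoid(drop(h %*% w$w2) + w$b2)
  list(h = h, p = p, w = w)
}

mlp_loss <- function(theta, x, y, n_in, hidden, decay) {
  fw <- mlp_forward(theta, x, n_in, hidden)
  p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
  ce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  ce + decay * (sum(fw$w$w1^2) + sum(fw$w$w2^2))
}

mlp_grad <- function(theta, x, y, n_in, hidden, decay) {
  fw <- mlp_forward(theta, x, n_in, hidden)
  n <- nrow(x)
  d2 <- (fw$p - y) / n                      # d loss / d output preactivation
  gw2 <- drop(crossprod(fw$h, d2)) + 2 * decay * fw$w$w2
  gb2 <- sum(d2)
  d1 <- (d2 %o% fw$w$w2) * fw$h * (1 - fw$h)
  gw1 <- crossprod(x, d1) + 2 * decay * fw$w$w1
  gb1 <- colSums(d1)
  c(as.numeric(gw1), gb1, gw2, gb2)
}

# forward pass on raw (unscaled) feature rows
score_matrix <- function(model, x) {
  x <- apply_scaling(x, model$scaling)
  h <- sigmoid(sweep(x %*% model$w1, 2, model$b1, `+`))
  drop(sigmoid(drop(h %*% model$w2) + model$b2))
}

#' Score gesture windows with a trained model
#'
#' Appends a `score` column — the network's probability in \[0, 1\] that
#' the window contains a smoking gesture — to a window tibble.
#'
#' @param windows Tibble from [gesture_windows()] (a `features` matrix
#'   column with the model's feature count).
#' @param model A [train_gesture_model()] fit.
#' @return `windows` with a `score` column.
#' @export
score_windows <- function(windows, model) {
  check_feature_count(model, windows$features)
  dplyr::mutate(windows, score = score_matrix(model, windows$features))
}

check_feature_count <- function(model, x) {
  if (!is.matrix(x) || ncol(x) != model$n_in) {
    abort(sprintf("expected %d features per window, got %s",
                  model$n_in, if (is.matrix(x)) ncol(x) else "a non-matrix"))
  }
  invisible(TRUE)
}

#' Classify every sample of a trace as gesture / non-gesture
#'
#' Scores 5-second rolling windows at stride 1 and assigns each window's
#' thresholded decision to its centre sample, producing a per-sample 0/1
#' gesture stream aligned with the trace. Edge samples that are not the
#' centre of any full window inherit the nearest valid window's decision.
#' Scoring is chunked so arbitrarily long traces never materialise the
#' full window matrix.
#'
#' @param trace An [accel_trace], normally already smoothed with
#'   [lowpass()].
#' @param model A [train_gesture_model()] fit.
#' @param window_s Window length in seconds (must match the model's
#'   feature count).
#' @param chunk Number of windows scored per chunk.
#' @return Integer vector of 0/1, one per trace sample.
#' @export
classify_stream <- function(trace, model, window_s = 5, chunk = 20000L) {
  fs <- trace_fs(trace)
  n <- nrow(trace)
  if (n == 0) return(integer(0))
  w <- as.integer(round(window_s * fs))
  if (3L * w != model$n_in) {
    abort(sprintf("window of %d samples gives %d features but model expects %d",
                  w, 3 * w, model$n_in))
  }
  if (n < w) abort("trace is shorter than one window")
  starts <- seq.int(1L, n - w + 1L)
  decisions <- logical(length(starts))
  for (lo in seq.int(1L, length(starts), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(starts))
    feats <- window_matrix(trace$x, trace$y, trace$z, starts[lo:hi], w)
    decisions[lo:hi] <- score_matrix(model, feats) > model$threshold
  }
  centers <- starts + w %/% 2L
  stream <- integer(n)
  stream[centers] <- as.integer(decisions)
  stream[seq_len(centers[1] - 1L)] <- stream[centers[1]]
  last <- centers[length(centers)]
  if (last < n) stream[(last + 1L):n] <- stream[last]
  stream
}

#' Serialise a gesture model to JSON
#'
#' Weights, biases, threshold, seed and scaling constants are written as
#' a JSON document at full double precision, so a model round-trips
#' losslessly through [read_gesture_model()].
#'
#' @param model A `gesture_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gesture_model <- function(model, path) {
  payload <- unclass(model)
  payload$w1 <- as.numeric(payload$w1) # column-major; shape restored on read
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_gesture_model
#' @export
read_gesture_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$w1 <- matrix(payload$w1, payload$n_in, payload$hidden)
  if (length(payload$scaling) == 0) payload$scaling <- NULL
  payload$holdout_accuracy <- payload$holdout_accuracy %||% NA_real_
  structure(payload, class = "gesture_model")
}

#' @export
print.gesture_model <- function(x, ...) {
  cat(sprintf(
    "<gesture_model> %d-%d-1 sigmoid network, threshold %.2f\n",
    x$n_in, x$hidden, x$threshold
  ))
  cat(sprintf(
    "  trained on %d windows (seed %d); holdout accuracy %.1f%% on %d windows\n",
    x$n_train, x$seed, 100 * x$holdout_accuracy, x$n_holdout
  ))
  invisible(x)
}

#' Tidy and glance methods for gesture models
#'
#' `tidy()` returns one row per weight (layer, unit, input term,
#' estimate); `glance()` returns a one-row model summary.
#'
#' @param x A `gesture_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gesture_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble(
      layer = "hidden",
      unit = rep(seq_len(x$hidden), each = x$n_in + 1),
      term = rep(c(paste0("in", seq_len(x$n_in)), "(bias)"), times = x$hidden),
      estimate = as.numeric(rbind(x$w1, x$b1))
    ),
    tibble(
      layer = "output", unit = 1L,
      term = c(paste0("h", seq_len(x$hidden)), "(bias)"),
      estimate = c(x$w2, x$b2)
    )
  )
}

#' @rdname tidy.gesture_model
#' @export
glance.gesture_model <- function(x, ...) {
  tibble(
    n_input = x$n_in, n_hidden = x$hidden, threshold = x$threshold,
    seed = x$seed, n_train = x$n_train, n_holdout = x$n_holdout,
    holdout_accuracy = x$holdout_accuracy, loss = x$loss,
    converged = x$convergence == 0
  )
}
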