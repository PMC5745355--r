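#' Timing parameters of the smoking-session model
#'
#' The rule layer interprets a per-sample gesture stream under a
#' five-parameter model of how a cigarette is smoked: a puff (raise,
#' inhale, lower) lasts more than `min_puff_s`; two puffs of the same
#' cigarette are separated by a rest between `min_gap_s` and `max_gap_s`;
#' a session holds at least `min_puffs` puffs and spans at most
#' `max_session_s` from the first puff's start to the last puff's end.
#' The session-duration cap takes precedence over the other rules: an
#' over-long run of otherwise valid puffs is split into several sessions
#' (chain-smoking).
#'
#' @param min_puff_s Minimum puff duration in seconds (exclusive bound).
#' @param min_gap_s Rest below which two adjacent gesture runs are the
#'   same puff, incorrectly split.
#' @param max_gap_s Rest above which two adjacent puffs belong to
#'   different sessions.
#' @param min_puffs Minimum puffs per session.
#' @param max_session_s Maximum session span in seconds.
#' @return A `session_params` list.
#' @export
#' @examples
#' session_params() # the default smoking-session model
session_params <- function(min_puff_s = 0.75, min_gap_s = 2.5,
                           max_gap_s = 240, min_puffs = 3,
                           max_session_s = 480) {
  if (min_puff_s <= 0) abort("min_puff_s must be positive")
  if (min_gap_s <= 0 || min_gap_s >= max_gap_s) {
    abort("need 0 < min_gap_s < max_gap_s")
  }
  if (min_puffs < 1) abort("min_puffs must be at least 1")
  if (max_session_s <= 0) abort("max_session_s must be positive")
  structure(
    list(
      min_puff_s = min_puff_s, min_gap_s = min_gap_s, max_gap_s = max_gap_s,
      min_puffs = as.integer(min_puffs), max_session_s = max_session_s
    ),
    class = "session_params"
  )
}

#' Extract puff events from a binary gesture stream
#'
#' Takes maximal runs of 1s as candidate puffs, merges adjacent
#' candidates whose separating rest is shorter than `min_gap_s` (they are
#' one puff that the classifier incorrectly split), then rejects any
#' merged candidate not longer than `min_puff_s`. Merging precedes the
#' duration filter so that fragments are reunited before their length is
#' judged. Run boundaries are converted to seconds via `fs`: a run over
#' samples \[i, j\] spans \[(i-1)/fs, j/fs).
#'
#' @param stream Integer/logical vector of per-sample 0/1 decisions.
#' @param fs Sampling frequency in Hz.
#' @param params A [session_params()] object.
#' @return Tibble of disjoint, sorted puffs with columns
#'   `start_s`, `end_s`.
#' @export
stream_to_puffs <- function(stream, fs = 20, params = session_params()) {
  if (is.logical(stream)) stream <- as.integer(stream)
  if (length(stream) == 0) return(tibble(start_s = numeric(0), end_s = numeric(0)))
  if (anyNA(stream) || !all(stream %in% c(0L, 1L))) {
    abort("stream must contain only 0 and 1")
  }
  r <- rle(stream)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values == 1L
  if (!any(keep)) return(tibble(start_s = numeric(0), end_s = numeric(0)))
  start_s <- (starts_i[keep] - 1) / fs
  end_s <- ends_i[keep] / fs

  # single left-to-right merge pass; extending an interval rightward never
  # changes its gap to the next candidate, so one pass is already stable
  ms <- me <- numeric(length(start_s))
  k <- 1L
  ms[1] <- start_s[1]; me[1] <- end_s[1]
  for (i in seq_along(start_s)[-1]) {
    if (start_s[i] - me[k] < params$min_gap_s) {
      me[k] <- end_s[i]
    } else {
      k <- k + 1L
      ms[k] <- start_s[i]; me[k] <- end_s[i]
    }
  }
  ms <- ms[1:k]; me <- me[1:k]
  long_enough <- (me - ms) > params$min_puff_s
  tibble(start_s = ms[long_enough], end_s = me[long_enough])
}

#' Group puff events into smoking sessions
#'
#' Partitions the puff sequence wherever the rest between adjacent puffs
#' exceeds `max_gap_s` (different cigarettes), then greedily splits each
#' chain left to right whenever adding the next puff would push the span
#' from the session's first puff past `max_session_s` (chain-smoking
#' handled by the session-duration rule, which takes precedence), and
#' finally discards groups with fewer than `min_puffs` puffs.
#'
#' @param puffs Tibble of sorted, disjoint puffs (`start_s`, `end_s`),
#'   as from [stream_to_puffs()].
#' @param params A [session_params()] object.
#' @return Tibble of sessions with columns `start_s`, `end_s`,
#'   `n_puffs`, and a `puffs` list column of per-session puff tibbles.
#' @export
puffs_to_sessions <- function(puffs, params = session_params()) {
  empty <- tibble(
    start_s = numeric(0), end_s = numeric(0), n_puffs = integer(0),
    puffs = list()
  )
  if (nrow(puffs) == 0) return(empty)
  if (any(puffs$end_s < puffs$start_s)) abort("puffs must have start_s <= end_s")
  if (nrow(puffs) > 1) {
    if (is.unsorted(puffs$start_s) ||
        any(puffs$start_s[-1] < puffs$end_s[-nrow(puffs)])) {
      abort("puffs must be sorted and disjoint")
    }
  }

  gaps <- puffs$start_s[-1] - puffs$end_s[-nrow(puffs)]
  chain_id <- cumsum(c(1, as.integer(gaps > params$max_gap_s)))

  groups <- list()
  for (ch in split(puffs, chain_id)) {
    first <- 1L
    for (i in seq_len(nrow(ch))) {
      if (ch$end_s[i] - ch$start_s[first] > params$max_session_s) {
        groups[[length(groups) + 1L]] <- ch[first:(i - 1L), ]
        first <- i
      }
    }
    groups[[length(groups) + 1L]] <- ch[first:nrow(ch), ]
  }

  groups <- groups[vapply(groups, nrow, integer(1)) >= params$min_puffs]
  if (length(groups) == 0) return(empty)
  tibble(
    start_s = vapply(groups, function(g) g$start_s[1], numeric(1)),
    end_s = vapply(groups, function(g) g$end_s[nrow(g)], numeric(1)),
    n_puffs = vapply(groups, nrow, integer(1)),
    puffs = groups
  )
}

#' Detect smoking sessions in a raw accelerometer trace
#'
#' The full hierarchical detector: low-pass smoothing, per-sample gesture
#' classification by the neural network, then the rule layer that builds
#' puffs and sessions. Returned sessions report their puff counts.
#'
#' @param trace A raw [accel_trace].
#' @param model A [train_gesture_model()] fit.
#' @param params A [session_params()] object.
#' @param cutoff_hz Low-pass cutoff in Hz.
#' @return Session tibble as from [puffs_to_sessions()].
#' @export
detect_sessions <- function(trace, model, params = session_params(),
                            cutoff_hz = 5) {
  if (nrow(trace) == 0) return(puffs_to_sessions(stream_to_puffs(integer(0))))
  smoothed <- lowpass(trace, cutoff_hz = cutoff_hz)
  stream <- classify_stream(smoothed, model)
  stream_to_puffs(stream, fs = trace_fs(trace), params = params) |>
    puffs_to_sessions(params = params)
}
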