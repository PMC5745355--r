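# Brute-force reference for the rule layer: naive loops that restate the
# smoking-session model directly, independent of the vectorised
# implementation under test.

oracle_runs <- function(stream, fs) {
  runs <- list()
  i <- 1L
  n <- length(stream)
  while (i <= n) {
    if (stream[i] == 1L) {
      j <- i
      while (j < n && stream[j + 1L] == 1L) j <- j + 1L
      runs[[length(runs) + 1L]] <- c((i - 1) / fs, j / fs)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}

oracle_puffs <- function(stream, fs, params = session_params()) {
  runs <- oracle_runs(stream, fs)
  # merge adjacent candidates with rest < min_gap, rescanning until stable
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    k <- 1L
    while (k < length(runs)) {
      if (runs[[k + 1L]][1] - runs[[k]][2] < params$min_gap_s) {
        runs[[k]] <- c(runs[[k]][1], runs[[k + 1L]][2])
        runs[[k + 1L]] <- NULL
        changed <- TRUE
      } else {
        k <- k + 1L
      }
    }
  }
  runs <- Filter(function(r) r[2] - r[1] > params$min_puff_s, runs)
  if (length(runs) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  data.frame(
    start_s = vapply(runs, `[`, numeric(1), 1),
    end_s = vapply(runs, `[`, numeric(1), 2)
  )
}

oracle_sessions <- function(puffs, params = session_params()) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_puffs = integer(0))
  if (nrow(puffs) == 0) return(empty)
  # chains split at rests exceeding the maximum
  chains <- list()
  cur <- list(1L)
  for (i in seq_len(nrow(puffs))[-1]) {
    if (puffs$start_s[i] - puffs$end_s[i - 1L] > params$max_gap_s) {
      chains[[length(chains) + 1L]] <- unlist(cur)
      cur <- list()
    }
    cur[[length(cur) + 1L]] <- i
  }
  chains[[length(chains) + 1L]] <- unlist(cur)
  # greedy duration split, then the minimum puff-count filter
  out <- list()
  for (ch in chains) {
    group <- integer(0)
    for (i in ch) {
      if (length(group) > 0 &&
          puffs$end_s[i] - puffs$start_s[group[1]] > params$max_session_s) {
        out[[length(out) + 1L]] <- group
        group <- integer(0)
      }
      group <- c(group, i)
    }
    out[[length(out) + 1L]] <- group
  }
  out <- Filter(function(g) length(g) >= params$min_puffs, out)
  if (length(out) == 0) return(empty)
  data.frame(
    start_s = vapply(out, function(g) puffs$start_s[g[1]], numeric(1)),
    end_s = vapply(out, function(g) puffs$end_s[g[length(g)]], numeric(1)),
    n_puffs = vapply(out, length, integer(1))
  )
}

# random binary stream with run structure on the scale the rules act on
random_stream <- function(n, fs = 20) {
  out <- integer(0)
  state <- sample(c(0L, 1L), 1)
  while (length(out) < n) {
    len <- if (state == 1L) {
      sample(1:120, 1) # up to 6 s of gesture
    } else {
      max(1L, round(stats::rexp(1, rate = 1 / 200))) # rests up to minutes
    }
    out <- c(out, rep(state, len))
    state <- 1L - state
  }
  out[seq_len(n)]
}

# rebuild a sample-aligned stream from puff intervals
puffs_to_stream <- function(puffs, n, fs = 20) {
  stream <- integer(n)
  for (i in seq_len(nrow(puffs))) {
    a <- round(puffs$start_s[i] * fs) + 1L
    b <- round(puffs$end_s[i] * fs)
    stream[a:b] <- 1L
  }
  stream
}
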