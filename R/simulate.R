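#' Configuration of the synthetic accelerometer generator
#'
#' The generator emulates what a right-wrist smartwatch records at 20 Hz:
#' gravity (9.81 m/s^2) rotating through the sensor frame as the arm
#' moves, plus Gaussian sensor noise. A puff is a smooth raise-hold-lower
#' gravity rotation (watch face up at rest, z near +9.81; y picks up the
#' gravity component as the wrist turns toward the mouth). Sessions are
#' built from `puffs_per_session_range` puffs separated by rests drawn
#' from `rest_range_s`; a drawn session that would exceed the 8-minute
#' session model is compressed by rescaling its rests (see the methods
#' vignette), so every generated session satisfies the default
#' [session_params()] constraints.
#'
#' @param fs Sampling frequency in Hz.
#' @param puff_raise_s,puff_hold_s,puff_lower_s Durations of the three
#'   puff phases in seconds (nominal total 3.5 s).
#' @param rest_range_s Two-element range the inter-puff rests are drawn
#'   from, seconds.
#' @param puffs_per_session_range Two-element integer range of puffs per
#'   session.
#' @param noise_sd Accelerometer noise standard deviation, m/s^2.
#' @param jitter_sd Multiplicative timing jitter (fractional sd; factors
#'   are clamped to \[0.5, 1.5\]).
#' @param report_slop_range_s Range of the uniform inflation added to
#'   each end of a self-reported session bound, reconciling
#'   participants' generous logging with the shorter observed sessions.
#' @param seed Default seed used by the simulation functions when they
#'   are not given one explicitly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(fs = 20, puff_raise_s = 1.0, puff_hold_s = 1.5,
                       puff_lower_s = 1.0, rest_range_s = c(20, 90),
                       puffs_per_session_range = c(5, 13), noise_sd = 0.3,
                       jitter_sd = 0.1, report_slop_range_s = c(0, 180),
                       seed = NULL) {
  durs <- c(puff_raise_s, puff_hold_s, puff_lower_s)
  if (any(durs <= 0)) abort("puff phase durations must be positive")
  if (length(rest_range_s) != 2 || rest_range_s[1] > rest_range_s[2] ||
      rest_range_s[1] <= 0) {
    abort("rest_range_s must be an increasing positive range")
  }
  if (length(puffs_per_session_range) != 2 ||
      puffs_per_session_range[1] > puffs_per_session_range[2] ||
      puffs_per_session_range[1] < 1) {
    abort("puffs_per_session_range must be an increasing range of counts >= 1")
  }
  rules <- session_params()
  if (0.5 * sum(durs) <= rules$min_puff_s) {
    warn("shortest possible puff does not exceed the minimum puff duration rule")
  }
  if (rest_range_s[1] <= rules$min_gap_s || rest_range_s[2] >= rules$max_gap_s) {
    warn("rest_range_s extends outside the inter-puff rest rules")
  }
  structure(
    list(
      fs = fs, puff_raise_s = puff_raise_s, puff_hold_s = puff_hold_s,
      puff_lower_s = puff_lower_s, rest_range_s = rest_range_s,
      puffs_per_session_range = as.integer(puffs_per_session_range),
      noise_sd = noise_sd, jitter_sd = jitter_sd,
      report_slop_range_s = report_slop_range_s, seed = seed
    ),
    class = "sim_config"
  )
}

GRAVITY <- 9.81

# unit gravity direction at rotation angle theta, tilting out of +z with
# lateral mix (mx, my); magnitude is exactly GRAVITY at every angle
gravity_xyz <- function(theta, mx, my) {
  sx <- mx * sin(theta)
  sy <- my * sin(theta)
  sz <- cos(theta)
  nrm <- sqrt(sx^2 + sy^2 + sz^2)
  list(x = GRAVITY * sx / nrm, y = GRAVITY * sy / nrm, z = GRAVITY * sz / nrm)
}

# raise-hold-lower rotation segment (noise-free); returns xyz vectors
rotation_segment <- function(n_raise, n_hold, n_lower, theta_max, mx, my) {
  theta <- c(
    theta_max * smoothstep(seq_len(n_raise) / n_raise),
    rep(theta_max, n_hold),
    theta_max * smoothstep(1 - seq_len(n_lower) / n_lower)
  )
  gravity_xyz(theta, mx, my)
}

add_noise <- function(seg, sd) {
  if (sd > 0) {
    n <- length(seg$x)
    seg$x <- seg$x + rnorm(n, 0, sd)
    seg$y <- seg$y + rnorm(n, 0, sd)
    seg$z <- seg$z + rnorm(n, 0, sd)
  }
  seg
}

idle_segment <- function(n, config) {
  add_noise(list(x = numeric(n), y = numeric(n), z = rep(GRAVITY, n)),
            config$noise_sd)
}

jitter_factor <- function(config) {
  pmin(pmax(1 + config$jitter_sd * rnorm(1), 0.5), 1.5)
}

#' Simulate a single puff gesture
#'
#' One hand-to-mouth smoking gesture: the gravity vector rotates smoothly
#' from the resting orientation (watch face up) toward the mouth
#' orientation and back, with multiplicative timing jitter and additive
#' sensor noise. The whole raise-hold-lower span is the puff interval.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; defaults to drawing from the current RNG
#'   stream (or `config$seed` at the top-level entry points).
#' @return A list with `segment` (tibble `x,y,z`), `duration_s`, and
#'   `n_samples`.
#' @export
simulate_puff <- function(config = sim_config(), seed = NULL) {
  with_seed_or_rng(seed, {
    fs <- config$fs
    n_raise <- max(1L, round(config$puff_raise_s * jitter_factor(config) * fs))
    n_hold <- max(1L, round(config$puff_hold_s * jitter_factor(config) * fs))
    n_lower <- max(1L, round(config$puff_lower_s * jitter_factor(config) * fs))
    seg <- rotation_segment(n_raise, n_hold, n_lower,
                            theta_max = 1.2, mx = 0.25, my = 0.95)
    seg <- add_noise(seg, config$noise_sd)
    n <- n_raise + n_hold + n_lower
    list(segment = as_tibble(seg), duration_s = n / fs, n_samples = n)
  })
}

# cap below the 8-minute session rule so generated ground truth always
# satisfies it with margin for classifier edge widening
SESSION_CAP_S <- 460

#' Simulate one smoking session
#'
#' Draws a puff count from `puffs_per_session_range` and rests from
#' `rest_range_s`; if the resulting span would exceed the session cap
#' the rests are rescaled proportionally (they remain far above the
#' minimum-rest rule). The returned ground truth therefore always
#' satisfies the default [session_params()] model.
#'
#' @inheritParams simulate_puff
#' @return A list with `segment` (tibble `x,y,z` starting at the first
#'   puff and ending at the last), `puffs` (tibble `start_s,end_s`
#'   relative to segment start), `n_puffs`, `duration_s`.
#' @export
simulate_session <- function(config = sim_config(), seed = NULL) {
  with_seed_or_rng(seed, {
    fs <- config$fs
    k <- sample(seq(config$puffs_per_session_range[1],
                    config$puffs_per_session_range[2]), 1)
    puffs <- lapply(seq_len(k), function(i) simulate_puff(config))
    puff_ns <- vapply(puffs, `[[`, integer(1) + 0, "n_samples")
    rest_s <- if (k > 1) {
      runif(k - 1, config$rest_range_s[1], config$rest_range_s[2])
    } else {
      numeric(0)
    }
    total <- sum(puff_ns) / fs + sum(rest_s)
    if (total > SESSION_CAP_S && k > 1) {
      rest_s <- rest_s * (SESSION_CAP_S - sum(puff_ns) / fs) / sum(rest_s)
    }
    rest_ns <- round(rest_s * fs)

    xs <- ys <- zs <- list()
    starts <- ends <- numeric(k)
    pos <- 0L
    for (i in seq_len(k)) {
      starts[i] <- pos / fs
      seg <- puffs[[i]]$segment
      xs[[length(xs) + 1]] <- seg$x
      ys[[length(ys) + 1]] <- seg$y
      zs[[length(zs) + 1]] <- seg$z
      pos <- pos + puff_ns[i]
      ends[i] <- pos / fs
      if (i < k) {
        idle <- idle_segment(rest_ns[i], config)
        xs[[length(xs) + 1]] <- idle$x
        ys[[length(ys) + 1]] <- idle$y
        zs[[length(zs) + 1]] <- idle$z
        pos <- pos + rest_ns[i]
      }
    }
    list(
      segment = tibble(x = unlist(xs), y = unlist(ys), z = unlist(zs)),
      puffs = tibble(start_s = starts, end_s = ends),
      n_puffs = k,
      duration_s = pos / fs
    )
  })
}

#' Simulate a confounder (nonsmoking) activity
#'
#' Parameterised caricatures of the activities smokers also perform with
#' the watch arm: `eating` (frequent short hand-to-mouth raises, mostly
#' closer together than the minimum inter-puff rest), `drinking` (sparse
#' raises with a longer hold and a different wrist rotation than a
#' puff), `walking` (about 2 Hz oscillation on all axes plus
#' high-frequency jitter), `typing` (low-amplitude high-frequency
#' jitter, face up), `tying_shoes` (a single slow bend), and `idle`
#' (gravity plus noise).
#'
#' @param kind One of `"eating"`, `"drinking"`, `"walking"`, `"typing"`,
#'   `"tying_shoes"`, `"idle"`.
#' @param duration_s Segment duration in seconds.
#' @inheritParams simulate_puff
#' @return A tibble `x,y,z` of `round(duration_s * fs)` samples.
#' @export
simulate_activity <- function(kind, duration_s, config = sim_config(),
                              seed = NULL) {
  kinds <- c("eating", "drinking", "walking", "typing", "tying_shoes", "idle")
  if (!kind %in% kinds) {
    abort(sprintf("unknown activity kind '%s'", kind))
  }
  if (duration_s <= 0) abort("duration_s must be positive")
  with_seed_or_rng(seed, {
    n <- max(1L, round(duration_s * config$fs))
    seg <- switch(kind,
      idle = idle_segment(n, config),
      walking = walking_segment(n, config),
      typing = typing_segment(n, config),
      drinking = event_train_segment(n, config,
        raise_s = 1.2, hold_range_s = c(3, 6), lower_s = 1.2,
        gap_range_s = c(25, 110), theta_max = 1.0, mx = -0.85, my = 0.35
      ),
      eating = eating_segment(n, config),
      tying_shoes = tying_segment(n, config)
    )
    as_tibble(seg)
  })
}

walking_segment <- function(n, config) {
  fs <- config$fs
  t <- (seq_len(n) - 1) / fs
  f <- runif(1, 1.8, 2.2)
  ph <- runif(6, 0, 2 * pi)
  hf <- function(a, p) a * sin(2 * pi * 9 * t + p)
  seg <- list(
    x = 1.4 * sin(2 * pi * f * t + ph[1]) + 0.6 * sin(2 * pi * 2 * f * t + ph[2]) +
      hf(1.0, ph[3]),
    y = 1.0 * sin(2 * pi * f * t + ph[4]) + hf(0.8, ph[5]),
    z = GRAVITY + 1.8 * sin(2 * pi * 2 * f * t + ph[6]) + hf(1.0, ph[1])
  )
  add_noise(seg, config$noise_sd)
}

typing_segment <- function(n, config) {
  fs <- config$fs
  t <- (seq_len(n) - 1) / fs
  ph <- runif(2, 0, 2 * pi)
  seg <- list(
    x = 0.3 * sin(2 * pi * 7.5 * t + ph[1]),
    y = 0.25 * sin(2 * pi * 6.5 * t + ph[2]),
    z = rep(GRAVITY, n)
  )
  add_noise(seg, max(config$noise_sd, 0.15))
}

# sparse raise-hold-lower events over an idle background
event_train_segment <- function(n, config, raise_s, hold_range_s, lower_s,
                                gap_range_s, theta_max, mx, my) {
  fs <- config$fs
  xs <- ys <- zs <- list()
  pos <- 0L
  gap_n <- round(runif(1, 2, gap_range_s[1]) * fs)
  while (pos < n) {
    gap_n <- min(gap_n, n - pos)
    idle <- idle_segment(gap_n, config)
    xs[[length(xs) + 1]] <- idle$x
    ys[[length(ys) + 1]] <- idle$y
    zs[[length(zs) + 1]] <- idle$z
    pos <- pos + gap_n
    if (pos >= n) break
    ev <- rotation_segment(
      max(1L, round(raise_s * jitter_factor(config) * fs)),
      max(1L, round(runif(1, hold_range_s[1], hold_range_s[2]) * fs)),
      max(1L, round(lower_s * jitter_factor(config) * fs)),
      theta_max, mx, my
    )
    ev <- add_noise(ev, config$noise_sd)
    take <- min(length(ev$x), n - pos)
    xs[[length(xs) + 1]] <- ev$x[seq_len(take)]
    ys[[length(ys) + 1]] <- ev$y[seq_len(take)]
    zs[[length(zs) + 1]] <- ev$z[seq_len(take)]
    pos <- pos + take
    gap_n <- round(runif(1, gap_range_s[1], gap_range_s[2]) * fs)
  }
  list(x = unlist(xs), y = unlist(ys), z = unlist(zs))
}

# frequent short raises; most consecutive raises closer than the
# minimum inter-puff rest, with an occasional longer pause
eating_segment <- function(n, config) {
  fs <- config$fs
  xs <- ys <- zs <- list()
  pos <- 0L
  gap_n <- round(runif(1, 0.8, 2.2) * fs)
  while (pos < n) {
    gap_n <- min(gap_n, n - pos)
    idle <- idle_segment(gap_n, config)
    xs[[length(xs) + 1]] <- idle$x
    ys[[length(ys) + 1]] <- idle$y
    zs[[length(zs) + 1]] <- idle$z
    pos <- pos + gap_n
    if (pos >= n) break
    ev <- rotation_segment(
      max(1L, round(0.5 * jitter_factor(config) * fs)),
      max(1L, round(0.35 * fs)),
      max(1L, round(0.5 * jitter_factor(config) * fs)),
      theta_max = 0.8, mx = 0.55, my = 0.75
    )
    ev <- add_noise(ev, config$noise_sd)
    take <- min(length(ev$x), n - pos)
    xs[[length(xs) + 1]] <- ev$x[seq_len(take)]
    ys[[length(ys) + 1]] <- ev$y[seq_len(take)]
    zs[[length(zs) + 1]] <- ev$z[seq_len(take)]
    pos <- pos + take
    gap_n <- if (runif(1) < 0.15) {
      round(runif(1, 3, 8) * fs)
    } else {
      round(runif(1, 0.8, 2.2) * fs)
    }
  }
  list(x = unlist(xs), y = unlist(ys), z = unlist(zs))
}

# one slow bend placed at a random offset in an otherwise idle segment
tying_segment <- function(n, config) {
  fs <- config$fs
  ev <- rotation_segment(
    round(1.5 * fs), round(runif(1, 2.5, 4) * fs), round(1.5 * fs),
    theta_max = 1.3, mx = 0.95, my = -0.2
  )
  ev <- add_noise(ev, config$noise_sd)
  m <- length(ev$x)
  seg <- idle_segment(n, config)
  if (m < n) {
    at <- sample.int(n - m, 1)
    idx <- at + seq_len(m) - 1L
    seg$x[idx] <- ev$x
    seg$y[idx] <- ev$y
    seg$z[idx] <- ev$z
  }
  seg
}

#' Simulate a full recording with ground truth and a self-report log
#'
#' Places `n_sessions` smoking sessions at random non-overlapping
#' positions (with clearance above the maximum inter-puff rest, so
#' sessions cannot chain together), fills the remaining time with
#' confounder activities, and produces the self-report a participant
#' would log: each true session's bounds inflated by a uniform slop at
#' each end, with injectable error modes — a missing start or end time
#' (`p_missing_bound`), an unreported session (`p_unreported`), and a
#' phantom entry with no underlying smoking (`p_phantom`, per session).
#'
#' @param n_sessions Number of smoking sessions to embed.
#' @param total_minutes Recording length in minutes.
#' @param log_errors List with elements `p_missing_bound`,
#'   `p_unreported`, `p_phantom`. Defaults are calibrated to observed
#'   field rates (about 22% of entries missing one bound, and a few
#'   percent unreported or phantom).
#' @inheritParams simulate_puff
#' @return A list: `trace` (an [accel_trace], `t0 = 0`), `sessions`
#'   (ground-truth tibble `start_s,end_s,n_puffs,puffs`), `stream`
#'   (per-sample 0/1 vector, 1 exactly within puff intervals),
#'   `activities` (tibble `kind,start_s,end_s`), and `log` (self-report
#'   tibble `start,end,puff_count,first_of_pack`).
#' @export
simulate_recording <- function(n_sessions, total_minutes,
                               log_errors = list(
                                 p_missing_bound = 27 / 123,
                                 p_unreported = 6 / 123,
                                 p_phantom = 2 / 123
                               ),
                               config = sim_config(), seed = config$seed) {
  with_seed_or_rng(seed, {
    fs <- config$fs
    n_total <- round(total_minutes * 60 * fs)
    clearance <- 260 # > max inter-puff rest rule, plus classifier edge margin

    sessions <- lapply(seq_len(n_sessions), function(i) simulate_session(config))
    sess_ns <- vapply(sessions, function(s) nrow(s$segment), integer(1))
    base_gap <- if (n_sessions > 0) clearance * fs else 0
    free <- n_total - sum(sess_ns) - (n_sessions + 1) * base_gap
    if (free < 0) {
      abort("infeasible packing: recording too short for the requested sessions")
    }
    u <- runif(n_sessions + 1)
    gap_ns <- round(base_gap + free * u / sum(u))

    xs <- ys <- zs <- list()
    stream <- integer(0)
    acts <- list()
    truth <- list()
    pos <- 0L
    append_seg <- function(seg) {
      xs[[length(xs) + 1]] <<- seg$x
      ys[[length(ys) + 1]] <<- seg$y
      zs[[length(zs) + 1]] <<- seg$z
    }
    for (i in seq_len(n_sessions + 1)) {
      fill <- fill_gap(gap_ns[i], config, offset_s = pos / fs)
      append_seg(fill$segment)
      acts[[length(acts) + 1]] <- fill$activities
      pos <- pos + gap_ns[i]
      if (i <= n_sessions) {
        s <- sessions[[i]]
        off <- pos / fs
        append_seg(s$segment)
        truth[[i]] <- tibble(
          start_s = off, end_s = off + s$duration_s, n_puffs = s$n_puffs,
          puffs = list(dplyr::mutate(s$puffs,
            start_s = .data$start_s + off, end_s = .data$end_s + off))
        )
        acts[[length(acts) + 1]] <- tibble(
          kind = "smoking", start_s = off, end_s = off + s$duration_s
        )
        pos <- pos + sess_ns[i]
      }
    }
    x <- unlist(xs); y <- unlist(ys); z <- unlist(zs)
    # trim rounding spillover to the requested length
    if (length(x) > n_total) {
      x <- x[seq_len(n_total)]; y <- y[seq_len(n_total)]; z <- z[seq_len(n_total)]
    } else if (length(x) < n_total) {
      pad <- idle_segment(n_total - length(x), config)
      x <- c(x, pad$x); y <- c(y, pad$y); z <- c(z, pad$z)
    }

    truth_sessions <- if (n_sessions > 0) dplyr::bind_rows(truth) else {
      tibble(start_s = numeric(0), end_s = numeric(0), n_puffs = integer(0),
             puffs = list())
    }
    stream <- integer(n_total)
    for (p in truth_sessions$puffs) {
      for (r in seq_len(nrow(p))) {
        a <- round(p$start_s[r] * fs) + 1L
        b <- round(p$end_s[r] * fs)
        stream[a:b] <- 1L
      }
    }

    log <- build_log(truth_sessions, gap_ns, sess_ns, log_errors, config)

    list(
      trace = accel_trace(x, y, z, fs = fs, t0 = 0),
      sessions = truth_sessions,
      stream = stream,
      activities = dplyr::bind_rows(acts),
      log = log
    )
  })
}

# fill a gap with randomly chosen confounder chunks
fill_gap <- function(n, config, offset_s) {
  fs <- config$fs
  kinds <- c("idle", "walking", "typing", "drinking", "eating", "tying_shoes")
  wts <- c(0.3, 0.2, 0.15, 0.12, 0.13, 0.1)
  xs <- ys <- zs <- list()
  acts <- list()
  pos <- 0L
  while (pos < n) {
    chunk <- min(n - pos, round(runif(1, 30, 120) * fs))
    kind <- if (chunk < 10 * fs) "idle" else sample(kinds, 1, prob = wts)
    seg <- simulate_activity(kind, chunk / fs, config)
    take <- min(nrow(seg), n - pos)
    xs[[length(xs) + 1]] <- seg$x[seq_len(take)]
    ys[[length(ys) + 1]] <- seg$y[seq_len(take)]
    zs[[length(zs) + 1]] <- seg$z[seq_len(take)]
    acts[[length(acts) + 1]] <- tibble(
      kind = kind, start_s = offset_s + pos / fs,
      end_s = offset_s + (pos + take) / fs
    )
    pos <- pos + take
  }
  list(
    segment = list(x = unlist(xs), y = unlist(ys), z = unlist(zs)),
    activities = dplyr::bind_rows(acts)
  )
}

build_log <- function(truth_sessions, gap_ns, sess_ns, log_errors, config) {
  slop <- config$report_slop_range_s
  entries <- list()
  for (i in seq_len(nrow(truth_sessions))) {
    if (runif(1) < log_errors$p_unreported) next
    start <- max(0, truth_sessions$start_s[i] - runif(1, slop[1], slop[2]))
    end <- truth_sessions$end_s[i] + runif(1, slop[1], slop[2])
    entry <- tibble(
      start = start, end = end,
      puff_count = truth_sessions$n_puffs[i],
      first_of_pack = runif(1) < 0.1
    )
    if (runif(1) < log_errors$p_missing_bound) {
      if (runif(1) < 0.5) entry$start <- NA_real_ else entry$end <- NA_real_
    }
    entries[[length(entries) + 1]] <- entry
    if (runif(1) < log_errors$p_phantom) {
      # phantom entry placed in the nonsmoking gap before this session
      gap_end <- truth_sessions$start_s[i] - 10
      dur <- runif(1, 240, 480)
      ph_start <- max(0, gap_end - dur - runif(1, 0, 60))
      entries[[length(entries) + 1]] <- tibble(
        start = ph_start, end = min(gap_end, ph_start + dur),
        puff_count = sample(3:13, 1), first_of_pack = FALSE
      )
    }
  }
  if (length(entries) == 0) {
    return(tibble(start = numeric(0), end = numeric(0),
                  puff_count = integer(0), first_of_pack = logical(0)))
  }
  out <- dplyr::bind_rows(entries)
  dplyr::arrange(out, dplyr::coalesce(.data$start, .data$end))
}

#' Generate a balanced corpus of labelled gesture windows
#'
#' Builds the training material for [train_gesture_model()]: simulated
#' smoking sessions (padded with idle time) and confounder activities
#' are smoothed with the same low-pass filter the detector applies,
#' cut into 5-second windows, and labelled by whether the window's
#' centre sample lies inside a ground-truth puff. Positives and
#' negatives are then subsampled to an exactly balanced corpus.
#'
#' @param n_windows Total windows returned (half each label).
#' @param stride Window stride in samples during extraction.
#' @param cutoff_hz Low-pass cutoff applied before windowing.
#' @param window_s Window length in seconds.
#' @inheritParams simulate_puff
#' @return Tibble with a `features` matrix column and a 0/1 `label`
#'   column, rows shuffled.
#' @export
simulate_training_windows <- function(n_windows = 10000,
                                      config = sim_config(),
                                      seed = config$seed,
                                      stride = 5, cutoff_hz = 5,
                                      window_s = 5) {
  with_seed_or_rng(seed, {
    fs <- config$fs
    w <- round(window_s * fs)
    pad_n <- round(8 * fs)
    target_pos <- ceiling(n_windows / 2)

    pos_feats <- list(); rest_feats <- list(); conf_feats <- list()
    n_pos <- 0L
    while (n_pos < target_pos) {
      s <- simulate_session(config)
      pad1 <- idle_segment(pad_n, config)
      pad2 <- idle_segment(pad_n, config)
      tr <- accel_trace(
        c(pad1$x, s$segment$x, pad2$x),
        c(pad1$y, s$segment$y, pad2$y),
        c(pad1$z, s$segment$z, pad2$z),
        fs = fs
      )
      stream <- integer(nrow(tr))
      for (r in seq_len(nrow(s$puffs))) {
        a <- pad_n + round(s$puffs$start_s[r] * fs) + 1L
        b <- pad_n + round(s$puffs$end_s[r] * fs)
        stream[a:b] <- 1L
      }
      win <- gesture_windows(lowpass(tr, cutoff_hz), window_s, stride)
      lab <- stream[win$start_index + w %/% 2L]
      pos_feats[[length(pos_feats) + 1]] <- win$features[lab == 1L, , drop = FALSE]
      rest_feats[[length(rest_feats) + 1]] <- win$features[lab == 0L, , drop = FALSE]
      n_pos <- n_pos + sum(lab == 1L)
    }
    # confounder material; event-sparse kinds get many short segments so
    # their events (drink raises, shoe-tying bends) are well represented
    conf_plan <- list(
      walking = rep(60, 5), typing = rep(60, 4), idle = rep(60, 4),
      drinking = rep(120, 5), eating = rep(60, 8), tying_shoes = rep(30, 20)
    )
    for (kind in names(conf_plan)) {
      for (dur in conf_plan[[kind]]) {
        seg <- simulate_activity(kind, dur, config)
        tr <- accel_trace(seg$x, seg$y, seg$z, fs = fs)
        win <- gesture_windows(lowpass(tr, cutoff_hz), window_s, stride)
        conf_feats[[length(conf_feats) + 1]] <- win$features
      }
    }

    pos <- do.call(rbind, pos_feats)
    rest <- do.call(rbind, rest_feats)
    conf <- do.call(rbind, conf_feats)
    n_half <- min(floor(n_windows / 2), nrow(pos), nrow(rest) + nrow(conf))
    # negatives drawn ~40% from within-session rests, ~60% from confounders
    n_conf <- min(nrow(conf), ceiling(0.6 * n_half))
    n_rest <- min(nrow(rest), n_half - n_conf)
    n_conf <- n_half - n_rest
    pos <- pos[sample.int(nrow(pos), n_half), , drop = FALSE]
    neg <- rbind(
      rest[sample.int(nrow(rest), n_rest), , drop = FALSE],
      conf[sample.int(nrow(conf), n_conf), , drop = FALSE]
    )
    feats <- rbind(pos, neg)
    label <- rep(c(1L, 0L), each = n_half)
    ord <- sample.int(nrow(feats))
    tibble(features = feats[ord, , drop = FALSE], label = label[ord])
  })
}
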