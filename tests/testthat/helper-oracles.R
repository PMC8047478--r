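# Independent brute-force oracles and small fixture builders shared by the
# test files. Everything here is deliberately naive (O(n*m) scans, explicit
# enumeration) and independent of the package's implementation paths.

# O(n*m) rule-by-rule event classification: every stimulus and response is
# checked against the timing criteria directly.
oracle_classify <- function(stim, resp, params = classification_params()) {
  lo <- params$hit_window[1]; hi <- params$hit_window[2]
  # replicate the documented linking rule: responses in order claim the most
  # recent unclaimed stimulus in [r - hi, r - lo]
  link <- rep(NA_integer_, length(resp))
  taken <- logical(length(stim))
  for (j in seq_along(resp)) {
    best <- NA_integer_
    for (i in seq_along(stim)) {
      if (!taken[i] && stim[i] >= resp[j] - hi && stim[i] <= resp[j] - lo) {
        if (is.na(best) || stim[i] > stim[best]) best <- i
      }
    }
    if (!is.na(best)) { link[j] <- best; taken[best] <- TRUE }
  }
  stim_label <- character(length(stim))
  for (i in seq_along(stim)) {
    stim_label[i] <- if (i %in% link) "hit"
    else {
      any_resp <- FALSE
      for (j in seq_along(resp))
        if (resp[j] >= stim[i] && resp[j] <= stim[i] + params$miss_horizon)
          any_resp <- TRUE
      if (any_resp) "margin" else "miss"
    }
  }
  resp_label <- character(length(resp))
  for (j in seq_along(resp)) {
    resp_label[j] <- if (!is.na(link[j])) "hit_response"
    else {
      any_stim <- FALSE
      for (i in seq_along(stim))
        if (stim[i] >= resp[j] - params$fa_lockout && stim[i] <= resp[j])
          any_stim <- TRUE
      if (any_stim) "margin" else "fa"
    }
  }
  list(stim_label = stim_label, resp_label = resp_label, link = link)
}

# exhaustive flood fill over a supra-threshold mask using repeated neighbor
# expansion (no union-find); dims = c(chan, time) or c(chan, freq, time)
oracle_clusters <- function(t_map, t_crit, adj_mat = NULL) {
  dims <- dim(t_map)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) t_map > t_crit else t_map < -t_crit
    todo <- which(mask)
    while (length(todo)) {
      comp <- todo[1]
      repeat {
        grown <- comp
        for (cell in comp) {
          idx <- arrayInd(cell, dims)
          for (cand in todo) {
            ci <- arrayInd(cand, dims)
            dvec <- abs(ci - idx)
            same_chan <- dvec[1] == 0
            adj_chan <- if (is.null(adj_mat)) FALSE else adj_mat[idx[1], ci[1]]
            neigh <- if (length(dims) == 2) {
              (same_chan && dvec[2] == 1) || (adj_chan && dvec[2] == 0)
            } else {
              (same_chan && dvec[2] == 0 && dvec[3] == 1) ||
                (same_chan && dvec[2] == 1 && dvec[3] == 0) ||
                (adj_chan && dvec[2] == 0 && dvec[3] == 0)
            }
            if (neigh) grown <- union(grown, cand)
          }
        }
        if (length(grown) == length(comp)) break
        comp <- grown
      }
      out[[length(out) + 1L]] <- list(cells = sort(comp), sign = sgn,
                                      sum = sum(t_map[comp]))
      todo <- setdiff(todo, comp)
    }
  }
  out
}

# exhaustive sign-flip permutation p-values for paired subject maps:
# enumerates all 2^N assignments, max |cluster sum| statistic
oracle_exhaustive_p <- function(maps_a, maps_b, t_crit, adj_mat = NULL) {
  n <- length(maps_a)
  shape <- dim(maps_a[[1]])
  diffs <- lapply(seq_len(n), function(s) maps_a[[s]] - maps_b[[s]])
  tmap_of <- function(signs) {
    d <- sapply(seq_len(n), function(s) as.numeric(diffs[[s]]) * signs[s])
    d <- matrix(d, ncol = n)
    m <- rowMeans(d)
    se <- apply(d, 1, stats::sd) / sqrt(n)
    t <- ifelse(se == 0, ifelse(m == 0, 0, sign(m) * Inf), m / se)
    array(t, dim = shape)
  }
  max_sum <- function(tm) {
    cl <- oracle_clusters(tm, t_crit, adj_mat)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "sum")))
  }
  signs_all <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null_max <- apply(signs_all, 1, function(s) max_sum(tmap_of(s)))
  obs <- oracle_clusters(tmap_of(rep(1, n)), t_crit, adj_mat)
  lapply(obs, function(cl) {
    cl$p <- mean(null_max >= abs(cl$sum))
    cl
  })
}

# exhaustive scan for CR anchor placement on a fixed grid: the earliest-
# feasible greedy tiling computed directly
oracle_cr_anchors <- function(stim, resp, dur, halfwidth, guard, grid = 0.01) {
  events <- sort(c(stim, resp))
  clear <- halfwidth + guard
  eps <- 1e-9
  ok_at <- function(t) all(events <= t - clear - eps | events >= t + clear + eps)
  anchors <- numeric(0)
  t <- ceiling(clear / grid - eps) * grid
  while (t + clear <= dur + eps) {
    if (ok_at(t)) {
      anchors <- c(anchors, t)
      t <- ceiling((t + 2 * halfwidth) / grid - eps) * grid
    } else {
      t <- t + grid
    }
  }
  anchors
}

# deterministic 1-up/2-down trace for a scripted response sequence: returns
# the level presented at each trial and the reversal levels, following the
# rule transitions step by step
oracle_staircase_trace <- function(responses, start_level, step1 = 1,
                                   step2 = 0.5, reduce_after = 4, stop_after = 9) {
  level <- start_level; n_corr <- 0L; last_dir <- 0L
  levels <- numeric(0); revs <- numeric(0)
  for (r in responses) {
    levels <- c(levels, level)
    move <- 0L
    if (r) { n_corr <- n_corr + 1L; if (n_corr >= 2L) move <- -1L }
    else move <- 1L
    if (move != 0L && last_dir != 0L && move != last_dir) revs <- c(revs, level)
    if (length(revs) >= stop_after) break
    if (move != 0L) {
      step <- if (length(revs) >= reduce_after) step2 else step1
      level <- level + move * step
      n_corr <- 0L
      last_dir <- move
    }
  }
  list(levels = levels, reversals = revs)
}

# noise snippet with a speech-like spectral envelope (low-frequency tilt
# with a voice-band emphasis) for the noise-synthesis tests
speech_like_snippet <- function(n, rate) {
  f <- pmin(0:(n - 1), n - 0:(n - 1)) * rate / n
  mag <- (f > 50) / (1 + (f / 500)^2)
  x <- Re(stats::fft(mag * exp(1i * stats::runif(n, 0, 2 * pi)), inverse = TRUE))
  waveform(x, rate)
}

# drop non-increasing duplicates, robust to empty vectors
dedupe_sorted <- function(x, tol = 1e-3) {
  if (length(x) < 2) return(x)
  x[c(TRUE, diff(x) > tol)]
}

# tiny two-channel montage with one adjacent pair
tiny_positions <- function() {
  data.frame(label = c("a", "b", "c"),
             x = c(0, 0.2, 0.9), y = 0, z = c(1, 0.98, 0.44))
}

# quick epoch-set builder: trials x channels x time from a function of time
make_epochs <- function(n_trials, n_channels, times, rate, fill = function(t) 0 * t) {
  arr <- array(0, dim = c(n_trials, n_channels, length(times)))
  for (i in seq_len(n_trials)) for (ch in seq_len(n_channels))
    arr[i, ch, ] <- fill(times)
  eeg_epochs(arr, times, rate)
}
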