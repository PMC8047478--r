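#' Trial-classification parameters for the continuous design
#'
#' The experiment has no discrete trials, so responses and stimuli are
#' categorized by timing rules derived from the group response-time
#' histogram: a response 300-1800 ms after a stimulus onset is a hit; a
#' stimulus with no response within 3600 ms is a miss; a response with
#' no stimulus onset in the preceding 3600 ms is a false alarm (FA).
#' Everything between the hit window and the 3600 ms horizons is a
#' deliberate margin and left unlabeled. Unclassified stretches of the
#' recording become correct rejections (CRs).
#'
#' @param hit_window Response window after stimulus onset defining hits,
#'   seconds (default `c(0.3, 1.8)`).
#' @param miss_horizon No-response horizon after onset defining misses,
#'   seconds (default 3.6).
#' @param fa_lockout Stimulus-free interval before a response required
#'   for an FA, seconds (default 3.6).
#' @param rt_bin RT histogram bin width, seconds (default 0.042).
#' @param smooth_window Gaussian smoothing window length, seconds
#'   (default 0.420).
#' @return A `classification_params` list.
#' @export
classification_params <- function(hit_window = c(0.3, 1.8), miss_horizon = 3.6,
                                  fa_lockout = 3.6, rt_bin = 0.042,
                                  smooth_window = 0.420) {
  if (!(0 < hit_window[1] && hit_window[1] < hit_window[2] &&
        hit_window[2] <= miss_horizon))
    stopf("need 0 < hit_window[1] < hit_window[2] <= miss_horizon")
  if (fa_lockout < hit_window[2])
    stopf("`fa_lockout` must be at least the hit-window end")
  structure(list(hit_window = hit_window, miss_horizon = miss_horizon,
                 fa_lockout = fa_lockout, rt_bin = rt_bin,
                 smooth_window = smooth_window),
            class = "classification_params")
}

#' Event stream of one continuous session
#'
#' @param stim_onsets Ascending stimulus-onset times (s).
#' @param responses Ascending button-press times (s).
#' @param dur_s Session duration (s).
#' @return An `event_stream` list.
#' @export
event_stream <- function(stim_onsets, responses, dur_s) {
  stim_onsets <- as.numeric(stim_onsets); responses <- as.numeric(responses)
  if (is.unsorted(stim_onsets, strictly = TRUE) ||
      is.unsorted(responses, strictly = TRUE))
    stopf("event times must be strictly ascending")
  if (length(stim_onsets) && (min(stim_onsets) < 0 || max(stim_onsets) > dur_s))
    stopf("stimulus onsets must lie within [0, dur_s]")
  if (length(responses) && (min(responses) < 0 || max(responses) > dur_s))
    stopf("responses must lie within [0, dur_s]")
  structure(list(stim_onsets = stim_onsets, responses = responses,
                 dur_s = dur_s), class = "event_stream")
}

#' Smoothed response-time histogram
#'
#' Bins the response times at `rt_bin` (42 ms) resolution, applies a
#' Gaussian-weighted moving average with window length `smooth_window`
#' (420 ms, ten bins), and normalizes the result so its trapezoidal
#' integral is 1, i.e. a probability-density estimate of the RT
#' distribution. This diagnostic motivated the 300-1800 ms hit window.
#'
#' @param rts Response times (s), non-empty.
#' @param params A [classification_params()].
#' @return A list with `bin_centers` (s), `density` (1/s), and the raw
#'   `counts`.
#' @export
smoothed_rt_histogram <- function(rts, params = classification_params()) {
  if (length(rts) == 0L) stopf("`rts` must be non-empty")
  h <- params$rt_bin
  # pad by the smoothing window so the kernel always fits the histogram
  pad <- params$smooth_window + h
  edges <- seq(floor((min(rts) - pad) / h) * h, max(rts) + pad, by = h)
  counts <- graphics::hist(rts, breaks = edges, plot = FALSE)$counts
  centers <- edges[-length(edges)] + h / 2
  # Gaussian kernel over the window, +/- 2.5 sd at the window edges;
  # odd length keeps the moving average symmetric (no half-bin lag)
  L <- max(1L, round(params$smooth_window / h))
  if (L %% 2 == 0) L <- L + 1L
  half <- (L - 1) / 2
  k <- exp(-0.5 * ((seq_len(L) - 1 - half) / (L / 5))^2)
  k <- k / sum(k)
  sm <- stats::filter(c(rep(0, L), counts, rep(0, L)), k, sides = 2)
  sm <- as.numeric(sm)[(L + 1):(L + length(counts))]
  area <- trapz(centers, sm)
  if (area <= 0) stopf("degenerate RT histogram")
  list(bin_centers = centers, density = sm / area, counts = counts)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Link responses to the stimuli that caused them
#'
#' Assigns each response to the most recent stimulus whose onset lies
#' `hit_window` before it; the first qualifying response wins each
#' stimulus, so the mapping is injective on hits. Responses qualifying
#' for two stimuli (impossible at the experimental ISI floor, possible
#' on arbitrary input) go to the closer, later stimulus.
#'
#' @param stream An [event_stream()].
#' @param params A [classification_params()].
#' @return Integer vector, one entry per response: the matched stimulus
#'   index or `NA`.
#' @export
link_responses_to_stimuli <- function(stream, params = classification_params()) {
  lo <- params$hit_window[1]; hi <- params$hit_window[2]
  link <- rep(NA_integer_, length(stream$responses))
  taken <- logical(length(stream$stim_onsets))
  for (j in seq_along(stream$responses)) {
    r <- stream$responses[j]
    cand <- which(stream$stim_onsets >= r - hi & stream$stim_onsets <= r - lo &
                  !taken)
    if (length(cand)) {
      i <- max(cand) # most recent stimulus
      link[j] <- i
      taken[i] <- TRUE
    }
  }
  link
}

#' Categorize stimuli and responses into hits, misses, FAs and margins
#'
#' Applies the continuous-design criteria: a stimulus is a *hit* when a
#' linked response falls in `hit_window` after its onset, a *miss* when
#' no response occurs within `miss_horizon`, and *margin* otherwise; a
#' response is a *hit response* when it defines a hit, an *FA* when no
#' stimulus onset occurred within `fa_lockout` before it, and *margin*
#' otherwise. CR anchors are placed in the event-free remainder via
#' [extract_cr_anchors()].
#'
#' @param stream An [event_stream()].
#' @param params A [classification_params()].
#' @param cr_halfwidth,cr_guard CR epoch half-width and guard (s) passed
#'   to [extract_cr_anchors()]; set `cr_halfwidth = NULL` to skip.
#' @return A `trial_labels` list: `stim_label` (hit/miss/margin per
#'   stimulus), `resp_label` (hit_response/fa/margin per response),
#'   `link` (response -> stimulus), `cr_anchors` (s), and `counts`.
#' @export
classify_events <- function(stream, params = classification_params(),
                            cr_halfwidth = 2.3, cr_guard = 1.0) {
  st <- stream$stim_onsets; rs <- stream$responses
  link <- link_responses_to_stimuli(stream, params)

  resp_label <- rep("margin", length(rs))
  resp_label[!is.na(link)] <- "hit_response"
  for (j in seq_along(rs)) {
    if (!is.na(link[j])) next
    if (!any(st >= rs[j] - params$fa_lockout & st <= rs[j]))
      resp_label[j] <- "fa"
  }

  stim_label <- rep("margin", length(st))
  stim_label[link[!is.na(link)]] <- "hit"
  for (i in seq_along(st)) {
    if (stim_label[i] == "hit") next
    if (!any(rs >= st[i] & rs <= st[i] + params$miss_horizon))
      stim_label[i] <- "miss"
  }

  labels <- structure(list(stim_label = stim_label, resp_label = resp_label,
                           link = link, cr_anchors = numeric(0)),
                      class = "trial_labels")
  if (!is.null(cr_halfwidth))
    labels$cr_anchors <- extract_cr_anchors(stream, labels,
                                            epoch_halfwidth = cr_halfwidth,
                                            guard = cr_guard)
  labels$counts <- c(hit = sum(stim_label == "hit"),
                     miss = sum(stim_label == "miss"),
                     fa = sum(resp_label == "fa"),
                     cr = length(labels$cr_anchors),
                     stim_margin = sum(stim_label == "margin"),
                     resp_margin = sum(resp_label == "margin"))
  labels
}

#' @export
print.trial_labels <- function(x, ...) {
  cat("<trial_labels> ", paste(names(x$counts), x$counts, sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}

#' Place correct-rejection anchors in event-free stretches
#'
#' Tiles the parts of the session left unlabeled by the hit/miss/FA
#' rules with non-overlapping CR epochs: an anchor at time `t` requires
#' `[t - halfwidth - guard, t + halfwidth + guard]` to contain no
#' stimulus onset and no response, and successive epochs
#' `[t - halfwidth, t + halfwidth]` must not overlap. Anchors are placed
#' greedily from the start of the record on a 10 ms grid.
#'
#' @param stream An [event_stream()].
#' @param labels Unused placeholder for API symmetry (classification of
#'   the events does not alter the event-free set).
#' @param epoch_halfwidth CR epoch half-width (s).
#' @param guard Extra clearance beyond the epoch (s, default 1).
#' @param grid Placement grid (s, default 0.01).
#' @return Numeric vector of anchor times (possibly empty).
#' @export
extract_cr_anchors <- function(stream, labels = NULL, epoch_halfwidth = 2.3,
                               guard = 1.0, grid = 0.01) {
  events <- sort(c(stream$stim_onsets, stream$responses))
  clear <- epoch_halfwidth + guard
  eps <- 1e-9
  snap_up <- function(x) ceiling(x / grid - eps) * grid # next grid point
  anchors <- numeric(0)
  t <- snap_up(clear)
  while (t + clear <= stream$dur_s + eps) {
    blocking <- events[events > t - clear - eps & events < t + clear + eps]
    if (length(blocking) == 0L) {
      anchors <- c(anchors, t)
      t <- snap_up(t + 2 * epoch_halfwidth)
    } else {
      # jump to the first grid point whose window clears the last blocker
      t <- snap_up(max(blocking) + clear)
      while (t - clear < max(blocking) + eps) t <- t + grid
    }
  }
  anchors
}
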