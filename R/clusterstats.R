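#' Paired (dependent-samples) t map across subjects
#'
#' Per-sample paired t statistic with N - 1 degrees of freedom over a
#' list of per-subject maps. Samples with zero variance across subjects
#' get `+/-Inf` with the sign of the mean difference (0 when the mean
#' difference is 0) — documented convention so downstream thresholding
#' stays well defined.
#'
#' @param maps_a,maps_b Lists (one element per subject) of equal-shape
#'   numeric arrays: channels x time, or channels x freqs x times.
#' @return Numeric array of t values, same shape as the maps.
#' @export
dependent_t <- function(maps_a, maps_b) {
  if (length(maps_a) != length(maps_b)) stopf("paired designs need equal subject counts")
  n <- length(maps_a)
  if (n < 2) stopf("need at least 2 subjects")
  shape <- dim(maps_a[[1]])
  if (is.null(shape)) shape <- c(1L, length(maps_a[[1]]))
  d <- vapply(seq_len(n),
              function(s) as.numeric(maps_a[[s]]) - as.numeric(maps_b[[s]]),
              numeric(prod(shape)))
  d <- matrix(d, nrow = prod(shape)) # keep samples x subjects even when 1 sample
  t_flat <- t_from_diffs(t(d))
  array(t_flat, dim = shape)
}

# rows = subjects, cols = samples; paired t against zero
t_from_diffs <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- m / se
  t[se == 0] <- sign(m[se == 0]) * Inf
  t[se == 0 & m == 0] <- 0
  t
}

#' Per-subject activation-vs-baseline paired maps
#'
#' For each subject, pairs every sample of the activation period with
#' that subject's time-averaged baseline value (per channel, and per
#' frequency for time-frequency data), the "activation versus baseline"
#' construction whose paired t feeds the cluster permutation test.
#'
#' @param maps List of per-subject arrays: channels x time or
#'   channels x freqs x times (subject averages, e.g. ERP means or raw
#'   ERSP power).
#' @param times Time axis (s) matching the last dimension.
#' @param activation `c(from, to)` activation window (s).
#' @param baseline `c(from, to)` baseline window (s).
#' @return List with `a` (activation maps) and `b` (matching constant
#'   baseline maps), plus `times` of the activation samples.
#' @export
actvsbl_subject_maps <- function(maps, times, activation, baseline) {
  act_idx <- which(times >= activation[1] & times <= activation[2])
  base_idx <- which(times >= baseline[1] & times <= baseline[2])
  if (!length(act_idx) || !length(base_idx))
    stopf("activation or baseline window outside the data")
  nd <- length(dim(maps[[1]]))
  a <- lapply(maps, function(m) {
    if (nd == 2) m[, act_idx, drop = FALSE] else m[, , act_idx, drop = FALSE]
  })
  b <- lapply(maps, function(m) {
    if (nd == 2) {
      bl <- rowMeans(m[, base_idx, drop = FALSE])
      matrix(bl, nrow = nrow(m), ncol = length(act_idx))
    } else {
      bl <- apply(m[, , base_idx, drop = FALSE], c(1, 2), mean)
      array(bl, dim = c(dim(m)[1:2], length(act_idx)))
    }
  })
  list(a = a, b = b, times = times[act_idx])
}

#' Find signed supra-threshold clusters in a t map
#'
#' Thresholds the t map at `+/- t_crit` and groups the surviving
#' samples into connected sets: samples are adjacent when they share a
#' channel and sit in neighboring time bins, share a time bin on
#' neighboring channels, or (for time-frequency maps) sit in adjacent
#' frequency bins. Positive and negative samples cluster separately;
#' singletons are allowed. Each cluster's summed t value is recorded.
#'
#' @param t_map Array channels x time or channels x freqs x times.
#' @param t_crit Positive threshold (e.g.
#'   `qt(0.975, n_subjects - 1)`, the 97.5th t quantile used with the
#'   2.5th as the two-sided cluster-forming threshold).
#' @param adjacency Channel [build_adjacency()] matrix, or `NULL` for
#'   no spatial neighbors (each channel clusters on its own).
#' @return List of clusters, each a list with `members` (matrix of
#'   array indices), `sign` (+1/-1), `sum` (summed t).
#' @export
find_clusters <- function(t_map, t_crit, adjacency = NULL) {
  dims <- dim(t_map)
  if (is.null(dims)) { dims <- c(1L, length(t_map)); t_map <- array(t_map, dims) }
  nbrs <- if (is.null(adjacency)) {
    rep(list(integer(0)), dims[1])
  } else {
    attr(adjacency, "neighbors")
  }
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(if (sgn > 0) t_map > t_crit else t_map < -t_crit)
    if (!length(supra)) next
    comp <- label_components(supra, dims, nbrs)
    for (cl in split(supra, comp)) {
      out[[length(out) + 1L]] <- list(
        members = arrayInd(cl, dims),
        sign = sgn,
        sum = sum(t_map[cl]))
    }
  }
  out
}

# union-find connected components over linear indices `cells` of an array
# with dims (chan, time) or (chan, freq, time); nbrs = channel neighbor lists
label_components <- function(cells, dims, nbrs) {
  pos <- match(seq_len(prod(dims)), cells) # linear index -> cell rank or NA
  parent <- seq_along(cells)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  nd <- length(dims)
  ind <- arrayInd(cells, dims)
  for (k in seq_along(cells)) {
    ch <- ind[k, 1]
    if (nd == 2) {
      ti <- ind[k, 2]
      if (ti < dims[2]) {
        j <- pos[cells[k] + dims[1]] # next time bin, same channel
        if (!is.na(j)) union_(k, j)
      }
      for (nb in nbrs[[ch]]) { # neighboring channel, same time
        j <- pos[cells[k] + (nb - ch)]
        if (!is.na(j)) union_(k, j)
      }
    } else {
      fi <- ind[k, 2]; ti <- ind[k, 3]
      if (ti < dims[3]) {
        j <- pos[cells[k] + dims[1] * dims[2]]
        if (!is.na(j)) union_(k, j)
      }
      if (fi < dims[2]) {
        j <- pos[cells[k] + dims[1]]
        if (!is.na(j)) union_(k, j)
      }
      for (nb in nbrs[[ch]]) {
        j <- pos[cells[k] + (nb - ch)]
        if (!is.na(j)) union_(k, j)
      }
    }
  }
  vapply(seq_along(cells), find, integer(1))
}

#' Cluster-based permutation test for paired multi-subject maps
#'
#' Nonparametric family-wise-error-controlled test: the observed paired
#' t map is thresholded at the 2.5th/97.5th quantiles of the t
#' distribution with N - 1 df, supra-threshold samples are clustered by
#' spatio-temporal(-spectral) adjacency, and each cluster's summed t is
#' compared against the permutation null of the maximum absolute
#' cluster sum obtained by randomly swapping the two conditions
#' independently per subject (equivalently, sign-flipping each
#' subject's difference map). Every observed cluster is tested against
#' the same max-statistic null, which is what controls the family-wise
#' error. Monte-Carlo p-values use the positively biased estimator
#' `(1 + #(null >= observed)) / (1 + B)` so they are never 0; with
#' `exhaustive = TRUE` (or automatically when `2^N <= n_permutations`)
#' all `2^N` sign assignments are enumerated and the p-value is the
#' exact proportion `#(null >= observed) / 2^N`.
#'
#' @param maps_a,maps_b Per-subject paired maps as in [dependent_t()]
#'   (for activation-vs-baseline designs, build them with
#'   [actvsbl_subject_maps()]).
#' @param adjacency Channel adjacency from [build_adjacency()], or
#'   `NULL`.
#' @param n_permutations Random partitions (default 1000).
#' @param alpha Final two-tailed significance level (default 0.05).
#' @param seed Integer seed for the permutation draws.
#' @param exhaustive `NA` (auto), `TRUE`, or `FALSE`.
#' @return A `cluster_result`: `clusters` (members, sign, sum, p,
#'   significant), `null_max` distribution, `t_crit`, `t_map`, `config`.
#' @export
permutation_test <- function(maps_a, maps_b, adjacency = NULL,
                             n_permutations = 1000, alpha = 0.05, seed = 1,
                             exhaustive = NA) {
  n <- length(maps_a)
  if (n < 2 || length(maps_b) != n) stopf("need >= 2 paired subjects")
  shape <- dim(maps_a[[1]])
  if (is.null(shape)) shape <- c(1L, length(maps_a[[1]]))
  d <- vapply(seq_len(n),
              function(s) as.numeric(maps_a[[s]]) - as.numeric(maps_b[[s]]),
              numeric(prod(shape)))
  d <- t(matrix(d, nrow = prod(shape))) # subjects x samples
  t_crit <- stats::qt(0.975, df = n - 1)

  t_obs <- array(t_from_diffs(d), dim = shape)
  clusters <- find_clusters(t_obs, t_crit, adjacency)

  if (is.na(exhaustive)) exhaustive <- 2^n <= n_permutations
  signs <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    with_seed(seed, matrix(sample(c(1, -1), n * n_permutations, replace = TRUE),
                           ncol = n))
  }
  max_stat <- function(t_flat) {
    cl <- find_clusters(array(t_flat, dim = shape), t_crit, adjacency)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "sum")))
  }
  # per-permutation t maps from flipped differences, fully vectorized:
  # mean and variance of the sign-flipped rows follow from the flipped
  # column means and the (flip-invariant) column means of squares
  msq <- colMeans(d^2)
  m_perm <- (signs %*% d) / n
  null_max <- vapply(seq_len(nrow(signs)), function(b) {
    m <- m_perm[b, ]
    v <- (msq - m^2) * n / (n - 1)
    v[v < 0] <- 0
    se <- sqrt(v / n)
    tt <- m / se
    tt[se == 0] <- sign(m[se == 0]) * Inf
    tt[se == 0 & m == 0] <- 0
    max_stat(tt)
  }, numeric(1))

  for (i in seq_along(clusters)) {
    # tolerance on the tie so identity permutations always count: observed
    # and permuted statistics travel different floating-point paths
    s <- abs(clusters[[i]]$sum) * (1 - 1e-9) - 1e-12
    clusters[[i]]$p <- if (exhaustive) {
      mean(null_max >= s)
    } else {
      (1 + sum(null_max >= s)) / (1 + length(null_max))
    }
    clusters[[i]]$significant <- clusters[[i]]$p < alpha
  }
  ord <- order(-abs(vapply(clusters, `[[`, numeric(1), "sum")))
  structure(list(clusters = clusters[ord], null_max = null_max,
                 t_crit = t_crit, t_map = t_obs, n_subjects = n,
                 config = list(n_permutations = n_permutations, alpha = alpha,
                               seed = seed, exhaustive = exhaustive)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d subjects, %d permutations%s, t_crit %.3f\n",
              x$n_subjects, length(x$null_max),
              if (x$config$exhaustive) " (exhaustive)" else "", x$t_crit))
  if (!length(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else {
    show <- utils::head(seq_along(x$clusters), 8L)
    for (i in show) {
      cl <- x$clusters[[i]]
      cat(sprintf("  cluster %d: sign %+d, %d samples, sum t = %.2f, p = %.4g%s\n",
                  i, cl$sign, nrow(cl$members), cl$sum, cl$p,
                  if (cl$significant) " *" else ""))
    }
    if (length(x$clusters) > 8L)
      cat(sprintf("  ... and %d smaller clusters\n", length(x$clusters) - 8L))
  }
  invisible(x)
}

#' Significant clusters of a result
#' @param result A `cluster_result`.
#' @return The subset of clusters with `p < alpha`.
#' @export
significant_clusters <- function(result) {
  Filter(function(cl) isTRUE(cl$significant), result$clusters)
}

#' Equalize trial counts between two conditions
#'
#' Before a paired comparison the larger side is subsampled uniformly
#' without replacement to the size of the smaller side; the smaller
#' side is untouched.
#'
#' @param epochs_a,epochs_b `eeg_epochs` objects.
#' @param seed Integer seed for the subsample.
#' @return List with `a` and `b`, both with `min(nA, nB)` trials.
#' @export
equalize_trials <- function(epochs_a, epochs_b, seed = 1) {
  na <- n_trials(epochs_a); nb <- n_trials(epochs_b)
  if (na == 0 || nb == 0) stopf("cannot equalize with an empty condition")
  n <- min(na, nb)
  pick <- function(ep, keep) {
    ep$data <- ep$data[keep, , , drop = FALSE]
    ep
  }
  with_seed(seed, {
    a <- if (na > n) pick(epochs_a, sort(sample(na, n))) else epochs_a
    b <- if (nb > n) pick(epochs_b, sort(sample(nb, n))) else epochs_b
    list(a = a, b = b)
  })
}

#' Export a cluster result as JSON
#'
#' @param result A `cluster_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_result <- function(result, path) {
  out <- list(
    n_subjects = result$n_subjects,
    t_crit = result$t_crit,
    config = result$config,
    clusters = lapply(result$clusters, function(cl)
      list(sign = cl$sign, sum = cl$sum, p = cl$p,
           significant = cl$significant,
           members = apply(cl$members, 1, paste, collapse = ","))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
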