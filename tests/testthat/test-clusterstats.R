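test_that("adjacency construction follows the distance threshold", {
  pos <- tiny_positions()
  adj <- suppressWarnings(build_adjacency(pos, threshold = 0.25)) # c isolated
  expect_true(adj["a", "b"] && adj["b", "a"])
  expect_false(adj["a", "c"])
  expect_false(any(diag(unclass(adj))))
  expect_warning(build_adjacency(pos, threshold = 0.0001), "isolated")
  # the full montage at the standard threshold: connected, 5-9 neighbors
  full <- build_adjacency(montage_1010(), 0.4)
  deg <- rowSums(unclass(full))
  expect_gte(mean(deg), 5)
  expect_lte(mean(deg), 9)
  nb <- attr(full, "neighbors")
  seen <- rep(FALSE, nrow(full)); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in nb[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  expect_true(all(seen))
})

test_that("activation-vs-baseline maps pair samples with the subject baseline mean", {
  times <- seq(-1, 1, by = 0.1)
  m1 <- matrix(rep(times, each = 2), 2) + c(0, 10)
  m2 <- m1 + 3
  ab <- actvsbl_subject_maps(list(m1, m2), times, activation = c(0, 1),
                             baseline = c(-1, -0.5))
  # baseline map is constant per channel at the subject's time-average
  base_mean1 <- rowMeans(m1[, times >= -1 & times <= -0.5])
  expect_true(all(ab$b[[1]] == base_mean1))
  expect_equal(dim(ab$a[[1]]), dim(ab$b[[1]]))
  # activation = baseline + c gives constant paired differences
  shifted <- lapply(list(m1, m2), function(m) {
    m[, times >= 0] <- matrix(rowMeans(m[, times >= -1 & times <= -0.5]) + 2,
                              nrow = 2, ncol = sum(times >= 0))
    m
  })
  ab2 <- actvsbl_subject_maps(shifted, times, c(0, 1), c(-1, -0.5))
  d <- ab2$a[[1]] - ab2$b[[1]]
  expect_true(all(abs(d - 2) < 1e-12))
  expect_error(actvsbl_subject_maps(list(m1), times, c(5, 6), c(-1, 0)),
               "outside")
})

test_that("the dependent t map matches closed forms and the textbook test", {
  # identical conditions: t = 0 by the zero-variance convention
  maps <- lapply(1:4, function(i) matrix(rnorm(6), 2, 3))
  t0 <- dependent_t(maps, maps)
  expect_true(all(t0 == 0))
  # constant difference d with per-subject scatter: matches t.test
  set.seed(44)
  base <- lapply(1:6, function(i) matrix(rnorm(4), 2, 2))
  shift <- lapply(base, function(m) m + matrix(rnorm(4, mean = 1), 2, 2))
  tm <- dependent_t(shift, base)
  for (r in 1:2) for (cc in 1:2) {
    a <- vapply(shift, function(m) m[r, cc], numeric(1))
    b <- vapply(base, function(m) m[r, cc], numeric(1))
    expect_equal(tm[r, cc], unname(t.test(a, b, paired = TRUE)$statistic))
  }
  # closed form d * sqrt(N) / s on a hand-built case
  d <- c(1.2, 0.8, 1.1, 0.9)
  tm2 <- dependent_t(lapply(d, function(x) matrix(x, 1, 1)),
                     lapply(d, function(x) matrix(0, 1, 1)))
  expect_equal(as.numeric(tm2), mean(d) * sqrt(4) / sd(d))
})

test_that("cluster finding matches a brute-force flood fill", {
  # hand-built cases
  tm <- matrix(0, 3, 5)
  tm[1, 2] <- 5 # singleton
  expect_length(find_clusters(tm, 3), 1)
  tm[3, 2] <- 5 # same time, non-adjacent channel -> separate cluster
  adj <- suppressWarnings(build_adjacency(tiny_positions(), 0.25))
  expect_length(find_clusters(tm, 3, adj), 2)
  tm[2, 2] <- 5 # b bridges a at the same time
  cl <- find_clusters(tm, 3, adj)
  sizes <- sort(vapply(cl, function(c) nrow(c$members), integer(1)))
  expect_equal(sizes, c(1L, 2L)) # c stays isolated from a-b
  # random maps, 2D and 3D, against the oracle
  set.seed(50)
  for (rep in 1:30) {
    m2 <- array(rnorm(3 * 5, sd = 3), c(3, 5))
    got <- find_clusters(m2, 2.5, adj)
    want <- oracle_clusters(m2, 2.5, unclass(adj))
    key <- function(cl) paste(sort(cl[[if (is.null(cl$cells)) "members" else "cells"]]),
                              collapse = ",")
    got_keys <- sort(vapply(got, function(cl)
      paste(sort((cl$members[, 2] - 1) * 3 + cl$members[, 1]), collapse = ","),
      character(1)))
    want_keys <- sort(vapply(want, function(cl) paste(cl$cells, collapse = ","),
                             character(1)))
    expect_equal(got_keys, want_keys)
    expect_equal(sort(vapply(got, `[[`, numeric(1), "sum")),
                 sort(vapply(want, `[[`, numeric(1), "sum")), tolerance = 1e-12)
  }
  for (rep in 1:10) {
    m3 <- array(rnorm(3 * 4 * 4, sd = 3), c(3, 4, 4))
    got <- find_clusters(m3, 2.5, adj)
    want <- oracle_clusters(m3, 2.5, unclass(adj))
    got_keys <- sort(vapply(got, function(cl)
      paste(sort((cl$members[, 3] - 1) * 12 + (cl$members[, 2] - 1) * 3 +
                   cl$members[, 1]), collapse = ","), character(1)))
    want_keys <- sort(vapply(want, function(cl) paste(cl$cells, collapse = ","),
                             character(1)))
    expect_equal(got_keys, want_keys)
  }
})

test_that("permutation test: null data give no clusters, enumeration is exact", {
  zero <- lapply(1:5, function(i) matrix(0, 2, 6))
  res0 <- permutation_test(zero, zero, n_permutations = 100, seed = 1)
  expect_length(res0$clusters, 0)

  # N = 4: all 16 sign assignments enumerated, p equals the exhaustive oracle
  set.seed(61)
  adj <- suppressWarnings(build_adjacency(tiny_positions(), 0.25))
  for (rep in 1:5) {
    a <- lapply(1:4, function(i) matrix(rnorm(9, mean = 1.2), 3, 3))
    b <- lapply(1:4, function(i) matrix(rnorm(9), 3, 3))
    res <- permutation_test(a, b, adj, n_permutations = 1000, seed = rep,
                            exhaustive = TRUE)
    want <- oracle_exhaustive_p(a, b, qt(0.975, 3), unclass(adj))
    expect_length(res$clusters, length(want))
    got_p <- sort(vapply(res$clusters, `[[`, numeric(1), "p"))
    want_p <- sort(vapply(want, `[[`, numeric(1), "p"))
    expect_equal(got_p, want_p)
  }
})

test_that("negating the data flips cluster signs and preserves p-values", {
  set.seed(77)
  a <- lapply(1:8, function(i) matrix(rnorm(12, mean = 0.8), 2, 6))
  b <- lapply(1:8, function(i) matrix(rnorm(12), 2, 6))
  res <- permutation_test(a, b, n_permutations = 300, seed = 5)
  neg <- permutation_test(lapply(a, `-`), lapply(b, `-`),
                          n_permutations = 300, seed = 5)
  expect_equal(vapply(res$clusters, `[[`, numeric(1), "sum"),
               -vapply(neg$clusters, `[[`, numeric(1), "sum"))
  expect_equal(vapply(res$clusters, `[[`, numeric(1), "p"),
               vapply(neg$clusters, `[[`, numeric(1), "p"))
})

test_that("a planted strong effect is detected with the smallest possible p", {
  set.seed(88)
  # Cohen's d = 2 on half the samples, 16 subjects
  eff <- c(rep(0, 10), rep(2, 10))
  a <- lapply(1:16, function(i) matrix(rnorm(20) + eff, 2, 10))
  b <- lapply(1:16, function(i) matrix(rnorm(20), 2, 10))
  pos2 <- data.frame(label = c("L", "R"), x = c(0, 0.1), y = 0, z = 1)
  res <- permutation_test(a, b, build_adjacency(pos2, 0.4),
                          n_permutations = 500, seed = 7)
  top <- res$clusters[[1]]
  expect_true(top$significant)
  expect_equal(top$p, 1 / 501)
  planted <- which(matrix(eff, 2, 10) > 0)
  covered <- (top$members[, 2] - 1) * 2 + top$members[, 1]
  expect_gte(length(intersect(covered, planted)), 0.8 * length(planted))
})

test_that("trial-count equalization subsamples only the larger side", {
  times <- (0:19) / 100
  big <- eeg_epochs(array(seq_len(50 * 1 * 20), c(50, 1, 20)), times, 100)
  small <- eeg_epochs(array(seq_len(30 * 1 * 20), c(30, 1, 20)), times, 100)
  eq <- equalize_trials(big, small, seed = 3)
  expect_equal(n_trials(eq$a), 30)
  expect_equal(n_trials(eq$b), 30)
  expect_identical(eq$b$data, small$data)
  # the subsample is a subset of original trials
  expect_true(all(eq$a$data[, 1, 1] %in% big$data[, 1, 1]))
  # deterministic under the seed
  eq2 <- equalize_trials(big, small, seed = 3)
  expect_identical(eq$a$data, eq2$a$data)
  # equal sizes pass through untouched
  eq3 <- equalize_trials(small, small, seed = 1)
  expect_identical(eq3$a$data, small$data)
  expect_error(equalize_trials(big, eeg_epochs(array(0, c(0, 1, 20)), times, 100)),
               "empty")
})

test_that("cluster results serialize to JSON with sums and p-values", {
  set.seed(91)
  a <- lapply(1:6, function(i) matrix(rnorm(8, mean = 1.5), 2, 4))
  b <- lapply(1:6, function(i) matrix(rnorm(8), 2, 4))
  res <- permutation_test(a, b, n_permutations = 64, seed = 2)
  path <- tempfile(fileext = ".json")
  write_cluster_result(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_subjects, 6)
  expect_equal(length(back$clusters$p), length(res$clusters))
})
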