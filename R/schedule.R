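#' Build the pseudo-random inter-stimulus-interval schedule
#'
#' The main experiment presents speech snippets in continuous noise over
#' `n_blocks` blocks of `block_length` seconds; each block is tiled by
#' `subblocks_per_block` sub-blocks of `subblock_length` seconds that all
#' share one onset pattern. Within a sub-block the inter-stimulus
#' intervals are short at the beginning and grow toward the end, which
#' manipulates the listener's expectation of hearing a voice. All ISIs
#' (including the wrap across sub-block boundaries) lie in
#' `[isi_min, isi_max]`.
#'
#' The per-sub-block pattern is drawn once from the seeded generator:
#' `n_per_subblock` gaps are sampled uniformly in `[isi_min, isi_max]`
#' and rescaled (by rejection) to sum to `subblock_length`; sorted
#' ascending they become the within-sub-block ISIs, the smallest gap
#' doubling as the boundary gap. The defaults give 3 blocks x 12
#' sub-blocks x 5 onsets = 180 stimulus onsets over 30 minutes.
#'
#' @param block_length Block length in seconds (default 600).
#' @param n_blocks Number of blocks (default 3).
#' @param subblock_length Sub-block length in seconds (default 50).
#' @param subblocks_per_block Sub-blocks per block (default 12).
#' @param n_per_subblock Stimulus onsets per sub-block (default 5).
#' @param isi_min,isi_max ISI bounds in seconds (defaults 3 and 19).
#' @param seed Integer seed for the pattern draw.
#' @return An `isi_schedule`: list with `onsets` (s), the per-sub-block
#'   `pattern` of onset offsets, and the configuration fields.
#' @export
build_isi_schedule <- function(block_length = 600, n_blocks = 3,
                               subblock_length = 50, subblocks_per_block = 12,
                               n_per_subblock = 5, isi_min = 3, isi_max = 19,
                               seed = 1) {
  if (subblock_length * subblocks_per_block != block_length)
    stopf("sub-blocks (%g x %g s) do not tile the block (%g s)",
          subblocks_per_block, subblock_length, block_length)
  if (n_per_subblock * isi_min > subblock_length ||
      n_per_subblock * isi_max < subblock_length)
    stopf("%d ISIs in [%g, %g] s cannot sum to the %g s sub-block",
          n_per_subblock, isi_min, isi_max, subblock_length)

  gaps <- with_seed(seed, {
    for (i in seq_len(10000)) {
      g <- stats::runif(n_per_subblock, isi_min, isi_max)
      g <- g * subblock_length / sum(g)
      if (all(g >= isi_min & g <= isi_max)) break
      g <- NULL
    }
    g
  })
  if (is.null(gaps)) stopf("could not sample a feasible ISI pattern")
  gaps <- sort(gaps)
  # offsets within a sub-block; shifting by gaps[1]/2 makes the gap across
  # the sub-block boundary exactly gaps[1], keeping every ISI in range
  pattern <- cumsum(gaps) - gaps[1] / 2

  starts <- seq(0, by = subblock_length,
                length.out = n_blocks * subblocks_per_block)
  onsets <- as.numeric(outer(pattern, starts, `+`))
  onsets <- sort(onsets)

  structure(list(onsets = onsets, pattern = pattern,
                 block_length = block_length, n_blocks = n_blocks,
                 subblock_length = subblock_length,
                 subblocks_per_block = subblocks_per_block,
                 isi_min = isi_min, isi_max = isi_max, seed = seed),
            class = "isi_schedule")
}

#' @export
print.isi_schedule <- function(x, ...) {
  isis <- diff(x$onsets)
  cat(sprintf("<isi_schedule> %d onsets, %d x %d sub-blocks of %g s, ISI %.2f-%.2f s\n",
              length(x$onsets), x$n_blocks, x$subblocks_per_block,
              x$subblock_length, min(isis), max(isis)))
  invisible(x)
}
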