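#' Read a BrainVision recording
#'
#' Minimal reader for the BrainVision Core format (as written by
#' BrainAmp systems): an INI-style text header (`.vhdr`) naming the
#' data/marker files, a binary or ASCII data file, and an optional
#' marker file (`.vmrk`). Supported data layouts: binary
#' `IEEE_FLOAT_32` or `INT_16` (multiplexed or vectorized,
#' little-endian) and `ASCII`. Channel resolutions (microvolts per bit)
#' are applied.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return An `eeg_recording` with attribute `markers`: data frame of
#'   `type`, `description`, `onset_s` (from the `.vmrk` file, if any).
#' @export
read_brainvision <- function(vhdr_path) {
  hdr <- parse_bv_ini(vhdr_path)
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stopf("not a BrainVision header: %s", vhdr_path)
  dir <- dirname(vhdr_path)
  n_chan <- as.integer(ci[["NumberOfChannels"]])
  rate <- 1e6 / as.numeric(ci[["SamplingInterval"]]) # header stores microseconds
  orientation <- toupper(ci[["DataOrientation"]] %||% "MULTIPLEXED")
  format <- toupper(ci[["DataFormat"]] %||% "BINARY")

  chans <- hdr[["Channel Infos"]]
  labels <- character(n_chan); res <- rep(1, n_chan)
  for (i in seq_len(n_chan)) {
    parts <- strsplit(chans[[sprintf("Ch%d", i)]], ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }

  data_file <- file.path(dir, ci[["DataFile"]])
  if (format == "BINARY") {
    bfmt <- toupper(hdr[["Binary Infos"]][["BinaryFormat"]] %||% "IEEE_FLOAT_32")
    size <- if (bfmt == "INT_16") 2L else 4L
    what <- if (bfmt == "INT_16") integer() else numeric()
    n_total <- file.info(data_file)$size / size
    raw <- readBin(data_file, what = what, n = n_total, size = size,
                   endian = "little")
    n_samp <- length(raw) %/% n_chan
    m <- if (orientation == "VECTORIZED") {
      t(matrix(raw, nrow = n_samp, ncol = n_chan))
    } else {
      matrix(raw, nrow = n_chan, ncol = n_samp)
    }
  } else if (format == "ASCII") {
    tab <- utils::read.table(data_file, header = FALSE,
                             skip = as.integer(hdr[["ASCII Infos"]][["SkipLines"]] %||% "0"))
    m <- if (orientation == "VECTORIZED") as.matrix(tab) else t(as.matrix(tab))
    if (nrow(m) != n_chan) m <- t(m)
  } else stopf("unsupported DataFormat '%s'", format)
  m <- m * res

  rec <- eeg_recording(m, rate, channels = labels)
  vmrk <- ci[["MarkerFile"]]
  if (!is.null(vmrk) && file.exists(file.path(dir, vmrk))) {
    attr(rec, "markers") <- parse_bv_markers(file.path(dir, vmrk), rate)
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_bv_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*($|;)", lines)]
  out <- list(); section <- "GLOBAL"
  for (ln in lines) {
    if (grepl("^\\s*\\[", ln)) {
      section <- gsub("^\\s*\\[|\\]\\s*$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      out[[section]][[key]] <- trimws(substr(ln, eq + 1, nchar(ln)))
    }
  }
  out
}

parse_bv_markers <- function(path, rate) {
  hdr <- parse_bv_ini(path)
  mk <- hdr[["Marker Infos"]]
  if (is.null(mk) || length(mk) == 0L)
    return(data.frame(type = character(0), description = character(0),
                      onset_s = numeric(0)))
  rows <- lapply(mk, function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    data.frame(type = parts[1], description = parts[2],
               onset_s = (as.numeric(parts[3]) - 1) / rate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
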