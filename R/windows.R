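#' Tile a chromosome with half-open windows
#'
#' Windows are 0-based half-open `[start, end)` intervals of width `size`
#' starting at 0, `step`, 2 `step`, ... . A trailing partial window is kept
#' only when it covers sequence beyond the last full window and is at least
#' `size / 2` long; shorter tails are dropped (with a message). `step > size`
#' would create silent gaps and is an error.
#'
#' @param chrom_length chromosome length in bp.
#' @param size window size in bp.
#' @param step distance between successive window starts (default `size`,
#'   i.e. non-overlapping tiling).
#' @param chrom chromosome name stored in the result.
#' @return data.frame with columns `chrom`, `start`, `end`, `label`
#'   (initialised to "unknown").
#' @export
make_windows <- function(chrom_length, size, step = size, chrom = "chr") {
  if (size <= 0) stop("size must be > 0")
  if (step <= 0 || step > size) stop("need 0 < step <= size (step > size would leave gaps)")
  starts <- seq(0L, max(0L, chrom_length - 1L), by = step)
  ends <- pmin(starts + size, chrom_length)
  full <- (ends - starts) == size
  keep <- full
  if (any(full)) {
    max_full_end <- max(ends[full])
    tail_ok <- !full & ends > max_full_end & (ends - starts) >= size / 2
    keep <- full | tail_ok
  } else {
    keep <- (ends - starts) >= size / 2
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("make_windows: dropped %d partial window(s)", n_drop))
  }
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             label = "unknown", stringsAsFactors = FALSE)
}

#' Label windows as SDR / PAR / autosome
#'
#' A window on the focal (sex) chromosome is labelled `SDR` when its midpoint
#' falls inside the recombination-suppressed interval `[sdr_start, sdr_end)`,
#' otherwise `PAR`. Windows on other chromosomes are labelled `autosome`.
#'
#' @param windows data.frame from [make_windows()].
#' @param sdr_start,sdr_end 0-based half-open SDR interval, or NULL for an
#'   autosome.
#' @return the windows data.frame with `label` filled in.
#' @export
label_windows <- function(windows, sdr_start = NULL, sdr_end = NULL) {
  if (is.null(sdr_start)) {
    windows$label <- "autosome"
    return(windows)
  }
  if (sdr_start >= sdr_end) stop("sdr_start must be < sdr_end")
  mid <- (windows$start + windows$end) / 2
  windows$label <- ifelse(mid >= sdr_start & mid < sdr_end, "SDR", "PAR")
  windows
}
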