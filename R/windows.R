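#' Enumerate sliding windows over contigs
#'
#' Windows start at 1, 1+step, 1+2*step, ... while the start does not
#' exceed the contig length; the final windows are truncated at the contig
#' end. Defaults are 100-kb windows advanced in 10-kb steps.
#'
#' @param contig_lengths named numeric vector (contig -> length bp).
#' @param size window size in bp (default 100000).
#' @param step step size in bp (default 10000); must satisfy
#'   \code{size >= step > 0}.
#' @param drop_tails drop windows truncated below \code{size} bp.
#' @return data.frame with columns \code{contig}, \code{start}, \code{end}
#'   (1-based inclusive) and \code{length}.
#' @export
enumerate_windows <- function(contig_lengths, size = 100000L,
                              step = 10000L, drop_tails = FALSE) {
  if (length(contig_lengths) == 0) stop("empty contig set")
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths)))) {
    stop("contig_lengths must be named")
  }
  stopifnot(size >= step, step > 0)
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(1, len, by = step)
    ends <- pmin(starts + size - 1, len)
    data.frame(contig = ctg, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$length <- out$end - out$start + 1
  if (drop_tails) out <- out[out$length == size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sum per-site values over (possibly overlapping) windows in O(sites + windows)
# via per-contig cumulative sums. `values`: matrix sites x k (NA = unusable,
# contributes nothing and is not counted).
window_site_sums <- function(sites, values, windows) {
  values <- as.matrix(values)
  usable <- stats::complete.cases(values)
  k <- ncol(values)
  sums <- matrix(0, nrow(windows), k)
  counts <- integer(nrow(windows))
  for (ctg in unique(windows$contig)) {
    sel <- which(sites$contig == ctg & usable)
    widx <- which(windows$contig == ctg)
    if (!length(widx)) next
    pos <- sites$pos[sel]
    cs <- apply(values[sel, , drop = FALSE], 2, function(v) cumsum(v))
    cs <- rbind(0, matrix(cs, ncol = k))
    lo <- findInterval(windows$start[widx] - 0.5, pos)   # sites before window
    hi <- findInterval(windows$end[widx] + 0.5, pos)     # sites up to window end
    counts[widx] <- hi - lo
    sums[widx, ] <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  }
  list(sums = sums, n_snps = counts)
}
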