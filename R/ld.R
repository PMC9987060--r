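#' Composite genotype r-squared between two sites
#'
#' Squared Pearson correlation of alt-allele dosages over jointly called
#' samples (Rogers-Huff composite LD) -- the phase-free analogue of the
#' squared allele-frequency correlation. Undefined (NA) when fewer than
#' two jointly called samples remain or either site is monomorphic among
#' them.
#'
#' @param dosages_i,dosages_j integer dosage vectors (0/1/2/NA), same
#'   samples.
#' @return numeric in [0, 1], or NA when undefined.
#' @export
genotype_r2 <- function(dosages_i, dosages_j) {
  stopifnot(length(dosages_i) == length(dosages_j))
  ok <- !is.na(dosages_i) & !is.na(dosages_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- dosages_i[ok]; y <- dosages_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD decay: mean r-squared in distance bins
#'
#' All intra-contig site pairs separated by at most \code{max_dist} bp are
#' pooled genome-wide into contiguous distance bins; pairs with undefined
#' r-squared (monomorphic among jointly called samples) are skipped and
#' counted separately.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param popmap named character vector (sample -> population).
#' @param pop population label whose samples are used.
#' @param max_dist maximum pair separation in bp (default 100000).
#' @param bin bin width in bp (default 1000).
#' @return data.frame with one row per nonempty bin: \code{dist_lo},
#'   \code{dist_hi} (bp, [lo, hi)), \code{mid}, \code{mean_r2},
#'   \code{n_pairs}. Attribute \code{"n_skipped"} counts undefined pairs.
#' @export
ld_decay <- function(G, popmap, pop, max_dist = 100000L, bin = 1000L) {
  stopifnot(inherits(G, "genotype_matrix"), max_dist > 0, bin > 0)
  ids <- names(popmap)[popmap == pop]
  ids <- intersect(G$samples, ids)
  if (!length(ids)) stop("population '", pop, "' has no samples")
  calls <- G$calls[ids, , drop = FALSE]

  n_bins <- ceiling(max_dist / bin)
  sum_r2 <- numeric(n_bins)
  n_pairs <- integer(n_bins)
  n_skipped <- 0L
  for (ctg in names(G$contig_lengths)) {
    idx <- which(G$sites$contig == ctg)
    if (length(idx) < 2) next
    pos <- G$sites$pos[idx]
    X <- calls[, idx, drop = FALSE]
    M <- !is.na(X)
    X0 <- X; X0[!M] <- 0L
    storage.mode(X0) <- "double"
    storage.mode(M) <- "double"
    S <- length(idx)
    # all pairs k sites apart at once; min separation grows with k, so
    # stop at the first offset whose closest pair exceeds max_dist
    for (k in seq_len(S - 1)) {
      d <- pos[(k + 1):S] - pos[1:(S - k)]
      if (min(d) > max_dist) break
      keep <- which(d <= max_dist)
      if (!length(keep)) next
      i <- keep; j <- keep + k
      MA <- M[, i, drop = FALSE];  MB <- M[, j, drop = FALSE]
      A <- X0[, i, drop = FALSE] * MB
      B <- X0[, j, drop = FALSE] * MA
      n <- colSums(MA * MB)
      sx <- colSums(A);  sy <- colSums(B)
      sxx <- colSums(A * A);  syy <- colSums(B * B)
      sxy <- colSums(A * B)
      vx <- n * sxx - sx^2
      vy <- n * syy - sy^2
      ok <- n >= 2 & vx > 0 & vy > 0
      n_skipped <- n_skipped + sum(!ok)
      if (!any(ok)) next
      r2 <- (n[ok] * sxy[ok] - sx[ok] * sy[ok])^2 / (vx[ok] * vy[ok])
      b <- pmin(n_bins, d[keep][ok] %/% bin + 1L)
      bt <- tabulate(b, n_bins)
      sum_r2 <- sum_r2 + unname(tapply_sum(r2, b, n_bins))
      n_pairs <- n_pairs + bt
    }
  }
  if (sum(n_pairs) == 0) stop("no valid site pairs within max_dist")
  keep <- n_pairs > 0
  out <- data.frame(dist_lo = (which(keep) - 1L) * bin,
                    dist_hi = pmin(which(keep) * bin, max_dist),
                    mean_r2 = sum_r2[keep] / n_pairs[keep],
                    n_pairs = n_pairs[keep])
  out$mid <- (out$dist_lo + out$dist_hi) / 2
  out <- out[, c("dist_lo", "dist_hi", "mid", "mean_r2", "n_pairs")]
  attr(out, "n_skipped") <- n_skipped
  out
}

# grouped sum into a fixed number of bins (vapply-free rowsum wrapper)
tapply_sum <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Distance at which mean r-squared falls to half its maximum
#'
#' Scans the binned decay curve for the first bin whose mean r-squared is
#' at or below half the maximum bin mean, interpolating linearly between
#' that bin's midpoint and the previous one. Returns \code{Inf} when the
#' curve never reaches half-maximum within the binned range.
#'
#' @param bins data.frame from \code{\link{ld_decay}}.
#' @return distance in bp (possibly \code{Inf}).
#' @export
half_decay_distance <- function(bins) {
  stopifnot(nrow(bins) >= 2)
  half <- max(bins$mean_r2) / 2
  below <- which(bins$mean_r2 <= half)
  if (!length(below)) return(Inf)
  i <- below[1]
  if (i == 1) return(bins$mid[1])
  x0 <- bins$mid[i - 1]; y0 <- bins$mean_r2[i - 1]
  x1 <- bins$mid[i];     y1 <- bins$mean_r2[i]
  if (y0 == y1) return(x1)
  x0 + (y0 - half) / (y0 - y1) * (x1 - x0)
}
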