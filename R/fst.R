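#' Weir-Cockerham variance components at single sites
#'
#' The two-population diploid variance-component decomposition of
#' Weir & Cockerham (1984): per site, the among-population (a),
#' among-individual-within-population (b) and within-individual (c)
#' components, computed from diploid sample sizes, alt-allele frequencies
#' and observed heterozygosity. The F_ST estimate at a site is
#' a / (a + b + c); windows combine sites by summing numerators and
#' denominators separately ("ratio of sums").
#'
#' @param freqA,freqB per-site frequency tables for the two populations,
#'   as returned by \code{\link{site_frequencies}} on the same matrix.
#' @return data.frame with columns \code{a}, \code{b}, \code{c} (NA at
#'   sites unusable in either population).
#' @export
site_fst_components <- function(freqA, freqB) {
  stopifnot(nrow(freqA) == nrow(freqB))
  n1 <- freqA$n_called; n2 <- freqB$n_called
  p1 <- freqA$p_alt;    p2 <- freqB$p_alt
  h1 <- freqA$n_het / pmax(n1, 1L)
  h2 <- freqB$n_het / pmax(n2, 1L)
  usable <- freqA$usable & freqB$usable

  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  a[!usable] <- NA_real_
  b[!usable] <- NA_real_
  cc[!usable] <- NA_real_
  data.frame(a = a, b = b, c = cc)
}

# Hudson-estimator per-site numerator/denominator (Bhatia et al. 2013 form),
# used as an optional estimator and as a cross-check on Weir-Cockerham.
site_hudson_components <- function(freqA, freqB) {
  n1h <- 2 * freqA$n_called; n2h <- 2 * freqB$n_called
  p1 <- freqA$p_alt; p2 <- freqB$p_alt
  usable <- freqA$usable & freqB$usable
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1h - 1) - p2 * (1 - p2) / (n2h - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!usable] <- NA_real_
  den[!usable] <- NA_real_
  data.frame(num = num, den = den)
}

fst_site_parts <- function(G, popmap, popA, popB,
                           estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  fa <- site_frequencies(G, popA, popmap)
  fb <- site_frequencies(G, popB, popmap)
  if (estimator == "wc") {
    comp <- site_fst_components(fa, fb)
    data.frame(num = comp$a, den = comp$a + comp$b + comp$c)
  } else {
    comp <- site_hudson_components(fa, fb)
    data.frame(num = comp$num, den = comp$den)
  }
}

#' Windowed F_ST between two populations
#'
#' Per window, F_ST = sum(a) / sum(a+b+c) over the usable sites it contains
#' (Weir-Cockerham; ratio of sums), or the analogous Hudson ratio with
#' \code{estimator = "hudson"}. Windows with fewer than \code{min_snps}
#' usable sites, or a zero denominator, are masked (NA). Small negative
#' values are legitimate estimator output near zero differentiation and
#' are not clamped.
#'
#' @param G a \code{\link{genotype_matrix}} (already site-filtered).
#' @param popmap named character vector (sample -> population).
#' @param popA,popB population labels.
#' @param windows data.frame from \code{\link{enumerate_windows}}.
#' @param min_snps minimum usable SNPs per window (default 10).
#' @param estimator \code{"wc"} (Weir-Cockerham, default) or
#'   \code{"hudson"}.
#' @return data.frame: the windows plus \code{n_snps} and \code{fst}.
#' @export
windowed_fst <- function(G, popmap, popA, popB, windows, min_snps = 10L,
                         estimator = c("wc", "hudson")) {
  parts <- fst_site_parts(G, popmap, popA, popB, estimator)
  ws <- window_site_sums(G$sites, parts, windows)
  fst <- ws$sums[, 1] / ws$sums[, 2]
  fst[ws$n_snps < min_snps | ws$sums[, 2] == 0] <- NA_real_
  if (all(is.na(fst))) {
    warning("windowed_fst: every window is masked (min_snps = ",
            min_snps, ")")
  }
  out <- windows
  out$n_snps <- ws$n_snps
  out$fst <- fst
  out
}

#' Genome-wide F_ST between two populations
#'
#' Single ratio-of-sums value over all usable sites.
#'
#' @inheritParams windowed_fst
#' @return numeric scalar.
#' @export
genomewide_fst <- function(G, popmap, popA, popB,
                           estimator = c("wc", "hudson")) {
  parts <- fst_site_parts(G, popmap, popA, popB, estimator)
  sum(parts$num, na.rm = TRUE) / sum(parts$den, na.rm = TRUE)
}

#' Pairwise genome-wide F_ST matrix across populations
#'
#' Ratio-of-sums F_ST for every population pair, plus each population's
#' mean F_ST against all others and a differentiation class using the
#' conventional 0.15 cutoff (populations with mean F_ST > 0.15 are called
#' highly differentiated).
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param popmap named character vector (sample -> population).
#' @param estimator \code{"wc"} or \code{"hudson"}.
#' @return list with \code{fst} (symmetric matrix, zero diagonal),
#'   \code{mean_fst} (named vector) and \code{class} (named character,
#'   \code{"high"}/\code{"low"}).
#' @export
pairwise_fst_matrix <- function(G, popmap, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  pops <- sort(unique(unname(popmap)))
  if (length(pops) < 2) stop("need at least 2 populations")
  freqs <- lapply(pops, function(p) site_frequencies(G, p, popmap))
  names(freqs) <- pops
  for (p in pops) {
    if (!any(freqs[[p]]$usable)) stop("population '", p, "' has no usable sites")
  }
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1]) {
    for (j in seq_len(i - 1)) {
      if (estimator == "wc") {
        comp <- site_fst_components(freqs[[i]], freqs[[j]])
        v <- sum(comp$a, na.rm = TRUE) /
          sum(comp$a + comp$b + comp$c, na.rm = TRUE)
      } else {
        comp <- site_hudson_components(freqs[[i]], freqs[[j]])
        v <- sum(comp$num, na.rm = TRUE) / sum(comp$den, na.rm = TRUE)
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  mean_fst <- vapply(seq_along(pops),
                     function(i) mean(m[i, -i]), numeric(1))
  names(mean_fst) <- pops
  list(fst = m, mean_fst = mean_fst,
       class = ifelse(mean_fst > 0.15, "high", "low"))
}
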