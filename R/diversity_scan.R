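#' Windowed nucleotide diversity (pi) for one population
#'
#' Per site, pi is the unbiased mean pairwise difference among the 2n
#' called haplotypes, (2n/(2n-1)) * 2 p (1-p) with n called diploids;
#' window pi is the sum of site values divided by the window length in bp
#' (per-bp diversity, so truncated tail windows are normalized by their
#' true length). Sites unusable in the population (< 2 called diploids)
#' contribute nothing.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param popmap named character vector (sample -> population).
#' @param pop population label.
#' @param windows data.frame from \code{\link{enumerate_windows}}.
#' @param min_snps windows with fewer usable SNPs are masked (default 0,
#'   i.e. monomorphic windows legitimately report pi = 0).
#' @return data.frame: the windows plus \code{n_snps} and \code{pi}.
#' @export
windowed_pi <- function(G, popmap, pop, windows, min_snps = 0L) {
  f <- site_frequencies(G, pop, popmap)
  nh <- 2 * f$n_called
  pi_site <- (nh / (nh - 1)) * 2 * f$p_alt * (1 - f$p_alt)
  pi_site[!f$usable] <- NA_real_
  ws <- window_site_sums(G$sites, matrix(pi_site, ncol = 1), windows)
  pi <- ws$sums[, 1] / windows$length
  pi[ws$n_snps < min_snps] <- NA_real_
  out <- windows
  out$n_snps <- ws$n_snps
  out$pi <- pi
  out
}

#' Log ratio of reference to focal nucleotide diversity
#'
#' ln(pi_ref / pi_focal) per window. Oriented so that diversity loss in the
#' focal (scanned) population -- the sweep signature -- gives large positive
#' scores. Masked (NA) where either pi is missing or zero.
#'
#' @param pi_ref,pi_focal numeric vectors of per-window pi (reference and
#'   focal populations, same windows).
#' @return numeric vector of scores.
#' @export
pi_lnratio <- function(pi_ref, pi_focal) {
  stopifnot(length(pi_ref) == length(pi_focal))
  out <- log(pi_ref / pi_focal)
  out[is.na(pi_ref) | is.na(pi_focal) | pi_ref <= 0 | pi_focal <= 0] <- NA_real_
  out
}
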