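#' Filter SNP sites by missingness and minor allele frequency
#'
#' Site-level hard filters applied to the pooled sample set before any
#' per-population statistic: a site is kept iff its missing-call fraction
#' is strictly below \code{max_missing} AND its pooled minor allele
#' frequency is strictly above \code{min_maf}. MAF is computed from
#' non-missing calls across all samples pooled, so monomorphic sites are
#' always removed by the MAF rule.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param max_missing maximum tolerated missing fraction (default 0.20).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return The filtered \code{genotype_matrix}, with an attribute
#'   \code{"removed"}: counts \code{c(missing = , maf = )} (a site failing
#'   both is counted under \code{missing}).
#' @export
filter_sites <- function(G, max_missing = 0.20, min_maf = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"),
            max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 1)
  n <- nrow(G$calls)
  n_miss <- colSums(is.na(G$calls))
  miss_frac <- n_miss / n
  n_called <- n - n_miss
  p <- colSums(G$calls, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  p[n_called == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  pass_miss <- miss_frac < max_missing
  pass_maf <- !is.na(maf) & maf > min_maf
  keep <- pass_miss & pass_maf
  removed <- c(missing = sum(!pass_miss),
               maf = sum(pass_miss & !pass_maf))
  if (!any(keep)) {
    warning("filter_sites: all ", length(keep), " sites removed")
  }
  out <- subset_genotypes(G, sites = keep)
  attr(out, "removed") <- removed
  out
}

#' Per-site allele frequencies within one population
#'
#' The shared kernel behind Ho/He/PIC, nucleotide diversity and F_ST:
#' counts of called diploids, alt-allele frequency and heterozygote counts
#' per site, restricted to the samples of one population. Sites with fewer
#' than two called diploids are flagged unusable.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param pop population label.
#' @param popmap named character vector mapping sample id to population
#'   (as returned by \code{\link{read_popmap}}).
#' @return data.frame with one row per site: \code{n_called}, \code{p_alt},
#'   \code{n_het}, \code{usable}.
#' @export
site_frequencies <- function(G, pop, popmap) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- names(popmap)[popmap == pop]
  ids <- intersect(G$samples, ids)
  if (!length(ids)) stop("population '", pop, "' has no samples in the matrix")
  calls <- G$calls[ids, , drop = FALSE]
  n_called <- colSums(!is.na(calls))
  p_alt <- colSums(calls, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  p_alt[n_called == 0] <- NA_real_
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  data.frame(n_called = n_called, p_alt = p_alt, n_het = n_het,
             usable = n_called >= 2L, row.names = NULL)
}

# Botstein PIC, biallelic closed form: 1 - (p^2 + q^2) - 2 p^2 q^2
pic_biallelic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Per-population diversity report (Ho, He, PIC)
#'
#' For every population: observed heterozygosity Ho = n_het / n_called,
#' expected heterozygosity He = 2p(1-p) and polymorphism information
#' content PIC = 1 - (p^2+q^2) - 2p^2q^2, each an unweighted mean over the
#' sites usable in that population (>= 2 called diploids). Rows are sorted
#' by PIC ascending; a final \code{Mean} row holds the unweighted mean over
#' populations.
#'
#' @param G a filtered \code{\link{genotype_matrix}}.
#' @param popmap named character vector (sample -> population).
#' @return data.frame with columns \code{population}, \code{n_sites},
#'   \code{Ho}, \code{He}, \code{PIC}.
#' @export
diversity_report <- function(G, popmap) {
  pops <- sort(unique(unname(popmap)))
  rows <- lapply(pops, function(pop) {
    f <- site_frequencies(G, pop, popmap)
    f <- f[f$usable, , drop = FALSE]
    if (nrow(f) == 0) {
      stop("population '", pop, "' has no usable sites")
    }
    p <- f$p_alt
    data.frame(population = pop, n_sites = nrow(f),
               Ho = mean(f$n_het / f$n_called),
               He = mean(2 * p * (1 - p)),
               PIC = mean(pic_biallelic(p)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$PIC), , drop = FALSE]
  mean_row <- data.frame(population = "Mean", n_sites = NA_integer_,
                         Ho = mean(out$Ho), He = mean(out$He),
                         PIC = mean(out$PIC), stringsAsFactors = FALSE)
  out <- rbind(out, mean_row)
  rownames(out) <- NULL
  out
}
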