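#' Configuration for the structured-population simulator
#'
#' The generator emulates the study design the scan is built for: K
#' populations of diploid individuals genotyped at biallelic SNPs, with
#' background differentiation following the Balding-Nichols model
#' (per-population allele frequencies drawn Beta(p(1-F)/F, (1-p)(1-F)/F)
#' around an ancestral frequency p ~ Uniform(0.05, 0.95), so the expected
#' F_ST is approximately F), uniform random missingness, and planted
#' "sweep" intervals inside which the focal population's allele
#' frequencies are pushed to within \code{eps} of fixation -- locally
#' erasing its diversity and inflating differentiation, the signature the
#' scan detects. Genes are tiled deterministically so region-to-gene
#' mapping has a known truth.
#'
#' The defaults are the benchmark fixture used throughout the test suite:
#' one 2-Mb contig, 20,000 SNPs, a reference and a focal population of 20
#' diploids each at background F = 0.05, 2% missingness, and three planted
#' 100-kb sweeps in the focal population.
#'
#' @param seed integer RNG seed; the same seed yields byte-identical VCF
#'   output.
#' @param contigs named numeric vector of contig lengths (bp).
#' @param n_sites total SNP count across contigs.
#' @param populations data.frame with columns \code{label}, \code{n}
#'   (diploids) and \code{F} (Balding-Nichols differentiation in (0,1)).
#'   The first row is taken as the reference population.
#' @param sweeps data.frame with columns \code{pop}, \code{contig},
#'   \code{start}, \code{end}, \code{eps} (minor-allele ceiling near
#'   fixation, default 0.02), or NULL for no sweeps.
#' @param missing_rate per-call missingness probability.
#' @param gene_length,gene_spacing deterministic gene tiling (bp).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 42L,
                       contigs = c(chr1 = 2e6),
                       n_sites = 20000L,
                       populations = data.frame(
                         label = c("SZ", "JL"), n = c(20L, 20L),
                         F = c(0.05, 0.05)),
                       sweeps = data.frame(
                         pop = "JL", contig = "chr1",
                         start = c(400001L, 1000001L, 1600001L),
                         end = c(500000L, 1100000L, 1700000L),
                         eps = 0.02),
                       missing_rate = 0.02,
                       gene_length = 5000L, gene_spacing = 15000L) {
  stopifnot(is.numeric(contigs), length(contigs) >= 1,
            !is.null(names(contigs)),
            n_sites >= 1, sum(populations$n) >= 2,
            all(populations$F > 0), all(populations$F < 1),
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(sweeps) && nrow(sweeps)) {
    if (is.null(sweeps$eps)) sweeps$eps <- 0.02
    stopifnot(all(sweeps$eps < 0.5),
              all(sweeps$pop %in% populations$label),
              all(sweeps$contig %in% names(contigs)),
              all(sweeps$start >= 1),
              all(sweeps$end <= contigs[sweeps$contig]),
              all(sweeps$start <= sweeps$end))
  }
  structure(list(seed = as.integer(seed), contigs = contigs,
                 n_sites = as.integer(n_sites), populations = populations,
                 sweeps = sweeps, missing_rate = missing_rate,
                 gene_length = as.integer(gene_length),
                 gene_spacing = as.integer(gene_spacing)),
            class = "sim_config")
}

#' Simulate a structured population with planted sweeps
#'
#' See \code{\link{sim_config}} for the generative model. Monomorphic
#' realized sites are retained (real variant sets contain them and the MAF
#' filter must remove them).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{G} (\code{\link{genotype_matrix}}),
#'   \code{popmap} (named character), \code{genes} (data.frame of gene
#'   models), and \code{truth}: planted \code{regions}, overlapping
#'   \code{gene_ids}, \code{realized_fst} (genome-wide Hudson F_ST of each
#'   population vs the reference) and \code{sweep_pi} (mean focal and
#'   reference pi inside each planted region).
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_sites
  pops <- config$populations

  # site positions: allocated to contigs proportional to length
  alloc <- round(S * config$contigs / sum(config$contigs))
  alloc[length(alloc)] <- S - sum(alloc[-length(alloc)])
  sites <- do.call(rbind, lapply(names(config$contigs), function(ctg) {
    data.frame(contig = ctg,
               pos = sort(sample.int(config$contigs[[ctg]], alloc[[ctg]])),
               stringsAsFactors = FALSE)
  }))
  base <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
  alt_shift <- sample.int(3, S, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  sites$ref <- base
  sites$alt <- bases[(match(base, bases) - 1L + alt_shift) %% 4L + 1L]

  p_anc <- stats::runif(S, 0.05, 0.95)
  calls_by_pop <- vector("list", nrow(pops))
  popmap <- character(0)
  for (k in seq_len(nrow(pops))) {
    F <- pops$F[k]
    pk <- stats::rbeta(S, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    if (!is.null(config$sweeps) && nrow(config$sweeps)) {
      sw <- config$sweeps[config$sweeps$pop == pops$label[k], , drop = FALSE]
      for (r in seq_len(nrow(sw))) {
        in_sw <- sites$contig == sw$contig[r] &
          sites$pos >= sw$start[r] & sites$pos <= sw$end[r]
        if (!any(in_sw)) next
        target <- ifelse(pk[in_sw] >= 0.5, 1, 0)
        pk[in_sw] <- abs(target - stats::runif(sum(in_sw)) * sw$eps[r])
      }
    }
    nk <- pops$n[k]
    gk <- matrix(stats::rbinom(nk * S, 2L, rep(pk, each = nk)), nrow = nk)
    if (config$missing_rate > 0) {
      gk[stats::runif(nk * S) < config$missing_rate] <- NA_integer_
    }
    rownames(gk) <- sprintf("%s_%02d", pops$label[k], seq_len(nk))
    calls_by_pop[[k]] <- gk
    popmap <- c(popmap,
                stats::setNames(rep(pops$label[k], nk), rownames(gk)))
  }
  calls <- do.call(rbind, calls_by_pop)
  G <- genotype_matrix(calls, sites, contig_lengths = config$contigs)

  genes <- tile_genes(config$contigs, config$gene_length,
                      config$gene_spacing)

  truth <- NULL
  if (!is.null(config$sweeps) && nrow(config$sweeps)) {
    regions <- data.frame(contig = config$sweeps$contig,
                          start = config$sweeps$start,
                          end = config$sweeps$end,
                          name = paste0("sweep_", seq_len(nrow(config$sweeps))),
                          stringsAsFactors = FALSE)
    truth_genes <- genes_in_regions(regions, genes)$genes
    ref <- pops$label[1]
    realized_fst <- vapply(pops$label[-1], function(pp)
      genomewide_fst(G, popmap, ref, pp, estimator = "hudson"), numeric(1))
    sw_windows <- data.frame(contig = regions$contig, start = regions$start,
                             end = regions$end,
                             length = regions$end - regions$start + 1)
    sweep_pi <- lapply(unique(config$sweeps$pop), function(fp) {
      data.frame(pop = fp,
                 region = regions$name,
                 pi_focal = windowed_pi(G, popmap, fp, sw_windows)$pi,
                 pi_ref = windowed_pi(G, popmap, ref, sw_windows)$pi)
    })
    truth <- list(regions = regions, gene_ids = truth_genes,
                  realized_fst = realized_fst,
                  sweep_pi = do.call(rbind, sweep_pi))
  }
  list(G = G, popmap = popmap, genes = genes, truth = truth,
       config = config)
}

# deterministic gene tiling: genes of fixed length separated by fixed gaps
tile_genes <- function(contigs, gene_length, gene_spacing) {
  out <- lapply(names(contigs), function(ctg) {
    starts <- seq(1, contigs[[ctg]] - gene_length + 1,
                  by = gene_length + gene_spacing)
    data.frame(gene_id = sprintf("%s_g%04d", ctg, seq_along(starts)),
               contig = ctg, start = as.integer(starts),
               end = as.integer(starts + gene_length - 1),
               strand = rep_len(c("+", "-"), length(starts)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate genotypes with tunable LD via a haplotype copying chain
#'
#' A separate generator for the LD module (the Balding-Nichols sweep
#' fixture has no linkage by construction): 2n haplotypes evolve along the
#' site sequence as a two-state Markov chain -- at each step the allele is
#' redrawn Bernoulli(p) with probability 1 - exp(-d / corr_length) (d = bp
#' to the previous site) and copied otherwise -- giving haplotype allele
#' correlation approximately exp(-d / corr_length), so larger
#' \code{corr_length} means slower r-squared decay. \code{corr_length = 0}
#' gives independent sites (free recombination).
#'
#' @param n_diploids number of individuals.
#' @param positions sorted site positions (bp) on one contig.
#' @param corr_length correlation length in bp (>= 0).
#' @param p allele frequency of the chain's stationary distribution.
#' @param contig contig name.
#' @param contig_length contig length (default: max position).
#' @param seed integer RNG seed.
#' @return a \code{\link{genotype_matrix}} (dosage = sum of the two
#'   haplotypes).
#' @export
simulate_ld_genotypes <- function(n_diploids, positions, corr_length,
                                  p = 0.5, contig = "chr1",
                                  contig_length = max(positions),
                                  seed = 1L) {
  stopifnot(n_diploids >= 2, corr_length >= 0, p > 0, p < 1,
            !is.unsorted(positions))
  set.seed(seed)
  nh <- 2L * n_diploids
  S <- length(positions)
  H <- matrix(0L, nh, S)
  H[, 1] <- stats::rbinom(nh, 1L, p)
  if (S > 1) {
    d <- diff(positions)
    sw_prob <- if (corr_length > 0) 1 - exp(-d / corr_length)
               else rep(1, S - 1)
    for (s in 2:S) {
      sw <- stats::runif(nh) < sw_prob[s - 1]
      H[, s] <- ifelse(sw, stats::rbinom(nh, 1L, p), H[, s - 1])
    }
  }
  calls <- H[seq(1, nh, by = 2), , drop = FALSE] +
    H[seq(2, nh, by = 2), , drop = FALSE]
  rownames(calls) <- sprintf("ind_%02d", seq_len(n_diploids))
  bases <- rep_len(c("A", "G"), S)
  sites <- data.frame(contig = contig, pos = positions,
                      ref = bases, alt = rep_len(c("T", "C"), S),
                      stringsAsFactors = FALSE)
  genotype_matrix(calls, sites,
                  contig_lengths = stats::setNames(contig_length, contig))
}

#' Base-pair recall and precision of called regions against planted truth
#'
#' recall = truth bp overlapped by calls / total truth bp;
#' precision = called bp overlapping truth / total called bp.
#'
#' @param called data.frame of called regions (\code{contig},
#'   \code{start}, \code{end}).
#' @param truth data.frame of truth regions (same columns).
#' @return named numeric \code{c(recall =, precision =)}. With no calls,
#'   recall is 0 and precision is reported as 0 with a warning.
#' @export
evaluate_recovery <- function(called, truth) {
  if (is.null(truth) || nrow(truth) == 0) stop("empty truth region set")
  gr_t <- GenomicRanges::reduce(GenomicRanges::GRanges(
    truth$contig, IRanges::IRanges(truth$start, truth$end)))
  if (is.null(called) || nrow(called) == 0) {
    warning("no called regions; precision undefined, reported as 0")
    return(c(recall = 0, precision = 0))
  }
  gr_c <- GenomicRanges::reduce(GenomicRanges::GRanges(
    called$contig, IRanges::IRanges(called$start, called$end)))
  ov <- sum(GenomicRanges::width(GenomicRanges::intersect(gr_t, gr_c)))
  c(recall = ov / sum(GenomicRanges::width(gr_t)),
    precision = ov / sum(GenomicRanges::width(gr_c)))
}
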