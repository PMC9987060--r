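#' Select sweep windows by top-quantile intersection
#'
#' The core decision rule of the scan: a window is selected iff its F_ST
#' and its pi ln-ratio both reach the empirical \code{q}-quantile of their
#' own distribution over unmasked windows (default: top 5% of each,
#' intersected). Quantiles use the type-7 order-statistic definition and
#' ties at a threshold are selected.
#'
#' @param fst numeric vector of per-window F_ST (NA = masked).
#' @param lnratio numeric vector of per-window pi ln-ratio, same windows.
#' @param q quantile level (default 0.95).
#' @return list with \code{selected} (logical vector; masked windows are
#'   \code{FALSE}) and \code{thresholds} (named numeric,
#'   \code{fst}/\code{lnratio}).
#' @export
select_sweep_windows <- function(fst, lnratio, q = 0.95) {
  stopifnot(length(fst) == length(lnratio), q > 0, q < 1)
  ok <- !is.na(fst) & !is.na(lnratio)
  if (sum(ok) < 20) {
    stop("only ", sum(ok),
         " unmasked windows; need >= 20 for a stable quantile")
  }
  thr_fst <- stats::quantile(fst[ok], q, type = 7, names = FALSE)
  thr_lnr <- stats::quantile(lnratio[ok], q, type = 7, names = FALSE)
  selected <- ok & fst >= thr_fst & lnratio >= thr_lnr
  list(selected = selected,
       thresholds = c(fst = thr_fst, lnratio = thr_lnr))
}

#' Merge selected windows into candidate sweep regions
#'
#' Overlapping or bookended selected windows on the same contig merge into
#' one region spanning their union (via \code{GenomicRanges::reduce}).
#' Merging is idempotent.
#'
#' @param windows data.frame with \code{contig}, \code{start}, \code{end}.
#' @param selected logical vector over rows of \code{windows}; defaults to
#'   a \code{selected} column, else all rows.
#' @return data.frame of regions: \code{contig}, \code{start}, \code{end},
#'   \code{n_windows}, plus a list-column \code{window_idx} of member row
#'   indices into \code{windows}.
#' @export
merge_regions <- function(windows, selected = NULL) {
  if (is.null(selected)) {
    selected <- if ("selected" %in% names(windows)) windows$selected
                else rep(TRUE, nrow(windows))
  }
  sel <- which(selected)
  if (!length(sel)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::GRanges(
    windows$contig[sel],
    IRanges::IRanges(windows$start[sel], windows$end[sel]))
  red <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(red, gr)
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red),
                    end = GenomicRanges::end(red),
                    stringsAsFactors = FALSE)
  members <- split(sel[S4Vectors::subjectHits(hits)],
                   factor(S4Vectors::queryHits(hits), seq_len(nrow(out))))
  out$n_windows <- lengths(members)
  out$window_idx <- unname(members)
  ord <- order(out$contig, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map genes onto candidate regions
#'
#' A gene overlaps a region iff the 1-based inclusive intervals share at
#' least one bp (bookended intervals do not overlap).
#'
#' @param regions data.frame with \code{contig}, \code{start}, \code{end}.
#' @param genes data.frame of gene models as from \code{\link{read_gff}}.
#' @return list with \code{regions} (the input plus a list-column
#'   \code{gene_ids}) and \code{genes} (character union over regions).
#' @export
genes_in_regions <- function(regions, genes) {
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    regions$gene_ids <- rep(list(character(0)), nrow(regions))
    return(list(regions = regions, genes = character(0)))
  }
  gr_r <- GenomicRanges::GRanges(
    regions$contig, IRanges::IRanges(regions$start, regions$end))
  gr_g <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g)
  ids <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits), seq_len(nrow(regions))))
  regions$gene_ids <- lapply(unname(ids), unique)
  list(regions = regions,
       genes = sort(unique(genes$gene_id[S4Vectors::subjectHits(hits)])))
}

#' Shared genes across comparisons and Venn partition
#'
#' @param gene_sets named list (one character vector of gene ids per
#'   focal-population comparison); at least two sets.
#' @return list with \code{intersection} (genes present in every set) and
#'   \code{venn}: named integer vector of exclusive partition counts, one
#'   entry per nonempty combination (names like \code{"A&B"}).
#' @export
shared_genes <- function(gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 2)
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- LETTERS[seq_along(gene_sets)]
  }
  gene_sets <- lapply(gene_sets, unique)
  all_genes <- unique(unlist(gene_sets))
  member <- vapply(gene_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row)
    paste(names(gene_sets)[row], collapse = "&"))
  k <- length(gene_sets)
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(gene_sets), m, paste, collapse = "&",
                 simplify = FALSE)))
  venn <- stats::setNames(integer(length(combos)), combos)
  tab <- table(pattern)
  venn[names(tab)] <- as.integer(tab)
  list(intersection = sort(Reduce(intersect, gene_sets)), venn = venn)
}

#' Full selective-sweep scan of a focal population against a reference
#'
#' Runs the windowed Weir-Cockerham F_ST and per-population nucleotide
#' diversity scans, forms the pi ln-ratio ln(pi_ref/pi_focal), selects
#' windows in the top \code{1 - q} tail of both statistics, merges them
#' into candidate regions and (optionally) maps genes onto the regions.
#'
#' @param G a filtered \code{\link{genotype_matrix}}.
#' @param popmap named character vector (sample -> population).
#' @param ref_pop reference (high-diversity, low-selection) population.
#' @param focal_pop scanned population.
#' @param genes optional gene models (from \code{\link{read_gff}}).
#' @param window_size,step window geometry in bp (defaults 100 kb / 10 kb).
#' @param q quantile level for both statistics (default 0.95).
#' @param min_snps minimum usable SNPs per window (default 10).
#' @param estimator F_ST estimator, \code{"wc"} or \code{"hudson"}.
#' @param drop_tails drop truncated tail windows (default keep).
#' @param merge merge selected windows into regions (default TRUE; FALSE
#'   reports raw selected windows as regions).
#' @return list with \code{windows} (per-window table: coordinates,
#'   \code{n_snps}, \code{fst}, \code{pi_ref}, \code{pi_focal},
#'   \code{pi_lnratio}, \code{selected}), \code{thresholds},
#'   \code{regions}, \code{genes} (union of overlapping gene ids, or NULL),
#'   and \code{params}.
#' @export
sweep_scan <- function(G, popmap, ref_pop, focal_pop, genes = NULL,
                       window_size = 100000L, step = 10000L, q = 0.95,
                       min_snps = 10L, estimator = c("wc", "hudson"),
                       drop_tails = FALSE, merge = TRUE) {
  estimator <- match.arg(estimator)
  windows <- enumerate_windows(G$contig_lengths, window_size, step,
                               drop_tails = drop_tails)
  wf <- windowed_fst(G, popmap, ref_pop, focal_pop, windows,
                     min_snps = min_snps, estimator = estimator)
  pr <- windowed_pi(G, popmap, ref_pop, windows)
  pf <- windowed_pi(G, popmap, focal_pop, windows)
  lnr <- pi_lnratio(pr$pi, pf$pi)
  sel <- select_sweep_windows(wf$fst, lnr, q = q)

  windows$n_snps <- wf$n_snps
  windows$fst <- wf$fst
  windows$pi_ref <- pr$pi
  windows$pi_focal <- pf$pi
  windows$pi_lnratio <- lnr
  windows$selected <- sel$selected

  regions <- if (merge) merge_regions(windows) else {
    data.frame(contig = windows$contig[sel$selected],
               start = windows$start[sel$selected],
               end = windows$end[sel$selected],
               stringsAsFactors = FALSE)
  }
  gene_union <- NULL
  if (!is.null(genes)) {
    gm <- genes_in_regions(regions, genes)
    regions <- gm$regions
    gene_union <- gm$genes
  }
  list(windows = windows, thresholds = sel$thresholds, regions = regions,
       genes = gene_union,
       params = list(ref_pop = ref_pop, focal_pop = focal_pop,
                     window_size = window_size, step = step, q = q,
                     min_snps = min_snps, estimator = estimator,
                     drop_tails = drop_tails, merge = merge))
}
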