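#' Genotype matrix container
#'
#' The central data structure of the package: diploid alt-allele dosages
#' (0, 1, 2 or \code{NA} for missing) for a set of samples at biallelic SNP
#' sites, together with site coordinates and contig lengths. All coordinates
#' are 1-based inclusive (the VCF/GFF convention); conversion to 0-based
#' half-open happens only when writing BED.
#'
#' @param calls integer matrix, samples in rows and sites in columns; values
#'   in \code{{0, 1, 2, NA}}. Row names are taken as sample identifiers when
#'   \code{sample_ids} is missing.
#' @param sites data.frame with columns \code{contig}, \code{pos} (1-based
#'   bp), \code{ref}, \code{alt}; one row per column of \code{calls}, sorted
#'   by (contig, pos) with unique positions per contig.
#' @param contig_lengths named numeric vector of contig lengths in bp. If
#'   omitted, the maximum observed position per contig is used.
#' @param sample_ids character vector of sample labels (defaults to
#'   \code{rownames(calls)}).
#'
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{samples}, \code{sites}, \code{calls}, \code{contig_lengths}.
#' @export
genotype_matrix <- function(calls, sites, contig_lengths = NULL,
                            sample_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(calls)))
  }
  stopifnot(length(sample_ids) == nrow(calls))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("`sites` must have columns contig, pos, ref, alt")
  }
  if (nrow(sites) != ncol(calls)) {
    stop("number of sites (", nrow(sites), ") does not match ncol(calls) (",
         ncol(calls), ")")
  }
  sites$contig <- as.character(sites$contig)
  sites$pos <- as.integer(sites$pos)
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")

  ord <- order(sites$contig, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  dup <- duplicated(sites[, c("contig", "pos")])
  if (any(dup)) {
    stop("duplicate site position(s): ",
         paste(sites$contig[dup], sites$pos[dup], sep = ":", collapse = ", "))
  }
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(sites$pos, sites$contig, max)
    contig_lengths <- stats::setNames(as.numeric(contig_lengths),
                                      names(contig_lengths))
  }
  missing_ctg <- setdiff(unique(sites$contig), names(contig_lengths))
  if (length(missing_ctg)) {
    stop("contig_lengths missing for: ", paste(missing_ctg, collapse = ", "))
  }
  too_far <- sites$pos > contig_lengths[sites$contig] | sites$pos < 1L
  if (any(too_far)) {
    stop("site position outside contig bounds at ",
         paste(sites$contig[too_far], sites$pos[too_far],
               sep = ":", collapse = ", "))
  }
  rownames(calls) <- sample_ids
  rownames(sites) <- NULL
  structure(
    list(samples = as.character(sample_ids), sites = sites, calls = calls,
         contig_lengths = contig_lengths[order(names(contig_lengths))]),
    class = "genotype_matrix"
  )
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$sites), "biallelic SNP sites on",
      length(x$contig_lengths), "contig(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param G a \code{genotype_matrix}.
#' @param samples character vector of sample ids or logical/integer index.
#' @param sites logical or integer index over site columns.
#' @return A \code{genotype_matrix}.
#' @export
subset_genotypes <- function(G, samples = NULL, sites = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  calls <- G$calls
  ids <- G$samples
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, ids)
      if (length(missing)) {
        stop("samples not present: ", paste(missing, collapse = ", "))
      }
      idx <- match(samples, ids)
    } else {
      idx <- samples
    }
    calls <- calls[idx, , drop = FALSE]
    ids <- ids[idx]
  }
  st <- G$sites
  if (!is.null(sites)) {
    calls <- calls[, sites, drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  genotype_matrix(calls, st, contig_lengths = G$contig_lengths,
                  sample_ids = ids)
}
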