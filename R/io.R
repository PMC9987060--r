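#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF (v4.x) with GT genotypes via \pkg{vcfR}, keeping only
#' biallelic SNP records. Multiallelic records, indels and other non-SNP
#' records are dropped and the count is reported via \code{message()}.
#' Missing and half-called genotypes (\code{./.}, \code{0/.}, ...) become
#' \code{NA}; \code{/} and \code{|} separators are treated identically.
#' Contig lengths come from \code{##contig} header lines when present,
#' otherwise the maximum observed position per contig is used.
#'
#' @param path VCF file path.
#' @param keep_samples optional character vector; restrict to these samples
#'   (error if any is absent from the file).
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_vcf <- function(path, keep_samples = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  head_lines <- readLines(path, n = 1000L)
  if (!any(startsWith(head_lines, "#CHROM"))) {
    stop("malformed VCF (no #CHROM header line found in ", path, ")")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T", "a", "c", "g", "t") &
    alt %in% c("A", "C", "G", "T", "a", "c", "g", "t")
  n_drop <- sum(!is_snp)
  if (n_drop > 0) {
    message("read_vcf: dropped ", n_drop,
            " non-biallelic-SNP record(s) of ", length(is_snp))
  }
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")   # variants x samples
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  samples <- colnames(gt)
  if (!is.null(keep_samples)) {
    missing <- setdiff(keep_samples, samples)
    if (length(missing)) {
      stop("keep_samples absent from VCF: ", paste(missing, collapse = ", "))
    }
    gt <- gt[, keep_samples, drop = FALSE]
    samples <- keep_samples
  }

  calls <- t(gt_to_dosage(gt))                  # samples x sites
  sites <- data.frame(contig = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)

  contig_lengths <- vcf_contig_lengths(vcf@meta)
  if (length(contig_lengths) == 0) contig_lengths <- NULL
  genotype_matrix(calls, sites, contig_lengths = contig_lengths,
                  sample_ids = samples)
}

# "0/1", "0|1", "./." ... -> dosage 0/1/2/NA; half-calls are missing
gt_to_dosage <- function(gt) {
  norm <- gsub("|", "/", gt, fixed = TRUE)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  d <- map[norm]
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

vcf_contig_lengths <- function(meta) {
  ctg <- grep("^##contig=<", meta, value = TRUE)
  if (!length(ctg)) return(numeric(0))
  ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
  has_len <- grepl("length=", ctg)
  lens <- rep(NA_real_, length(ctg))
  lens[has_len] <- as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg[has_len]))
  out <- stats::setNames(lens, ids)
  out[!is.na(out)]
}

#' Write a genotype matrix as a minimal GT-only VCF v4.2 file
#'
#' Deterministic plain-text output: identical input always yields
#' byte-identical files, so a simulation seed fixes the VCF bytes.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    sprintf("##contig=<ID=%s,length=%d>", names(G$contig_lengths),
            as.integer(G$contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$samples), collapse = "\t")
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[G$calls + 1L],
                   nrow = nrow(G$calls))
  gt_str[is.na(G$calls)] <- "./."
  body <- paste(G$sites$contig, G$sites$pos, ".", G$sites$ref, G$sites$alt,
                ".", ".", ".", "GT",
                apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two tab-separated columns (sample, population), no header.
#'
#' @param path TSV file path.
#' @return Named character vector: names are sample ids, values population
#'   labels.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("popmap file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("popmap file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- which(nfield != 2L)[1]
    stop("popmap line ", bad, " has ", nfield[bad],
         " tab-separated fields (expected 2)")
  }
  sample <- vapply(parts, `[[`, "", 1L)
  pop <- vapply(parts, `[[`, "", 2L)
  dup <- duplicated(sample)
  if (any(dup)) {
    stop("sample(s) listed more than once in popmap: ",
         paste(unique(sample[dup]), collapse = ", "))
  }
  stats::setNames(pop, sample)
}

#' Read gene models from a GFF3 file
#'
#' Imports via \pkg{rtracklayer} and keeps records of type \code{gene}.
#' Coordinates stay 1-based inclusive as in GFF3.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns \code{gene_id}, \code{contig},
#'   \code{start}, \code{end}, \code{strand}, sorted by (contig, start).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (!length(gr)) stop("no gene records in ", path)
  id <- as.character(gr$ID)
  if (any(is.na(id) | !nzchar(id))) {
    stop("gene record(s) without an ID attribute in ", path)
  }
  out <- data.frame(gene_id = id,
                    contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "."
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write genomic regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so the emitted start is \code{start - 1} and the end is \code{end}.
#'
#' @param regions data.frame with columns \code{contig}, \code{start},
#'   \code{end} and optionally \code{name}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(regions, path) {
  regions <- as.data.frame(regions)
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(c("contig", "start", "end") %in% names(regions)))
  name <- if ("name" %in% names(regions)) regions$name else
    paste0("region_", seq_len(nrow(regions)))
  lines <- paste(regions$contig,
                 format(regions$start - 1, scientific = FALSE, trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE),
                 name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive regions
#'
#' @param path BED file path.
#' @return data.frame with columns \code{contig}, \code{start}, \code{end},
#'   \code{name} (1-based inclusive coordinates).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "bed")
  nm <- gr$name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             name = as.character(nm),
             stringsAsFactors = FALSE)
}
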