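#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds diploid alt-allele dosage calls (0, 1, 2 or
#' `NA` for missing) for a set of samples at a set of biallelic SNPs,
#' together with the variant coordinates. It is the container shared by
#' every scan, LD, genotyping and introgression function in the package.
#'
#' Internally all interval arithmetic (windows, regions) is 0-based
#' half-open; VCF input/output converts to and from the 1-based `POS`
#' convention.
#'
#' @param calls Integer matrix, samples in rows and variants in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param variants Data frame with columns `chrom`, `pos` (1-based, as in
#'   VCF), `ref` and `alt` (single nucleotides), one row per column of
#'   `calls`. Rows must be sorted by `(chrom, pos)`.
#' @param sample_ids Character vector of sample identifiers, one per row
#'   of `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants` and `sample_ids`.
#' @export
genotype_matrix <- function(calls, variants, sample_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (nrow(variants) != ncol(calls))
    stop("variants must have one row per column of calls")
  if (length(sample_ids) != nrow(calls))
    stop("sample_ids must have one entry per row of calls")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("non-missing calls must be dosages in {0, 1, 2}")
  if (any(variants$pos < 1)) stop("variant positions are 1-based; pos >= 1")
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(variants) <- NULL
  rownames(calls) <- sample_ids
  colnames(calls) <- paste(variants$chrom, variants$pos, sep = "_")
  structure(list(calls = calls, variants = variants,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.1f%% missing)\n",
              length(x$sample_ids), nrow(x$variants), 100 * miss))
  cat("chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param samples Optional character vector of sample ids or
#'   logical/integer index over samples.
#' @param variants Optional logical/integer index over variant columns.
#' @return A `genotype_matrix` restricted to the requested samples and
#'   variants.
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- seq_along(gm$sample_ids)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$sample_ids) else
      si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  vi <- seq_len(nrow(gm$variants))
  if (!is.null(variants)) vi <- vi[variants]
  genotype_matrix(gm$calls[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE],
                  gm$sample_ids[si])
}

#' Logical index of variants falling in a genomic region
#'
#' @param gm A [genotype_matrix()].
#' @param chrom Chromosome identifier.
#' @param start,end Region bounds, 0-based half-open. Defaults select the
#'   whole chromosome.
#' @return Logical vector over the variant columns of `gm`.
#' @export
variants_in_region <- function(gm, chrom, start = 0, end = Inf) {
  stopifnot(inherits(gm, "genotype_matrix"), end > start)
  # pos is 1-based: site at pos p occupies 0-based coordinate p - 1
  gm$variants$chrom == chrom & (gm$variants$pos - 1) >= start &
    (gm$variants$pos - 1) < end
}

#' Alt-allele frequency per site
#'
#' Computed over non-missing chromosomes (two per non-missing call).
#'
#' @param gm A [genotype_matrix()] .
#' @param samples Optional sample subset (ids or index).
#' @return Numeric vector of alt frequencies, `NaN` where no calls.
#' @export
alt_freq <- function(gm, samples = NULL) {
  if (!is.null(samples)) gm <- subset_genotypes(gm, samples = samples)
  colSums(gm$calls, na.rm = TRUE) / (2 * colSums(!is.na(gm$calls)))
}

#' Minor-allele frequency per site
#' @inheritParams alt_freq
#' @return Numeric vector in `[0, 0.5]`.
#' @export
minor_allele_freq <- function(gm, samples = NULL) {
  p <- alt_freq(gm, samples)
  pmin(p, 1 - p)
}
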