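#' Read diploid genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) and returns the biallelic-SNP
#' dosage matrix. Multiallelic records, indels and non-ACGT alleles are
#' dropped; half-calls (e.g. `./1`) and `./.` become missing. Phased and
#' unphased separators are treated identically. The number of dropped
#' records is reported via `message()`.
#'
#' @param path Path to a VCF file with a GT FORMAT field.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  nuc <- c("A", "C", "G", "T")
  keep <- fix$REF %in% nuc & fix$ALT %in% nuc
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " non-biallelic-SNP record(s) dropped")
  if (!any(keep))
    stop("no biallelic SNPs retained from ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = sum(keep),
                                   dimnames = list(NULL, colnames(v@gt)[-1]))
  dosage <- gt_to_dosage(gt)
  variants <- data.frame(chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         ref = fix$REF[keep], alt = fix$ALT[keep],
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dosage), variants, colnames(gt))
}

# Map GT strings to dosages; any allele "." (incl. half-calls) -> NA.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".")) return(NA_integer_)
    av <- suppressWarnings(as.integer(al))
    if (anyNA(av) || any(av > 1)) return(NA_integer_)
    sum(av)
  }, integer(1))
  m <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt))
  dimnames(m) <- dimnames(gt)
  m
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal VCF 4.2 file with a GT-only FORMAT column; missing
#' calls are written as `./.`. `read_vcf(write_vcf(gm, f))` reproduces
#' `gm` exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$sample_ids) == 0) stop("cannot write a VCF with no samples")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=supergene",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gm$sample_ids),
                     collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- apply(gm$calls, 2, function(d) {
    out <- gt_codes[d + 1L]
    out[is.na(d)] <- "./."
    out
  })
  # apply() returns samples in rows of each column result; body is
  # samples x variants only when >1 sample, so rebuild explicitly
  body <- matrix(body, nrow = length(gm$sample_ids))
  lines <- paste(gm$variants$chrom, gm$variants$pos, ".",
                 gm$variants$ref, gm$variants$alt, ".", "PASS", ".", "GT",
                 apply(body, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated file with header columns `sample_id`, `ecotype`,
#' `latitude`, `season` and optionally `inversion_genotype`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with validated columns.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "ecotype", "latitude", "season")
  if (!all(req %in% names(md)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  if (!all(md$ecotype %in% c("common", "hoary", "lesser")))
    stop("ecotype must be one of common/hoary/lesser")
  if (!all(md$season %in% c("breeding", "nonbreeding")))
    stop("season must be breeding or nonbreeding")
  if (any(md$latitude < -90 | md$latitude > 90))
    stop("latitude must lie in [-90, 90]")
  if (!is.null(md$inversion_genotype) &&
      !all(is.na(md$inversion_genotype) |
           md$inversion_genotype %in% c("AA", "AB", "BB")))
    stop("inversion_genotype must be AA/AB/BB or NA")
  invisible(md)
}

#' Filter sites by minor-allele frequency
#'
#' Retains sites whose minor-allele frequency, computed over non-missing
#' alleles across the whole dataset, is at least `threshold`.
#'
#' @param gm A [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return Filtered `genotype_matrix` (possibly with zero variants).
#' @export
filter_by_maf <- function(gm, threshold) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  maf <- minor_allele_freq(gm)
  keep <- !is.na(maf) & maf >= threshold
  subset_genotypes(gm, variants = keep)
}

#' Filter sites by missing-call fraction
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing_fraction Retain sites whose fraction of missing
#'   calls is at most this value (0 = complete data only, as in a "100p"
#'   dataset; 0.25 = a "75p" dataset).
#' @return Filtered `genotype_matrix`.
#' @export
filter_by_missingness <- function(gm, max_missing_fraction) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  miss <- colMeans(is.na(gm$calls))
  subset_genotypes(gm, variants = miss <= max_missing_fraction)
}

#' Build a window grid over chromosomes
#'
#' Windows are 0-based half-open `[start, end)`; the last window of a
#' chromosome may be shorter than `size`. With `step == size` the grid
#' tiles each chromosome exactly.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param size Window size in bp.
#' @param step Distance between successive window starts in bp
#'   (default `size`).
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size, step = size) {
  stopifnot(size > 0, step > 0, length(chrom_lengths) > 0,
            !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size, len))
  })
  do.call(rbind, out)
}

#' Write a window grid as a BED file
#'
#' BED is 0-based half-open, matching the internal convention.
#'
#' @param windows Data frame from [make_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  utils::write.table(windows[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
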