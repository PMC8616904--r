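#' Composite genotype linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of the two dosage vectors over
#' pairwise-complete samples. This is the standard unphased-data LD
#' measure (composite genotype LD); no haplotype phase is inferred.
#'
#' @param dosage_x,dosage_y Dosage vectors at the two sites.
#' @return r-squared in `[0, 1]`, or `NA` if fewer than two complete
#'   pairs or either site is monomorphic among them.
#' @export
genotype_r2 <- function(dosage_x, dosage_y) {
  ok <- !is.na(dosage_x) & !is.na(dosage_y)
  x <- dosage_x[ok]; y <- dosage_y[ok]
  if (length(x) < 2) return(NA_real_)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Linkage-disequilibrium decay curve for a region
#'
#' All within-region site pairs separated by at most `max_distance` are
#' binned by distance (measured between the 1-based VCF positions) and
#' the mean r-squared per bin is reported. Bins are
#' `(0, bin_width], (bin_width, 2 bin_width], ...`.
#'
#' @param gm A [genotype_matrix()].
#' @param region Logical/integer index over variants (e.g. from
#'   [variants_in_region()]); default all sites. The region must lie on
#'   one chromosome.
#' @param max_distance Maximum pair separation in bp.
#' @param bin_width Bin width in bp.
#' @param label Region label stored on the curve (default "region").
#' @return Data frame of class `ld_decay_curve` with columns `region`,
#'   `bin_start`, `bin_end`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(gm, region = NULL, max_distance = 1e5,
                     bin_width = 1e4, label = "region") {
  sub <- subset_genotypes(gm, variants = region)
  if (nrow(sub$variants) < 2) stop("region must contain at least 2 sites")
  if (length(unique(sub$variants$chrom)) != 1)
    stop("LD decay is computed within a single chromosome")
  pos <- sub$variants$pos
  cm <- suppressWarnings(stats::cor(sub$calls,
                                    use = "pairwise.complete.obs"))^2
  dm <- abs(outer(pos, pos, "-"))
  ut <- upper.tri(dm)
  d <- dm[ut]; r2 <- cm[ut]
  keep <- d > 0 & d <= max_distance & !is.na(r2)
  edges <- seq(0, max_distance, by = bin_width)
  if (edges[length(edges)] < max_distance)
    edges <- c(edges, max_distance)
  out <- data.frame(region = label,
                    bin_start = edges[-length(edges)],
                    bin_end = edges[-1])
  if (!any(keep)) {
    warning("no qualifying site pairs in region '", label, "'")
    out$mean_r2 <- NA_real_
    out$n_pairs <- 0L
  } else {
    bin <- cut(d[keep], breaks = edges, labels = FALSE)
    out$mean_r2 <- as.numeric(tapply(r2[keep], factor(bin,
                    levels = seq_len(nrow(out))), mean))
    np <- tabulate(bin, nbins = nrow(out))
    out$n_pairs <- np
  }
  class(out) <- c("ld_decay_curve", class(out))
  out
}

#' Combine LD-decay curves from several regions
#'
#' Stacks curves computed on a common bin grid into one long-format
#' table for comparison (e.g. inversion vs rest-of-chromosome vs other
#' chromosomes).
#'
#' @param curves List of [ld_decay()] outputs sharing identical bins.
#' @return Long-format data frame `region x bin x mean_r2 x n_pairs`.
#' @export
compare_ld_regions <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1)
  ref <- curves[[1]][, c("bin_start", "bin_end")]
  for (cv in curves[-1]) {
    if (!isTRUE(all.equal(ref, cv[, c("bin_start", "bin_end")],
                          check.attributes = FALSE)))
      stop("curves must share identical distance bins")
  }
  out <- do.call(rbind, lapply(curves, as.data.frame))
  rownames(out) <- NULL
  out
}
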