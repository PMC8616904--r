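#' Per-site nucleotide diversity within a group
#'
#' For variant sites, pi at a site is the probability that two
#' chromosomes drawn without replacement differ:
#' `pi = (n / (n - 1)) * 2 p (1 - p)` where `p` is the alt-allele
#' frequency over the `n` non-missing chromosomes (two per called
#' sample). Sites with fewer than two chromosomes are returned as `NA`
#' (skipped, not an error).
#'
#' @param dosages Integer matrix (samples x sites) of dosages for the
#'   group, or a vector for a single site.
#' @return Numeric vector of per-site pi values.
#' @export
site_pi <- function(dosages) {
  if (is.null(dim(dosages))) dosages <- matrix(dosages, ncol = 1)
  n <- 2 * colSums(!is.na(dosages))
  p <- colSums(dosages, na.rm = TRUE) / n
  out <- ifelse(n >= 2, (n / pmax(n - 1, 1)) * 2 * p * (1 - p), NA_real_)
  as.numeric(out)
}

#' Per-site absolute divergence between two groups
#'
#' `dxy = p1 (1 - p2) + p2 (1 - p1)`: the probability that one
#' chromosome from each group differs at the site.
#'
#' @param p1,p2 Alt-allele frequency vectors for the two groups; `NA`
#'   where a group has no called chromosome (site skipped).
#' @return Numeric vector of per-site dXY values.
#' @export
site_dxy <- function(p1, p2) p1 * (1 - p2) + p2 * (1 - p1)

#' Hudson FST for a window of sites
#'
#' Ratio-of-averages Hudson estimator:
#' `FST = 1 - mean(H_within) / mean(H_between)` over usable sites, where
#' `H_within` is the average of the two groups' per-site pi and
#' `H_between` is the per-site dXY. A site is usable when both groups
#' have at least two non-missing chromosomes. Negative estimates are
#' reported, not clipped.
#'
#' @param dos1,dos2 Dosage matrices (samples x sites) for the two groups
#'   over the same sites.
#' @return List with `fst`, `n_sites` (usable sites), `mean_hw`,
#'   `mean_hb`. `fst` is `NA` when no usable site or no between-group
#'   diversity.
#' @export
window_fst <- function(dos1, dos2) {
  if (is.null(dim(dos1))) dos1 <- matrix(dos1, ncol = 1)
  if (is.null(dim(dos2))) dos2 <- matrix(dos2, ncol = 1)
  stopifnot(ncol(dos1) == ncol(dos2))
  pi1 <- site_pi(dos1)
  pi2 <- site_pi(dos2)
  p1 <- colSums(dos1, na.rm = TRUE) / (2 * colSums(!is.na(dos1)))
  p2 <- colSums(dos2, na.rm = TRUE) / (2 * colSums(!is.na(dos2)))
  usable <- !is.na(pi1) & !is.na(pi2)
  if (!any(usable))
    return(list(fst = NA_real_, n_sites = 0L, mean_hw = NA_real_,
                mean_hb = NA_real_))
  hw <- (pi1[usable] + pi2[usable]) / 2
  hb <- site_dxy(p1[usable], p2[usable])
  mhw <- mean(hw)
  mhb <- mean(hb)
  fst <- if (mhb > 0) 1 - mhw / mhb else NA_real_
  list(fst = fst, n_sites = sum(usable), mean_hw = mhw, mean_hb = mhb)
}

#' Observed heterozygosity over a set of samples and sites
#'
#' Fraction of non-missing calls equal to dosage 1. For an inversion
#' region this is the quantity that roughly doubles in inversion
#' heterozygotes relative to the homozygote clusters.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Sample ids or index (default: all samples).
#' @param region Logical/integer index over variants (default: all
#'   sites), e.g. from [variants_in_region()].
#' @return Single numeric fraction; `NA` if no non-missing calls.
#' @export
observed_heterozygosity <- function(gm, samples = NULL, region = NULL) {
  sub <- subset_genotypes(gm, samples = samples, variants = region)
  if (ncol(sub$calls) == 0) stop("region contains no sites")
  calls <- sub$calls
  n <- sum(!is.na(calls))
  if (n == 0) return(NA_real_)
  sum(calls == 1L, na.rm = TRUE) / n
}

#' Windowed diversity and differentiation scan
#'
#' Computes, for every window, per-group pi, pairwise dXY and pairwise
#' Hudson FST as unweighted means of the per-site values over usable
#' sites (sites with at least two non-missing chromosomes in every group
#' involved). This is the genome-scan used to localise divergent regions
#' such as an inversion.
#'
#' @param gm A [genotype_matrix()].
#' @param group_map Named list mapping group name to a character vector
#'   of sample ids; groups must be non-overlapping.
#' @param windows Data frame from [make_windows()].
#' @return Data frame with one row per window: `chrom`, `start`, `end`,
#'   `n_sites`, `pi_<group>`, `dxy_<g1>_<g2>`, `fst_<g1>_<g2>` columns.
#'   The FST estimator is recorded in the `"fst_estimator"` attribute.
#' @export
popgen_scan <- function(gm, group_map, windows) {
  stopifnot(inherits(gm, "genotype_matrix"), is.list(group_map),
            length(group_map) >= 1, !is.null(names(group_map)))
  all_ids <- unlist(group_map)
  if (anyDuplicated(all_ids)) stop("groups must be non-overlapping")
  for (g in names(group_map)) {
    if (length(group_map[[g]]) == 0) stop("empty group: ", g)
    if (!all(group_map[[g]] %in% gm$sample_ids))
      stop("unknown sample id(s) in group: ", g)
  }
  groups <- names(group_map)
  pairs <- if (length(groups) >= 2) utils::combn(groups, 2) else NULL
  dos <- lapply(group_map, function(ids)
    gm$calls[match(ids, gm$sample_ids), , drop = FALSE])

  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    idx <- which(variants_in_region(gm, w$chrom, w$start, w$end))
    row <- list(chrom = w$chrom, start = w$start, end = w$end)
    dpi <- lapply(dos, function(m)
      if (length(idx)) site_pi(m[, idx, drop = FALSE]) else numeric(0))
    usable <- if (length(idx)) Reduce(`&`, lapply(dpi, function(x) !is.na(x)))
              else logical(0)
    row$n_sites <- sum(usable)
    for (g in groups)
      row[[paste0("pi_", g)]] <-
        if (any(usable)) mean(dpi[[g]][usable]) else NA_real_
    if (!is.null(pairs)) {
      for (j in seq_len(ncol(pairs))) {
        g1 <- pairs[1, j]; g2 <- pairs[2, j]
        nm <- paste0(g1, "_", g2)
        if (any(usable)) {
          d1 <- dos[[g1]][, idx[usable], drop = FALSE]
          d2 <- dos[[g2]][, idx[usable], drop = FALSE]
          p1 <- colSums(d1, na.rm = TRUE) / (2 * colSums(!is.na(d1)))
          p2 <- colSums(d2, na.rm = TRUE) / (2 * colSums(!is.na(d2)))
          row[[paste0("dxy_", nm)]] <- mean(site_dxy(p1, p2))
          row[[paste0("fst_", nm)]] <- window_fst(d1, d2)$fst
        } else {
          row[[paste0("dxy_", nm)]] <- NA_real_
          row[[paste0("fst_", nm)]] <- NA_real_
        }
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fst_estimator") <- "Hudson (ratio of averages)"
  out
}

#' Write a scan table as TSV
#'
#' The FST estimator is recorded in a comment header line.
#'
#' @param scan_table Output of [popgen_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan_table, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# fst_estimator: ",
                    attr(scan_table, "fst_estimator")), con)
  utils::write.table(scan_table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
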