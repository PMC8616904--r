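#' PCA of a dosage matrix
#'
#' Sites are filtered at a minor-allele-frequency cutoff (the
#' karyotyping convention is a high cutoff, default 0.40, which
#' enriches for sites segregating between inversion haplotypes),
#' missing dosages are mean-imputed per site, and the centred matrix is
#' decomposed with `prcomp`.
#'
#' @param gm A [genotype_matrix()].
#' @param maf_cutoff MAF cutoff applied before the PCA (default 0.40).
#' @return List with `scores` (samples x PCs), `variance_explained`
#'   (proportions, summing to 1), `n_sites`, and `site_index` (logical
#'   index over the variants of `gm` that entered the PCA).
#' @export
inversion_pca <- function(gm, maf_cutoff = 0.40) {
  stopifnot(inherits(gm, "genotype_matrix"),
            length(gm$sample_ids) >= 2)
  keep <- {
    maf <- minor_allele_freq(gm)
    !is.na(maf) & maf >= maf_cutoff
  }
  if (sum(keep) < 2)
    stop("fewer than 2 sites pass the MAF cutoff of ", maf_cutoff)
  x <- gm$calls[, keep, drop = FALSE]
  storage.mode(x) <- "double"
  # per-site mean imputation of missing dosages
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- mu[na_idx[, 2]]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  rownames(pc$x) <- gm$sample_ids
  list(scores = pc$x, variance_explained = ve, n_sites = sum(keep),
       site_index = keep)
}

#' One-dimensional k-means clustering of PC1 scores
#'
#' Deterministic Lloyd iteration initialised at the 1/6, 3/6 and 5/6
#' quantiles of the scores (for k = 3: the cluster-prior positions of
#' the two homozygote and the heterozygote karyotype groups).
#' Clusters are returned relabelled in ascending PC1-centre order.
#'
#' @param scores Numeric vector of PC1 scores.
#' @param k Number of clusters (default 3).
#' @return Integer vector of cluster assignments in `1..k` (1 = lowest
#'   PC1 centre), with the centres in attribute `"centers"`.
#' @export
cluster_pc1 <- function(scores, k = 3) {
  scores <- as.numeric(scores)
  if (length(unique(scores)) < k)
    stop("fewer than k distinct scores; cannot form ", k, " clusters")
  qs <- stats::quantile(scores, probs = (2 * seq_len(k) - 1) / (2 * k),
                        names = FALSE, type = 7)
  if (length(unique(qs)) < k)
    qs <- qs + seq(0, 1e-9, length.out = k)  # break exact quantile ties
  km <- stats::kmeans(scores, centers = matrix(qs, ncol = 1),
                      algorithm = "Lloyd", iter.max = 100)
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(k), ord)
  out <- relabel[km$cluster]
  attr(out, "centers") <- sort(km$centers[, 1])
  out
}

#' Call inversion genotypes from region SNPs
#'
#' Runs the PCA on the requested region, clusters PC1 into three
#' groups, orients PC1 so that the larger outer cluster is leftmost
#' (PC sign is arbitrary and must be pinned; with genotype counts like
#' 37:7:28 this places the convention's AA cluster on the left), labels
#' the clusters AA / AB / BB left to right, and verifies that the
#' middle (AB) cluster has higher observed heterozygosity than each
#' outer cluster — the signature of inversion heterozygotes. On
#' failure the labels are still returned with `het_check_passed =
#' FALSE`.
#'
#' @param gm A [genotype_matrix()].
#' @param region Logical/integer variant index of the inversion region
#'   (default: all sites).
#' @param maf_cutoff MAF cutoff for the PCA (default 0.40).
#' @return An `inversion_call_set`: data frame (sample_id, pc1,
#'   cluster, genotype) with attributes `cluster_het` (per-cluster
#'   observed heterozygosity over the PCA sites), `variance_explained`,
#'   `het_check_passed`, `pc1_flipped`, `n_sites`.
#' @export
call_inversion_genotypes <- function(gm, region = NULL, maf_cutoff = 0.40) {
  sub <- subset_genotypes(gm, variants = region)
  pc <- inversion_pca(sub, maf_cutoff)
  pc1 <- pc$scores[, 1]
  cl <- cluster_pc1(pc1, k = 3)
  flipped <- FALSE
  sizes <- tabulate(cl, nbins = 3)
  if (sizes[3] > sizes[1]) {      # orient: larger outer cluster leftmost
    pc1 <- -pc1
    cl <- 4L - cl
    flipped <- TRUE
  }
  genotype <- c("AA", "AB", "BB")[cl]
  het <- vapply(1:3, function(i)
    observed_heterozygosity(sub, samples = which(cl == i),
                            region = pc$site_index), numeric(1))
  names(het) <- c("AA", "AB", "BB")
  ok <- !anyNA(het) && het["AB"] > het["AA"] && het["AB"] > het["BB"]
  out <- data.frame(sample_id = gm$sample_ids, pc1 = unname(pc1),
                    cluster = cl, genotype = genotype,
                    stringsAsFactors = FALSE)
  if (!ok)
    warning("heterozygosity check failed: middle cluster is not the ",
            "most heterozygous (no inversion signal?)")
  structure(out, cluster_het = het,
            variance_explained = pc$variance_explained,
            het_check_passed = ok, pc1_flipped = flipped,
            n_sites = pc$n_sites,
            class = c("inversion_call_set", "data.frame"))
}

#' Latitude trend of inversion-haplotype dosage
#'
#' Kendall tau-b between B-haplotype dosage (0/1/2) and latitude, with
#' a two-sided permutation p-value (latitudes permuted against
#' dosages). Detects a cline in which one haplotype becomes more
#' common at higher latitude.
#'
#' @param metadata Data frame with `latitude` and `inversion_genotype`
#'   (AA/AB/BB) columns.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @return List with `tau`, `p`, `n_perm`, and per-genotype latitude
#'   summaries.
#' @export
latitude_trend <- function(metadata, n_perm = 10000, seed = NULL) {
  stopifnot(all(c("latitude", "inversion_genotype") %in% names(metadata)))
  dos <- c(AA = 0, AB = 1, BB = 2)[metadata$inversion_genotype]
  ok <- !is.na(dos) & !is.na(metadata$latitude)
  dos <- dos[ok]
  lat <- metadata$latitude[ok]
  if (length(unique(dos)) < 2)
    stop("at least two genotype groups are required")
  if (!is.null(seed)) set.seed(seed)
  tau <- stats::cor(dos, lat, method = "kendall")
  perm <- replicate(n_perm,
    stats::cor(dos, sample(lat), method = "kendall"))
  p <- (1 + sum(abs(perm) >= abs(tau))) / (n_perm + 1)
  list(tau = tau, p = p, n_perm = n_perm,
       group_means = tapply(lat, names(dos), mean))
}

#' Per-site association scan of phenotype on dosage
#'
#' A per-site linear trend test: the t-test on the slope of phenotype
#' regressed on alt-allele dosage (equivalently on the Pearson
#' correlation). This is a deliberately simple surrogate for
#' mixed-model association: the synthetic cohorts this package
#' validates against carry no kinship structure, so no relatedness
#' correction is fitted. Results on real, structured data would need a
#' mixed model instead.
#'
#' @param gm A [genotype_matrix()].
#' @param phenotype Named (by sample id) or ordered numeric phenotype
#'   vector.
#' @param alpha Significance threshold on the p-value (default 1e-5).
#' @return Data frame per site: `chrom`, `pos`, `stat` (t), `p`,
#'   `significant`. Monomorphic or data-poor sites get `NA` p and are
#'   never flagged.
#' @export
association_scan <- function(gm, phenotype, alpha = 1e-5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(names(phenotype)))
    phenotype <- phenotype[gm$sample_ids]
  if (length(phenotype) != length(gm$sample_ids))
    stop("phenotype must have one value per sample")
  if (sum(!is.na(phenotype)) < 3)
    stop("phenotype defined for fewer than 3 samples")
  if (stats::var(phenotype, na.rm = TRUE) == 0)
    stop("phenotype is constant")
  n_sites <- ncol(gm$calls)
  stat <- p <- rep(NA_real_, n_sites)
  for (j in seq_len(n_sites)) {
    x <- gm$calls[, j]
    ok <- !is.na(x) & !is.na(phenotype)
    n <- sum(ok)
    if (n < 3) next
    sx <- stats::var(x[ok]); sy <- stats::var(phenotype[ok])
    if (sx == 0 || sy == 0) next
    r <- stats::cor(x[ok], phenotype[ok])
    r <- max(min(r, 1), -1)
    t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    stat[j] <- t
    p[j] <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  p[!is.na(p)] <- pmax(p[!is.na(p)], .Machine$double.xmin)
  data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos,
             stat = stat, p = p,
             significant = !is.na(p) & p < alpha,
             stringsAsFactors = FALSE)
}

#' Check additivity of phenotype on inversion dosage
#'
#' Computes per-genotype phenotype means with bootstrap confidence
#' intervals and flags whether the means are monotone in dosage
#' (AA < AB < BB or the reverse), the expectation under an additive
#' haplotype effect.
#'
#' @param phenotypes Numeric phenotype vector.
#' @param genotypes Character vector of AA/AB/BB labels, same length.
#' @param n_boot Bootstrap replicates for the CIs (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return List with `means` (named AA/AB/BB), `ci` (2 x 3 matrix),
#'   `additive` flag (`NA` when a genotype class is absent).
#' @export
additivity_check <- function(phenotypes, genotypes, n_boot = 1000,
                             conf = 0.95, seed = NULL) {
  stopifnot(length(phenotypes) == length(genotypes))
  if (!is.null(seed)) set.seed(seed)
  lv <- c("AA", "AB", "BB")
  means <- vapply(lv, function(g) mean(phenotypes[genotypes == g]),
                  numeric(1))
  ci <- vapply(lv, function(g) {
    x <- phenotypes[genotypes == g]
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    bs <- replicate(n_boot, mean(sample(x, replace = TRUE)))
    stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  }, numeric(2))
  additive <- if (anyNA(means)) NA else
    (means["AA"] < means["AB"] && means["AB"] < means["BB"]) ||
    (means["AA"] > means["AB"] && means["AB"] > means["BB"])
  list(means = means, ci = ci, additive = additive)
}
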