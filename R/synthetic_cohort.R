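#' Configuration for a synthetic inversion cohort
#'
#' Defines a two-chromosome diploid cohort whose statistical structure
#' mirrors a genome homogenised by gene flow except for one divergent
#' inversion region: background SNPs share one allele-frequency spectrum
#' across all samples, inversion SNPs are drawn from two haplotype pools
#' (A and B) whose per-site allele frequencies differ by `d`, and a
#' small set of modifier SNPs differentiates the lesser-ecotype
#' subsample. Phenotype is additive on B-haplotype dosage; latitude
#' shifts upward with dosage.
#'
#' Defaults follow the empirical study design this generator emulates:
#' 72 samples with inversion-genotype counts 37 AA : 7 AB : 28 BB,
#' ecotype counts 26 common / 32 hoary / 14 lesser, 27 samples collected
#' in the non-breeding season.
#'
#' @param n_samples Named integer vector of samples per ecotype.
#' @param genotype_counts Named integer counts of AA/AB/BB genotypes;
#'   must sum to `sum(n_samples)`.
#' @param n_background_snps Background (genome-wide) SNP count, placed
#'   on chr1 outside the inversion and on chr2, proportional to length.
#' @param n_inversion_snps SNPs inside the inversion interval on chr1.
#' @param inversion_interval 0-based half-open `(start, end)` on chr1.
#' @param haplotype_divergence Per-site allele-frequency difference
#'   `d` in `[0, 1]` between the A and B haplotype pools.
#' @param n_modifier_snps,modifier_effect Count of lesser-ecotype
#'   modifier SNPs (on chr2) and their total phenotype effect; the
#'   modifier pool frequency difference between lesser and other
#'   ecotypes is 0.8. The effect size default is arbitrary (no
#'   quantitative value is available for it).
#' @param beta_inv Phenotype effect per B haplotype copy.
#' @param phenotype_noise_sd Gaussian phenotype noise SD.
#' @param latitude_model List `(base, dosage_shift, sd)` in degrees:
#'   latitude = base + dosage * dosage_shift + N(0, sd).
#' @param chrom_lengths Named lengths of the two chromosomes (bp).
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = c(common = 26, hoary = 32, lesser = 14),
                          genotype_counts = c(AA = 37, AB = 7, BB = 28),
                          n_background_snps = 2000,
                          n_inversion_snps = 500,
                          inversion_interval = c(3e6, 7e6),
                          haplotype_divergence = 0.8,
                          n_modifier_snps = 20,
                          modifier_effect = 0.3,
                          beta_inv = 1,
                          phenotype_noise_sd = 0.25,
                          latitude_model = list(base = 55, dosage_shift = 4,
                                                sd = 3),
                          chrom_lengths = c(chr1 = 1e7, chr2 = 5e6),
                          seed = 1L) {
  cfg <- list(n_samples = n_samples, genotype_counts = genotype_counts,
              n_background_snps = n_background_snps,
              n_inversion_snps = n_inversion_snps,
              inversion_interval = inversion_interval,
              haplotype_divergence = haplotype_divergence,
              n_modifier_snps = n_modifier_snps,
              modifier_effect = modifier_effect, beta_inv = beta_inv,
              phenotype_noise_sd = phenotype_noise_sd,
              latitude_model = latitude_model,
              chrom_lengths = chrom_lengths, seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  d <- cfg$haplotype_divergence
  if (d < 0 || d > 1) stop("haplotype_divergence must lie in [0, 1]")
  if (sum(cfg$genotype_counts) != sum(cfg$n_samples))
    stop("genotype_counts must sum to the total sample count")
  iv <- cfg$inversion_interval
  if (iv[1] < 0 || iv[2] > cfg$chrom_lengths[["chr1"]] || iv[2] <= iv[1])
    stop("inversion_interval must lie within chr1")
  if (cfg$n_inversion_snps == 0 && d > 0)
    stop("nonzero haplotype_divergence requires inversion SNPs")
  invisible(cfg)
}

#' Generate a synthetic inversion cohort
#'
#' Draws genotypes, sample metadata and ground truth per
#' [cohort_config()]. Background site frequencies come from a shared
#' Beta(0.8, 0.8) spectrum (one frequency per site for all samples,
#' i.e. no population structure). Inversion sites have pool frequencies
#' `pA` and `pB = pA +/- d`; each individual carries two haplotypes
#' drawn independently from the pools its genotype dictates, so
#' recombination suppression is implicit. Modifier sites differentiate
#' the lesser ecotype. Phenotype is
#' `dosage(B) * beta_inv + modifier score + noise`; latitude is
#' Gaussian around a dosage-shifted mean.
#'
#' @param config A [cohort_config()].
#' @return List with elements `genotypes` (a [genotype_matrix()]),
#'   `metadata` (data frame: sample_id, ecotype, latitude, season,
#'   inversion_genotype, phenotype) and `truth` (list: `genotype`
#'   per-sample, `region` per-site label in
#'   background/inversion/modifier, `phenotype`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- sum(config$n_samples)
  ecotype <- rep(names(config$n_samples), config$n_samples)
  sample_ids <- sprintf("S%02d", seq_len(n))
  genotype <- sample(rep(names(config$genotype_counts),
                         config$genotype_counts))
  dosage <- c(AA = 0L, AB = 1L, BB = 2L)[genotype]

  len1 <- config$chrom_lengths[["chr1"]]
  len2 <- config$chrom_lengths[["chr2"]]
  iv <- config$inversion_interval

  # background: chr1 outside the inversion + chr2, proportional to length
  bg_len1 <- len1 - (iv[2] - iv[1])
  n_bg1 <- round(config$n_background_snps * bg_len1 / (bg_len1 + len2))
  n_bg2 <- config$n_background_snps - n_bg1
  pos_bg1 <- sample_positions_outside(n_bg1, len1, iv)
  pos_inv <- if (config$n_inversion_snps > 0)
    sort(sample.int(iv[2] - iv[1], config$n_inversion_snps) + iv[1])
    else integer(0)
  # draw chr2 positions jointly so background and modifier never collide
  pos2 <- sample.int(len2, n_bg2 + config$n_modifier_snps)
  pos_bg2 <- sort(pos2[seq_len(n_bg2)])
  pos_mod <- sort(pos2[n_bg2 + seq_len(config$n_modifier_snps)])

  p_bg <- stats::rbeta(n_bg1 + n_bg2, 0.8, 0.8)
  bg_calls <- matrix(stats::rbinom(n * length(p_bg), 2,
                                   rep(p_bg, each = n)), nrow = n)

  d <- config$haplotype_divergence
  n_inv <- config$n_inversion_snps
  inv_calls <- matrix(integer(0), nrow = n)
  if (n_inv > 0) {
    pA <- stats::runif(n_inv, 0, 1 - d)
    pB <- pA + d
    flip <- stats::runif(n_inv) < 0.5   # random sign of the divergence
    tmp <- pA[flip]; pA[flip] <- pB[flip]; pB[flip] <- tmp
    hap_from <- function(p) matrix(stats::rbinom(n * n_inv, 1,
                                   rep(p, each = n)), nrow = n)
    hA1 <- hap_from(pA); hA2 <- hap_from(pA)
    hB1 <- hap_from(pB); hB2 <- hap_from(pB)
    inv_calls <- matrix(0L, n, n_inv)
    inv_calls[dosage == 0L, ] <- hA1[dosage == 0L, ] + hA2[dosage == 0L, ]
    inv_calls[dosage == 1L, ] <- hA1[dosage == 1L, ] + hB1[dosage == 1L, ]
    inv_calls[dosage == 2L, ] <- hB1[dosage == 2L, ] + hB2[dosage == 2L, ]
  }

  n_mod <- config$n_modifier_snps
  mod_calls <- matrix(integer(0), nrow = n)
  if (n_mod > 0) {
    d_mod <- 0.8
    p_other <- stats::runif(n_mod, 0, 1 - d_mod)
    p_lesser <- p_other + d_mod
    mod_calls <- matrix(0L, n, n_mod)
    is_lesser <- ecotype == "lesser"
    mod_calls[is_lesser, ] <- matrix(stats::rbinom(sum(is_lesser) * n_mod, 2,
                              rep(p_lesser, each = sum(is_lesser))),
                              ncol = n_mod)
    mod_calls[!is_lesser, ] <- matrix(stats::rbinom(sum(!is_lesser) * n_mod,
                               2, rep(p_other, each = sum(!is_lesser))),
                               ncol = n_mod)
  }

  variants <- data.frame(
    chrom = c(rep("chr1", n_bg1 + n_inv), rep("chr2", n_bg2 + n_mod)),
    pos = c(pos_bg1, pos_inv, pos_bg2, pos_mod),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  region <- c(rep("background", n_bg1), rep("inversion", n_inv),
              rep("background", n_bg2), rep("modifier", n_mod))
  calls <- cbind(bg_calls[, seq_len(n_bg1), drop = FALSE], inv_calls,
                 bg_calls[, n_bg1 + seq_len(n_bg2), drop = FALSE],
                 mod_calls)
  # genotype_matrix() sorts by (chrom, pos); apply the same order to the
  # truth labels
  ord <- order(variants$chrom, variants$pos)
  gm <- genotype_matrix(calls[, ord, drop = FALSE],
                        variants[ord, , drop = FALSE], sample_ids)
  region <- region[ord]

  mod_score <- if (n_mod > 0)
    config$modifier_effect * rowSums(mod_calls) / (2 * n_mod) else 0
  phenotype <- dosage * config$beta_inv + mod_score +
    stats::rnorm(n, 0, config$phenotype_noise_sd)
  lm <- config$latitude_model
  latitude <- lm$base + dosage * lm$dosage_shift + stats::rnorm(n, 0, lm$sd)
  latitude <- pmin(pmax(latitude, -90), 90)
  season <- sample(rep(c("nonbreeding", "breeding"), c(27, n - 27))[seq_len(n)])

  metadata <- data.frame(sample_id = sample_ids, ecotype = ecotype,
                         latitude = latitude, season = season,
                         inversion_genotype = genotype,
                         phenotype = phenotype,
                         stringsAsFactors = FALSE)
  validate_metadata(metadata)
  list(genotypes = gm, metadata = metadata,
       truth = list(genotype = stats::setNames(genotype, sample_ids),
                    region = stats::setNames(region, colnames(gm$calls)),
                    phenotype = stats::setNames(phenotype, sample_ids)))
}

# n distinct positions on [1, len] excluding the 0-based half-open
# interval iv (i.e. excluding pos with iv[1] < pos <= iv[2])
sample_positions_outside <- function(n, len, iv) {
  u <- sample.int(len - (iv[2] - iv[1]), n)
  sort(ifelse(u <= iv[1], u, u + (iv[2] - iv[1])))
}

#' Write a cohort to disk
#'
#' Emits the VCF, the metadata TSV and a per-site truth TSV next to each
#' other.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             metadata = file.path(dir, paste0(prefix, "_metadata.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_vcf(cohort$genotypes, paths[["vcf"]])
  utils::write.table(cohort$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_df <- data.frame(site = names(cohort$truth$region),
                         region = cohort$truth$region)
  utils::write.table(truth_df, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
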