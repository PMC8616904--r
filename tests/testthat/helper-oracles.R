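# Independent brute-force oracles: everything here works by explicit
# enumeration of chromosome pairs / arithmetic terms, never by calling
# the package's estimator code paths.

# expand a dosage vector into a list of allele calls (two chromosomes
# per non-missing sample)
chromosomes_of <- function(dosages) {
  dosages <- dosages[!is.na(dosages)]
  unlist(lapply(dosages, function(d) c(rep(1, d), rep(0, 2 - d))))
}

# pi as the fraction of differing unordered chromosome pairs
oracle_site_pi <- function(dosages) {
  al <- chromosomes_of(dosages)
  n <- length(al)
  if (n < 2) return(NA_real_)
  diffs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diffs <- diffs + (al[i] != al[j])
  diffs / choose(n, 2)
}

# dxy as the fraction of differing cross-group chromosome pairs
oracle_site_dxy <- function(dos1, dos2) {
  a1 <- chromosomes_of(dos1); a2 <- chromosomes_of(dos2)
  if (!length(a1) || !length(a2)) return(NA_real_)
  mean(outer(a1, a2, `!=`))
}

# Hudson window FST from raw genotype lists
oracle_window_fst <- function(dos1, dos2) {
  if (is.null(dim(dos1))) dos1 <- matrix(dos1, ncol = 1)
  if (is.null(dim(dos2))) dos2 <- matrix(dos2, ncol = 1)
  hw <- hb <- c()
  for (j in seq_len(ncol(dos1))) {
    p1 <- oracle_site_pi(dos1[, j]); p2 <- oracle_site_pi(dos2[, j])
    if (is.na(p1) || is.na(p2)) next
    hw <- c(hw, (p1 + p2) / 2)
    hb <- c(hb, oracle_site_dxy(dos1[, j], dos2[, j]))
  }
  if (!length(hw) || mean(hb) == 0) return(NA_real_)
  1 - mean(hw) / mean(hb)
}

# squared Pearson correlation from first principles
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  (sxy / sqrt(sxx * syy))^2
}

# symmetric frequency D by explicit per-site accumulation
oracle_d <- function(p1, p2, p3, p4) {
  num <- den <- 0
  for (i in seq_along(p1)) {
    abba <- (1 - p1[i]) * p2[i] * p3[i] * (1 - p4[i]) +
      p1[i] * (1 - p2[i]) * (1 - p3[i]) * p4[i]
    baba <- p1[i] * (1 - p2[i]) * p3[i] * (1 - p4[i]) +
      (1 - p1[i]) * p2[i] * (1 - p3[i]) * p4[i]
    num <- num + (abba - baba)
    den <- den + (abba + baba)
  }
  num / den
}

# quick genotype_matrix builder: calls is samples x sites, positions
# default to 1 kb spacing on one chromosome
make_gm <- function(calls, pos = NULL, chrom = "chr1") {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000L
  genotype_matrix(calls,
                  data.frame(chrom = chrom, pos = as.integer(pos),
                             ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  sprintf("s%02d", seq_len(nrow(calls))))
}

# small shared default cohort, generated once per test run
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_config())
    cache
  }
})
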