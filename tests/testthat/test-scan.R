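# Windowed diversity/differentiation statistics against brute-force
# pair-enumeration oracles

test_that("site_pi matches hand values and the pair-enumeration oracle", {
  expect_equal(site_pi(c(0L, 0L, 0L)), 0)          # monomorphic
  expect_equal(site_pi(c(2L, 2L)), 0)
  expect_equal(site_pi(matrix(1L, 1, 1)), 1)       # one het sample: 2 chroms
  expect_equal(site_pi(c(1L, 1L)), 2 / 3)          # 4 chroms, counts 2/2
  expect_equal(site_pi(c(2L, 0L)), 2 / 3)
  set.seed(21)
  for (rep in 1:20) {
    dos <- sample(c(0:2, NA), 8, replace = TRUE)
    expect_equal(site_pi(dos), oracle_site_pi(dos), tolerance = 1e-12)
  }
  expect_equal(site_pi(c(NA, NA, 1L)), 1)  # one called sample: n = 2
  expect_true(is.na(site_pi(rep(NA_integer_, 3))))  # n < 2: skipped
})

test_that("site_dxy matches hand values and the oracle", {
  expect_equal(site_dxy(1, 0), 1)
  expect_equal(site_dxy(0.5, 0.5), 0.5)
  expect_equal(site_dxy(0.2, 0.7), 0.62)
  set.seed(22)
  for (rep in 1:20) {
    d1 <- sample(0:2, 6, replace = TRUE)
    d2 <- sample(0:2, 4, replace = TRUE)
    p1 <- sum(d1) / 12; p2 <- sum(d2) / 8
    expect_equal(site_dxy(p1, p2), oracle_site_dxy(d1, d2),
                 tolerance = 1e-12)
  }
})

test_that("window FST equals the direct pair-enumeration oracle", {
  # 5-site toy with listed genotypes
  dos1 <- rbind(c(0L, 1L, 2L, 0L, 1L),
                c(0L, 2L, 2L, 1L, 0L),
                c(1L, 1L, 2L, 0L, 0L))
  dos2 <- rbind(c(2L, 0L, 0L, 0L, 1L),
                c(2L, 1L, 0L, 1L, 1L),
                c(1L, 0L, 1L, 0L, 2L))
  expect_equal(window_fst(dos1, dos2)$fst, oracle_window_fst(dos1, dos2),
               tolerance = 1e-12)
  # fixed differences at every site -> FST = 1
  expect_equal(window_fst(matrix(0L, 3, 4), matrix(2L, 3, 4))$fst, 1)
  # random toys with missing data
  set.seed(23)
  for (rep in 1:10) {
    d1 <- matrix(sample(c(0:2, NA), 18, TRUE), nrow = 3)
    d2 <- matrix(sample(c(0:2, NA), 18, TRUE), nrow = 3)
    got <- window_fst(d1, d2)$fst
    want <- oracle_window_fst(d1, d2)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("FST is ~0 for groups sampled from identical frequencies", {
  set.seed(24)
  p <- stats::runif(400, 0.1, 0.9)
  d1 <- vapply(p, function(q) stats::rbinom(20, 2, q), integer(20))
  d2 <- vapply(p, function(q) stats::rbinom(20, 2, q), integer(20))
  expect_lt(abs(window_fst(d1, d2)$fst), 0.03)
})

test_that("FST is invariant under allele-label swap", {
  set.seed(25)
  d1 <- matrix(sample(0:2, 30, TRUE), nrow = 5)
  d2 <- matrix(sample(0:2, 30, TRUE), nrow = 5)
  expect_equal(window_fst(d1, d2)$fst, window_fst(2L - d1, 2L - d2)$fst,
               tolerance = 1e-12)
})

test_that("dxy of a group with itself relates to pi by (n-1)/n", {
  set.seed(26)
  dos <- sample(0:2, 10, TRUE)
  p <- sum(dos) / 20
  n <- 20
  expect_equal(site_dxy(p, p), 2 * p * (1 - p), tolerance = 1e-12)
  expect_equal(site_dxy(p, p), ((n - 1) / n) * site_pi(dos),
               tolerance = 1e-12)
})

test_that("observed heterozygosity counts dosage-1 calls", {
  expect_equal(observed_heterozygosity(make_gm(matrix(c(0L, 2L, 2L, 0L),
                                                      2))), 0)
  expect_equal(observed_heterozygosity(make_gm(matrix(1L, 2, 3))), 1)
  # 2 samples x 4 sites with 3 het calls of 8
  calls <- rbind(c(1L, 0L, 2L, 1L), c(0L, 1L, 2L, 0L))
  expect_equal(observed_heterozygosity(make_gm(calls)), 3 / 8)
  expect_error(observed_heterozygosity(make_gm(calls), region = logical(4)),
               "no sites")
})

test_that("scan rows agree with direct per-site computation", {
  set.seed(27)
  calls <- matrix(sample(c(0:2, NA), 60, TRUE, prob = c(.3, .3, .3, .1)),
                  nrow = 6)
  gm <- make_gm(calls)
  groups <- list(g1 = gm$sample_ids[1:3], g2 = gm$sample_ids[4:6])
  w <- make_windows(c(chr1 = 11000), 11000)
  sc <- popgen_scan(gm, groups, w)
  expect_equal(nrow(sc), 1L)
  d1 <- calls[1:3, , drop = FALSE]; d2 <- calls[4:6, , drop = FALSE]
  pi1 <- site_pi(d1); pi2 <- site_pi(d2)
  usable <- !is.na(pi1) & !is.na(pi2)
  expect_equal(sc$n_sites, sum(usable))
  expect_equal(sc$pi_g1, mean(pi1[usable]))
  expect_equal(sc$fst_g1_g2,
               window_fst(d1[, usable, drop = FALSE],
                          d2[, usable, drop = FALSE])$fst)
  expect_error(popgen_scan(gm, list(g1 = gm$sample_ids[1:3],
                                    g2 = character(0)), w), "empty group")
  expect_error(popgen_scan(gm, list(g1 = gm$sample_ids[1:3],
                                    g2 = gm$sample_ids[3:6]), w),
               "non-overlapping")
})

test_that("planted inversion dominates the FST landscape", {
  co <- default_cohort()
  md <- co$metadata
  grp <- split(md$sample_id, md$inversion_genotype)
  w <- make_windows(c(chr1 = 1e7, chr2 = 5e6), 25000)
  sc <- popgen_scan(co$genotypes, grp[c("AA", "BB")], w)
  inside <- sc$chrom == "chr1" & sc$start >= 3e6 & sc$end <= 7e6
  f_in <- mean(sc$fst_AA_BB[inside], na.rm = TRUE)
  f_out <- mean(sc$fst_AA_BB[!inside], na.rm = TRUE)
  expect_gt(f_in, 5 * abs(f_out))
  # homozygote pi depressed relative to heterozygote pi inside
  sc2 <- popgen_scan(co$genotypes, grp[c("AA", "AB")], w[inside, ])
  expect_lt(mean(sc2$pi_AA, na.rm = TRUE), mean(sc2$pi_AB, na.rm = TRUE))
})

test_that("stronger planted divergence raises inversion FST", {
  w <- make_windows(c(chr1 = 1e7), 25000)
  w <- w[w$start >= 3e6 & w$end <= 7e6, ]
  mean_fst <- vapply(c(0.3, 0.8), function(d) {
    co <- generate_cohort(cohort_config(haplotype_divergence = d,
                                        n_background_snps = 200,
                                        seed = 28))
    grp <- split(co$metadata$sample_id, co$metadata$inversion_genotype)
    sc <- popgen_scan(co$genotypes, grp[c("AA", "BB")], w)
    mean(sc$fst_AA_BB, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean_fst[2], mean_fst[1])
})

test_that("scan TSV output records the estimator", {
  co <- default_cohort()
  grp <- split(co$metadata$sample_id, co$metadata$inversion_genotype)
  w <- make_windows(c(chr1 = 1e7), 5e6)
  sc <- popgen_scan(co$genotypes, grp[c("AA", "BB")], w)
  f <- tempfile(fileext = ".tsv")
  write_scan_tsv(sc, f)
  expect_match(readLines(f, n = 1), "Hudson")
})
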