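# ABBA-BABA D, block jackknife, topology catalog and weighting

test_that("D matches pattern counts and the arithmetic oracle", {
  # binary sites: ABBA = (0,1,1,0), BABA = (1,0,1,0)
  abba <- matrix(rep(c(0, 1, 1, 0), 10), ncol = 4, byrow = TRUE)
  baba <- matrix(rep(c(1, 0, 1, 0), 10), ncol = 4, byrow = TRUE)
  eq <- rbind(abba, baba)
  expect_equal(d_statistic(eq[, 1], eq[, 2], eq[, 3], eq[, 4])$D, 0)
  tab <- rbind(abba[1:10, ], abba[1:5, ], baba[1:5, ])  # 15 vs 5
  expect_equal(d_statistic(tab[, 1], tab[, 2], tab[, 3], tab[, 4])$D, 0.5)
  # 6-site frequency table, term-by-term oracle
  p1 <- c(0.10, 0.30, 0.00, 0.80, 0.50, 0.20)
  p2 <- c(0.70, 0.20, 0.90, 0.10, 0.55, 0.60)
  p3 <- c(0.60, 0.80, 0.85, 0.20, 0.50, 0.70)
  p4 <- c(0.00, 0.10, 0.05, 0.90, 0.00, 0.15)
  expect_equal(d_statistic(p1, p2, p3, p4)$D, oracle_d(p1, p2, p3, p4),
               tolerance = 1e-12)
  expect_error(d_statistic(0.5, 0.5, 0, 0), "undefined")
})

test_that("D flips sign on P1/P2 swap and ignores allele labels", {
  set.seed(61)
  p <- matrix(stats::runif(24), ncol = 4)
  d <- d_statistic(p[, 1], p[, 2], p[, 3], p[, 4])$D
  expect_equal(d_statistic(p[, 2], p[, 1], p[, 3], p[, 4])$D, -d,
               tolerance = 1e-12)
  expect_equal(d_statistic(1 - p[, 1], 1 - p[, 2], 1 - p[, 3],
                           1 - p[, 4])$D, d, tolerance = 1e-12)
})

test_that("block jackknife handles degenerate identical blocks", {
  num <- rep(0.2, 1000)
  den <- rep(1.0, 1000)
  expect_warning(jk <- block_jackknife(num, den, block_size = 100),
                 "zero")
  expect_equal(jk$D, 0.2)
  expect_lte(jk$p, 1e-300)
  expect_error(block_jackknife(num[1:500], den[1:500], block_size = 100),
               "fewer than 10 blocks")
})

test_that("jackknife Z has nominal coverage under the null", {
  set.seed(62)
  n_rep <- 200
  covered <- vapply(seq_len(n_rep), function(i) {
    q12 <- stats::runif(1000, 0.05, 0.95)
    q34 <- stats::runif(1000, 0.05, 0.95)
    p1 <- stats::rbinom(1000, 20, q12) / 20
    p2 <- stats::rbinom(1000, 20, q12) / 20
    p3 <- stats::rbinom(1000, 20, q34) / 20
    p4 <- stats::rbinom(1000, 20, q34) / 20
    abs(d_test(p1, p2, p3, p4, block_size = 50)$z) < 2
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("planted gene flow yields positive significant D", {
  set.seed(63)
  n <- 2000
  q <- stats::runif(n, 0.05, 0.95)
  p1 <- stats::rbinom(n, 20, q) / 20
  p2 <- stats::rbinom(n, 20, q) / 20
  p3 <- stats::rbinom(n, 20, stats::runif(n, 0.05, 0.95)) / 20
  flow <- sample(n, n / 5)              # 20% of sites introgressed
  p3[flow] <- p2[flow]
  p4 <- stats::rbinom(n, 20, 0.1) / 20
  dt <- d_test(p1, p2, p3, p4, block_size = 100)
  expect_gt(dt$D, 0)
  expect_lt(dt$p, 0.05)
})

test_that("topology catalog counts follow the double factorial", {
  # (2g-5)!! for g = 3..7
  dfact <- function(k) prod(seq(k, 1, by = -2))
  for (g in 3:7) {
    cat_g <- enumerate_topologies(letters[1:g])
    expect_equal(nrow(cat_g), if (g == 3) 1 else dfact(2 * g - 5))
    expect_false(any(duplicated(cat_g$key)))
  }
  expect_error(enumerate_topologies(letters[1:2]), "3 and 7")
  expect_error(enumerate_topologies(letters[1:8]), "3 and 7")
})

test_that("sister-pair filtering counts cherries correctly", {
  cat4 <- enumerate_topologies(c("a", "b", "c", "d"))
  expect_equal(nrow(cat4), 3L)
  expect_equal(sum(has_sister_pair(cat4, c("a", "b"))), 1L)
  cat5 <- enumerate_topologies(c("hapA", "hapB", "x", "y", "z"))
  # the printed count: three of the fifteen 5-taxon topologies carry
  # a given sister relationship
  expect_equal(sum(has_sister_pair(cat5, c("hapA", "hapB"))), 3L)
})

test_that("reciprocal monophyly gives weight 1 and weights sum to 1", {
  gs <- c(a = 3, b = 2, c = 2, d = 2, e = 1)
  trees <- generate_window_trees(5, gs, c("(((a,b),(c,d)),e);" = 1),
                                 seed = 64)
  for (tr in trees) {
    w <- topology_weights(tr, mode = "exact")
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_equal(unname(max(w)), 1)
  }
})

test_that("exact and Monte-Carlo weights agree on scattered trees", {
  gs <- c(a = 3, b = 3, c = 2, d = 2, e = 2)
  trees <- generate_window_trees(3, gs, c("(((a,b),(c,d)),e);" = 1),
                                 scatter = 0.5, seed = 65)
  for (tr in trees) {
    we <- topology_weights(tr, mode = "exact")
    wm <- topology_weights(tr, mode = "montecarlo",
                           n_subsamples = 10000, seed = 66)
    expect_equal(sum(wm), 1, tolerance = 1e-9)
    expect_lt(max(abs(we - wm)), 0.02)
  }
})

test_that("exact weights are invariant to tip order", {
  gs <- c(a = 2, b = 2, c = 2, d = 1, e = 1)
  tr <- generate_window_trees(1, gs, c("(((a,b),(c,d)),e);" = 1),
                              scatter = 0.6, seed = 67)[[1]]
  w1 <- topology_weights(tr, mode = "exact")
  tr2 <- ape::read.tree(text = ape::write.tree(ape::rotateConstr(
    tr, rev(tr$tip.label))))
  w2 <- topology_weights(tr2, mode = "exact")
  expect_equal(w1, w2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("weight summaries aggregate sister topologies", {
  gs <- c(a = 2, b = 2, c = 2, d = 2, e = 1)
  trees <- generate_window_trees(6, gs, c("(((a,b),(c,d)),e);" = 1),
                                 seed = 68)
  ws <- lapply(trees, topology_weights, mode = "exact")
  sw <- summarize_weights(ws, c("a", "b"))
  expect_equal(sw$aggregate, 1)
  expect_equal(length(sw$sister_topologies), 3L)
  # uniform weights spread 3/15 over a sister pair
  cat5 <- attr(ws[[1]], "catalog")
  wu <- rep(1 / 15, 15)
  names(wu) <- cat5$newick
  attr(wu, "catalog") <- cat5
  expect_equal(summarize_weights(list(wu), c("a", "b"))$aggregate, 3 / 15)
  expect_error(summarize_weights(ws, c("a", "nope")), "pair")
})

test_that("groups with no tip in the tree are reported", {
  gs <- c(a = 2, b = 2, c = 1)
  tr <- generate_window_trees(1, gs, c("((a,b),c);" = 1), seed = 69)[[1]]
  map <- groups_from_labels(tr)
  expect_error(topology_weights(tr, tip_to_group = map,
                                catalog = enumerate_topologies(
                                  c("a", "b", "c", "ghost"))),
               "catalog|group")
})
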