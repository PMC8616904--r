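# Spatial forward-time supergene models: unit behaviour and
# population-genetic invariants at scaled-down sizes

test_that("initial states honour the configuration", {
  cfg <- sim_config(N = 400, init_B_frequency = 0, seed = 70)
  set.seed(70)
  st <- init_population(cfg)
  expect_true(all(state_dosage(st) == 0))            # all AA
  cfg2 <- sim_config(N = 2000, init_B_frequency = 0.5, seed = 71)
  set.seed(71)
  st2 <- init_population(cfg2)
  # E[n_AB]/N = 0.5; binomial 99% interval
  expect_lt(abs(mean(state_dosage(st2) == 1) - 0.5),
            3 * sqrt(0.25 / 2000))
  expect_true(all(st2$x >= 0 & st2$x <= 1 & st2$y >= 0 & st2$y <= 1))
  # determinism
  set.seed(72); a <- init_population(cfg2)
  set.seed(72); b <- init_population(cfg2)
  expect_identical(a, b)
  # model 2: populations fixed for alternative haplotypes
  cfg3 <- sim_config(model = 2, N = 100, seed = 73)
  set.seed(73)
  st3 <- init_population(cfg3)
  expect_true(all(state_dosage(st3)[st3$pop == 0] == 0))
  expect_true(all(state_dosage(st3)[st3$pop == 1] == 2))
})

test_that("fitness follows the linear-mismatch, competition-scaled form", {
  cfg <- sim_config(N = 3, s = 0.4, competition_strength = 0, seed = 74)
  st <- list(x = c(0.5, 0.5, 0.5), y = c(1, 1, 0.5), pop = c(0L, 0L, 0L),
             inv1 = c(1L, 0L, 1L), inv2 = c(1L, 0L, 0L),
             neut1 = matrix(0L, 3, 0), neut2 = matrix(0L, 3, 0))
  class(st) <- "sim_state"
  w <- sim_fitness(st, cfg)
  expect_equal(w[1], 1)                  # BB at y = 1: zero mismatch
  expect_equal(w[2], 0.6)                # AA at y = 1: 1 - 0.4 * 1
  expect_equal(w[3], 1)                  # AB at y = 0.5
  cfg0 <- sim_config(N = 3, s = 0, competition_strength = 0, seed = 75)
  expect_equal(unique(sim_fitness(st, cfg0)), 1)
  # crowding penalty: neighbours within the radius divide fitness
  cfgc <- sim_config(N = 3, s = 0, competition_strength = 0.5,
                     competition_radius = 0.2, seed = 76)
  wc <- sim_fitness(st, cfgc)
  expect_equal(wc[1], 1 / (1 + 0.5 * 1))  # one neighbour at same point
  expect_equal(wc[3], 1)                  # isolated individual
})

test_that("mate choice weights follow fitness and the assortment kernel", {
  set.seed(77)
  expect_equal(choose_mate(2L, 1.0, 2L, 0.5), 1L)   # single candidate
  # a = 0, equal fitness: uniform choice over 4 candidates
  draws <- replicate(10000, choose_mate(c(0L, 1L, 2L, 1L), rep(1, 4),
                                        0L, 0))
  gof <- stats::chisq.test(tabulate(draws, 4), p = rep(0.25, 4))
  expect_gt(gof$p.value, 0.001)
  # a = 0.99: same-genotype mate almost always chosen
  draws2 <- replicate(2000, choose_mate(c(0L, 1L, 2L), rep(1, 3), 0L, 0.99))
  expect_gte(mean(draws2 == 1L), 0.98)
})

test_that("gametes respect linkage and suppressed heterozygote recombination", {
  cfg <- sim_config(n_neutral_loci = 20, mutation_rate = 0,
                    recombination_rate = 0, seed = 78)
  neut <- rbind(rep(1L, 20), rep(0L, 20))
  set.seed(78)
  for (i in 1:20) {
    g <- recombine(c(1L, 0L), neut, cfg)
    # no recombination: gamete is an exact parental haplotype
    expect_true(identical(g$neutral, neut[1, ]) ||
                identical(g$neutral, neut[2, ]))
    expect_equal(g$inv, if (identical(g$neutral, neut[1, ])) 1L else 0L)
  }
  # heavy recombination in an inversion heterozygote: loci inside the
  # inversion stay with their inversion allele
  cfg2 <- sim_config(n_neutral_loci = 20, mutation_rate = 0,
                     recombination_rate = 1e-4, seed = 79)
  inside <- cfg2$loci_positions >= 25000 & cfg2$loci_positions < 75000
  set.seed(79)
  crossed_outside <- FALSE
  for (i in 1:100) {
    g <- recombine(c(1L, 0L), neut, cfg2)
    expect_true(all(g$neutral[inside] == g$inv))
    if (any(g$neutral[!inside] != g$inv)) crossed_outside <- TRUE
  }
  expect_true(crossed_outside)   # recombination does act outside
  # homozygous parent: crossovers land anywhere, inversion intact
  set.seed(80)
  g3 <- recombine(c(1L, 1L), neut, cfg2)
  expect_equal(g3$inv, 1L)
})

test_that("generations conserve population size and obey dispersal", {
  cfg <- sim_config(N = 120, generations = 1, s = 0.3, a = 0.2,
                    dispersal_sd = 0, n_neutral_loci = 4, seed = 81)
  set.seed(81)
  st <- init_population(cfg)
  nxt <- step_generation(st, cfg)
  expect_equal(length(nxt$x), 120L)
  expect_equal(sum(tabulate(state_dosage(nxt) + 1L, 3)), 120L)
  # zero dispersal: every offspring sits on a parent position
  expect_true(all(nxt$x %in% st$x))
  expect_true(all(nxt$y %in% st$y))
})

test_that("offspring are in Hardy-Weinberg proportions under random mating", {
  cfg <- sim_config(N = 2000, s = 0, a = 0, competition_strength = 0,
                    n_neutral_loci = 0, seed = 82)
  set.seed(82)
  st <- init_population(cfg)
  p <- mean(c(st$inv1, st$inv2))
  nxt <- step_generation(st, cfg)
  g <- state_dosage(nxt)
  expect_lt(abs(mean(g == 1) - 2 * p * (1 - p)), 0.04)
  expect_lt(abs(mean(g == 0) - (1 - p)^2), 0.04)
  expect_lt(abs(mean(g == 2) - p^2), 0.04)
})

test_that("seeded runs are exactly reproducible", {
  cfg <- sim_config(N = 60, generations = 30, iterations = 2, s = 0.4,
                    a = 0.5, n_neutral_loci = 6, seed = 83)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$trajectories, r2$trajectories)
  expect_identical(r1$final_states, r2$final_states)
})

test_that("zero generations reflect the initial draw", {
  cfg <- sim_config(N = 50, generations = 0, iterations = 3,
                    init_B_frequency = 0.5, n_neutral_loci = 0, seed = 84)
  r <- run_simulation(cfg)
  expect_true(all(r$summary$stable ==
                  (r$summary$b_frequency > 0 & r$summary$b_frequency < 1)))
})

test_that("ratio difference scores signed heterozygote excess", {
  expect_equal(ratio_difference(c(37, 7, 28) * 3), 0)
  expect_equal(ratio_difference(c(50, 0, 50)), -7 / 72)
  expect_equal(ratio_difference(c(25, 50, 25)), 0.5 - 7 / 72)
  expect_error(ratio_difference(c(0, 0, 0)), "nonzero")
})

test_that("spatial stratification flags ordered gradients", {
  pos <- c(0.1, 0.12, 0.5, 0.55, 0.9, 0.95)
  gt <- c("AA", "AA", "AB", "AB", "BB", "BB")
  ss <- spatial_stratification(pos, gt)
  expect_true(ss$stratified)
  expect_equal(unname(ss$mean_y), c(0.11, 0.525, 0.925))
  # genotype-independent positions: ordered with probability ~1/6
  set.seed(85)
  hits <- vapply(1:600, function(i)
    isTRUE(spatial_stratification(stats::runif(30),
                                  sample(0:2, 30, TRUE),
                                  n_boot = 2)$stratified), logical(1))
  expect_lt(abs(mean(hits) - 1 / 6), 0.06)
  expect_true(is.na(spatial_stratification(stats::runif(5),
                                           rep("AA", 5))$stratified))
})

test_that("suppressed heterozygote recombination preserves the inversion
           linkage signature seen by the scan and LD modules", {
  cfg <- sim_config(model = 1, N = 200, generations = 150, iterations = 6,
                    s = 0.5, a = 0, n_neutral_loci = 60,
                    mutation_rate = 1e-4, recombination_rate = 5e-5,
                    init_neutral_from_inversion = TRUE, seed = 7)
  r <- run_simulation(cfg)
  ok <- which(r$summary$stable & r$summary$n_AA >= 3 &
              r$summary$n_AB >= 3 & r$summary$n_BB >= 3)
  expect_gt(length(ok), 0)
  it <- ok[1]
  st <- r$final_states[[it]]
  gm <- state_to_genotypes(st, cfg)
  g <- state_dosage(st)
  inv <- variants_in_region(gm, "sim1", 25000, 75000)
  expect_gt(sum(inv), 2); expect_gt(sum(!inv), 2)
  r2_in <- ld_decay(gm, inv, max_distance = 5e4, bin_width = 5e4)$mean_r2
  r2_out <- ld_decay(gm, !inv, max_distance = 5e4, bin_width = 5e4)$mean_r2
  expect_gt(r2_in, r2_out)
  aa <- which(g == 0); ab <- which(g == 1); bb <- which(g == 2)
  pi_aa <- mean(site_pi(gm$calls[aa, inv, drop = FALSE]), na.rm = TRUE)
  pi_ab <- mean(site_pi(gm$calls[ab, inv, drop = FALSE]), na.rm = TRUE)
  expect_lt(pi_aa, pi_ab)   # homozygote diversity depressed inside
  fst_in <- window_fst(gm$calls[aa, inv, drop = FALSE],
                       gm$calls[bb, inv, drop = FALSE])$fst
  fst_out <- window_fst(gm$calls[aa, !inv, drop = FALSE],
                        gm$calls[bb, !inv, drop = FALSE])$fst
  expect_gt(fst_in, fst_out)
})

test_that("config files round-trip through key = value text", {
  cfg <- sim_config(model = 2, N = 150, m = 0.02, seed = 86)
  f <- tempfile(fileext = ".cfg")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$N, 150)
  expect_equal(back$m, 0.02)
  expect_equal(back$inversion_interval, cfg$inversion_interval)
  expect_equal(back$loci_positions, cfg$loci_positions)
})

test_that("a 1x1 sweep equals a bare run", {
  cfg <- sim_config(N = 80, generations = 60, iterations = 4, s = 0.5,
                    a = 0.9, n_neutral_loci = 0, seed = 87)
  sw <- sweep_simulations(cfg, s_values = 0.5, axis_values = 0.9)
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1          # the sweep derives per-cell seeds
  r <- run_simulation(cfg2)
  expect_equal(sw$stable_fraction, mean(r$summary$stable))
  if (any(r$summary$stable))
    expect_equal(sw$mean_n_AB, mean(r$summary$n_AB[r$summary$stable]))
})
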