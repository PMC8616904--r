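#' Configuration for the spatial supergene-maintenance models
#'
#' Two spatially explicit forward-time Wright-Fisher-style models of a
#' chromosomal inversion polymorphism. Model 1: one population in the
#' unit square with spatially varying selection along the y-axis,
#' assortative mating of strength `a`, and local competition (crowded
#' individuals lose fitness). Model 2: two populations in two unit
#' squares that span the same selection gradient, initially fixed for
#' alternative inversion haplotypes (one per homozygote ecotype) and
#' exchanging migrants with per-offspring probability `m`; migrants
#' keep their coordinates and only switch squares.
#'
#' Phenotype is additive on inversion-B dosage `g`: `phi = g / 2`,
#' matched against the gradient position; fitness is
#' `max(0, 1 - s * |gradient position - phi|)`, divided in model 1 by
#' `1 + competition_strength * n_neighbours_within_radius`. Mating is
#' hermaphroditic: mothers are drawn in proportion to fitness and pick
#' a mate within `mate_search_radius` with weight
#' `fitness * (1 - a)^|g_focal - g_mate|`.
#'
#' The historical-scale run is `N = 1000` diploids on a 100-kb
#' chromosome with a 50-kb inversion for 10,000 generations and 50
#' iterations; scaled-down settings (N = 100-200, 1,000-2,000
#' generations) reproduce the qualitative regimes at desk scale.
#'
#' @param model 1 (assortative mating + competition) or 2 (two
#'   populations + migration).
#' @param N Total diploid population size (model 2: split evenly
#'   between the two populations).
#' @param generations Generations per iteration.
#' @param iterations Independent iterations.
#' @param s Selection strength (>= 0).
#' @param a Assortative-mating strength in `[0, 1)` (model 1).
#' @param m Per-offspring migration probability in `[0, 0.5]`
#'   (model 2).
#' @param competition_radius,competition_strength Neighbourhood radius
#'   and crowding penalty (model 1).
#' @param mate_search_radius Mate search radius. The default (1.5)
#'   exceeds the habitat diameter, i.e. mate choice is
#'   population-wide and spatial structure enters only through
#'   selection, competition and dispersal; set a small radius to make
#'   mating itself spatially local.
#' @param dispersal_sd SD of offspring dispersal from the mother
#'   (reflected at the habitat boundary).
#' @param chromosome_length Chromosome length in bp.
#' @param inversion_interval Inversion `(start, end)` in bp.
#' @param n_neutral_loci Neutral biallelic loci, evenly spaced along
#'   the chromosome (initialised monomorphic).
#' @param mutation_rate Per-locus per-gamete neutral mutation rate.
#' @param recombination_rate Per-bp crossover rate; crossovers inside
#'   the inversion are rejected in inversion heterozygotes.
#' @param init_B_frequency Initial B-haplotype frequency (model 1;
#'   model 2 starts its populations fixed for alternative haplotypes).
#' @param init_neutral_from_inversion If `TRUE`, each haplotype's
#'   neutral alleles start equal to its inversion allele (two fully
#'   diverged haplotype pools, emulating an old inversion); if `FALSE`
#'   (default) neutral loci start monomorphic.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(model = 1, N = 1000, generations = 10000,
                       iterations = 50, s = 0.5, a = 0.5, m = 0.01,
                       competition_radius = 0.1,
                       competition_strength = 0.02,
                       mate_search_radius = 1.5, dispersal_sd = 0.05,
                       chromosome_length = 1e5,
                       inversion_interval = c(25000, 75000),
                       n_neutral_loci = 40, mutation_rate = 1e-3,
                       recombination_rate = 1e-6,
                       init_B_frequency = 0.5,
                       init_neutral_from_inversion = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  cfg$loci_positions <- if (n_neutral_loci > 0)
    seq(0.5, n_neutral_loci - 0.5) / n_neutral_loci * chromosome_length
    else numeric(0)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$model %in% c(1, 2), cfg$N >= 2, cfg$generations >= 0,
            cfg$iterations >= 1, cfg$s >= 0,
            cfg$a >= 0, cfg$a < 1, cfg$m >= 0, cfg$m <= 0.5,
            cfg$mutation_rate >= 0, cfg$recombination_rate >= 0,
            cfg$init_B_frequency >= 0, cfg$init_B_frequency <= 1,
            cfg$inversion_interval[1] >= 0,
            cfg$inversion_interval[2] > cfg$inversion_interval[1],
            cfg$inversion_interval[2] <= cfg$chromosome_length)
  invisible(cfg)
}

#' Initialise a simulation state
#'
#' Individuals are placed uniformly in the unit square (model 2: half
#' in each population's square). In model 1 each haplotype carries the
#' B arrangement with probability `init_B_frequency`. In model 2 the
#' two populations correspond to the two homozygote ecotypes:
#' population 0 starts fixed for A and population 1 fixed for B (the
#' metapopulation B frequency starts at 0.5). Neutral loci start
#' monomorphic (allele 0).
#'
#' @param config A [sim_config()].
#' @return A `sim_state` list: `x`, `y`, `pop` (0/1), `inv1`, `inv2`
#'   (0 = A, 1 = B), `neut1`, `neut2` (N x loci matrices).
#' @export
init_population <- function(config) {
  N <- config$N
  L <- config$n_neutral_loci
  if (config$model == 2) {
    pop <- rep(0:1, c(N %/% 2, N - N %/% 2))
    inv1 <- pop
    inv2 <- pop
  } else {
    pop <- integer(N)
    inv1 <- as.integer(stats::runif(N) < config$init_B_frequency)
    inv2 <- as.integer(stats::runif(N) < config$init_B_frequency)
  }
  if (isTRUE(config$init_neutral_from_inversion)) {
    neut1 <- matrix(inv1, N, L)
    neut2 <- matrix(inv2, N, L)
  } else {
    neut1 <- matrix(0L, N, L)
    neut2 <- matrix(0L, N, L)
  }
  state <- list(x = stats::runif(N), y = stats::runif(N), pop = pop,
                inv1 = inv1, inv2 = inv2,
                neut1 = neut1, neut2 = neut2)
  class(state) <- "sim_state"
  state
}

#' Inversion-genotype dosage of a state
#' @param state A `sim_state`.
#' @return Integer vector of B-dosages (0/1/2).
#' @export
state_dosage <- function(state) state$inv1 + state$inv2

#' Fitness of every individual in a state
#'
#' `max(0, 1 - s * |gradient position - g/2|)`, divided in model 1 by
#' `1 + competition_strength * n_neighbours` (neighbours within
#' `competition_radius`).
#'
#' @param state A `sim_state`.
#' @param config A [sim_config()].
#' @return Numeric fitness vector (>= 0).
#' @export
sim_fitness <- function(state, config) {
  nb <- if (config$model == 1 && config$competition_strength > 0)
    cpp_count_neighbors(state$x, state$y, state$pop,
                        config$competition_radius)
    else integer(length(state$x))
  cpp_fitness(state$y, state$pop, state_dosage(state), nb, config$s,
              config$competition_strength, config$model)
}

#' Draw a mate for a focal individual
#'
#' Mate sampled among candidates with weight
#' `fitness * (1 - a)^|g_focal - g_candidate|`; `a = 0` reduces to
#' fitness-weighted random mating, `a -> 1` forbids cross-genotype
#' pairing in the limit.
#'
#' @param candidate_g Candidate dosages.
#' @param candidate_w Candidate fitness values.
#' @param g_focal Focal dosage.
#' @param a Assortative-mating strength.
#' @return 1-based index of the chosen candidate (0 if none viable).
#' @export
choose_mate <- function(candidate_g, candidate_w, g_focal, a) {
  stopifnot(length(candidate_g) == length(candidate_w))
  if (length(candidate_g) == 0) return(0L)
  cpp_choose_mate(as.integer(candidate_g), as.numeric(candidate_w),
                  as.integer(g_focal), a)
}

#' Produce one gamete from a parent
#'
#' Crossover count is Poisson(`recombination_rate` x
#' `chromosome_length`) with uniform positions; crossovers falling
#' inside the inversion are discarded when the parent is inversion
#' heterozygous, so neutral alleles inside the inversion stay linked
#' to their inversion allele. Neutral alleles then mutate at
#' `mutation_rate` per locus.
#'
#' @param inv Length-2 vector of the parent's inversion alleles.
#' @param neut 2 x L matrix of the parent's neutral haplotypes.
#' @param config A [sim_config()].
#' @return List with `inv` (gamete inversion allele) and `neutral`
#'   (length-L allele vector).
#' @export
recombine <- function(inv, neut, config) {
  stopifnot(length(inv) == 2)
  neut <- matrix(as.integer(neut), nrow = 2)
  cpp_recombine(as.integer(inv), neut, config$loci_positions,
                config$inversion_interval[1], config$inversion_interval[2],
                config$chromosome_length, config$recombination_rate,
                config$mutation_rate)
}

#' Advance a state by one non-overlapping generation
#'
#' @param state A `sim_state`.
#' @param config A [sim_config()].
#' @return The next `sim_state` (same N). If no reproducing pair can
#'   be formed the returned object has attribute `"extinct" = TRUE`
#'   and the iteration should stop.
#' @export
step_generation <- function(state, config) {
  res <- cpp_step_generation(unclass(state), unclass(config))
  if (isTRUE(res$extinct)) {
    attr(state, "extinct") <- TRUE
    return(state)
  }
  res$extinct <- NULL
  class(res) <- "sim_state"
  res
}

#' Run a spatial supergene-maintenance simulation
#'
#' Runs `config$iterations` independent iterations of
#' `config$generations` generations each. An iteration is "stable"
#' when both inversion haplotypes are still segregating at the final
#' generation. Once one haplotype fixes it can never return (there is
#' no inversion mutation), so iterations stop early on fixation and
#' the B-frequency trajectory is padded with the fixed value.
#'
#' @param config A [sim_config()].
#' @return A `sim_result` list: `summary` (data frame per iteration:
#'   stable, extinct, n_AA, n_AB, n_BB, final B frequency),
#'   `trajectories` (list of per-generation B-frequency vectors),
#'   `final_states` (list of `sim_state`s), and `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  iters <- vector("list", config$iterations)
  for (it in seq_len(config$iterations)) {
    state <- init_population(config)
    traj <- numeric(config$generations + 1)
    traj[1] <- mean(c(state$inv1, state$inv2))
    extinct <- FALSE
    gen_done <- config$generations
    for (gen in seq_len(config$generations)) {
      state <- step_generation(state, config)
      if (isTRUE(attr(state, "extinct"))) {
        extinct <- TRUE
        gen_done <- gen - 1
        traj[(gen + 1):(config$generations + 1)] <- NA_real_
        break
      }
      f <- mean(c(state$inv1, state$inv2))
      traj[gen + 1] <- f
      if (f == 0 || f == 1) {          # fixation is absorbing
        if (gen < config$generations)
          traj[(gen + 2):(config$generations + 1)] <- f
        gen_done <- gen
        break
      }
    }
    g <- state_dosage(state)
    f_final <- mean(c(state$inv1, state$inv2))
    iters[[it]] <- list(
      stable = !extinct && f_final > 0 && f_final < 1,
      extinct = extinct, generations_run = gen_done,
      counts = c(n_AA = sum(g == 0), n_AB = sum(g == 1),
                 n_BB = sum(g == 2)),
      b_frequency = f_final, trajectory = traj, state = state)
  }
  summary <- data.frame(
    iteration = seq_along(iters),
    stable = vapply(iters, `[[`, logical(1), "stable"),
    extinct = vapply(iters, `[[`, logical(1), "extinct"),
    n_AA = vapply(iters, function(z) z$counts[["n_AA"]], numeric(1)),
    n_AB = vapply(iters, function(z) z$counts[["n_AB"]], numeric(1)),
    n_BB = vapply(iters, function(z) z$counts[["n_BB"]], numeric(1)),
    b_frequency = vapply(iters, `[[`, numeric(1), "b_frequency"))
  structure(list(summary = summary,
                 trajectories = lapply(iters, `[[`, "trajectory"),
                 final_states = lapply(iters, `[[`, "state"),
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: model %d, N = %d, %d generations, %d iterations\n",
              x$config$model, x$config$N, x$config$generations,
              nrow(x$summary)))
  cat(sprintf("stable polymorphism in %d/%d iterations\n",
              sum(x$summary$stable), nrow(x$summary)))
  invisible(x)
}

#' Parameter sweep over selection and mating/migration strength
#'
#' Runs [run_simulation()] for every grid cell of `s_values` by
#' `axis_values` (assortment `a` for model 1, migration `m` for model
#' 2), recording the stable fraction, mean genotype counts over stable
#' iterations, and the signed heterozygote-ratio difference from the
#' empirical genotype counts. Cells with zero stable iterations are
#' the "unstable" (white) cells of the sweep heat map.
#'
#' @param config Base [sim_config()]; each cell reuses it with the
#'   axis parameters replaced and a distinct seed derived from
#'   `config$seed`.
#' @param s_values Selection strengths.
#' @param axis_values Values of `a` (model 1) or `m` (model 2).
#' @param empirical_counts Genotype counts for the ratio comparison
#'   (default `c(37, 7, 28)`, the observed AA/AB/BB sample counts).
#' @return A `sweep_grid` data frame: `s`, `a`/`m`, `stable_fraction`,
#'   `mean_n_AA`, `mean_n_AB`, `mean_n_BB`, `het_fraction`,
#'   `ratio_difference`, `stratified_fraction` (fraction of stable
#'   iterations with AA < AB < BB mean gradient position).
#' @export
sweep_simulations <- function(config, s_values, axis_values,
                              empirical_counts = c(37, 7, 28)) {
  stopifnot(length(s_values) >= 1, length(axis_values) >= 1)
  axis_name <- if (config$model == 1) "a" else "m"
  cells <- expand.grid(s = s_values, axis = axis_values)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- config
    cfg$s <- cells$s[i]
    cfg[[axis_name]] <- cells$axis[i]
    cfg$seed <- config$seed + i
    res <- run_simulation(cfg)
    sm <- res$summary
    st <- sm$stable
    ss <- lapply(which(st), function(it) {
      fs <- res$final_states[[it]]
      spatial_stratification(gradient_position(fs, cfg),
                             state_dosage(fs), n_boot = 0,
                             min_class_n = 5)
    })
    strat <- vapply(ss, function(z) isTRUE(z$stratified), logical(1))
    my <- if (length(ss))
      colMeans(do.call(rbind, lapply(ss, `[[`, "mean_y")), na.rm = TRUE)
      else c(AA = NA_real_, AB = NA_real_, BB = NA_real_)
    data.frame(
      s = cells$s[i], axis = cells$axis[i],
      stable_fraction = mean(st),
      mean_n_AA = if (any(st)) mean(sm$n_AA[st]) else NA_real_,
      mean_n_AB = if (any(st)) mean(sm$n_AB[st]) else NA_real_,
      mean_n_BB = if (any(st)) mean(sm$n_BB[st]) else NA_real_,
      het_fraction = if (any(st)) mean(sm$n_AB[st] / config$N)
                     else NA_real_,
      ratio_difference = if (any(st))
        ratio_difference(c(mean(sm$n_AA[st]), mean(sm$n_AB[st]),
                           mean(sm$n_BB[st])), empirical_counts)
        else NA_real_,
      stratified_fraction = if (any(st)) mean(strat) else NA_real_,
      mean_y_AA = my[["AA"]], mean_y_AB = my[["AB"]],
      mean_y_BB = my[["BB"]])
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "axis"] <- axis_name
  class(out) <- c("sweep_grid", class(out))
  out
}

#' Position of each individual along the selection gradient
#'
#' The y coordinate: both models (and, in model 2, both habitat
#' squares) share one selection gradient along the y-axis.
#'
#' @param state A `sim_state`.
#' @param config A [sim_config()] (kept for interface stability).
#' @return Numeric vector in `[0, 1]`.
#' @export
gradient_position <- function(state, config) state$y

#' Signed heterozygote-ratio difference from empirical counts
#'
#' `(simulated AB proportion) - (empirical AB proportion)`: positive
#' values mean the simulation produced more heterozygotes than
#' observed, negative fewer.
#'
#' @param sim_counts Numeric AA/AB/BB counts from a simulation.
#' @param empirical_counts Observed AA/AB/BB counts (default
#'   `c(37, 7, 28)`).
#' @return Signed numeric score.
#' @export
ratio_difference <- function(sim_counts, empirical_counts = c(37, 7, 28)) {
  stopifnot(length(sim_counts) == 3, length(empirical_counts) == 3,
            all(sim_counts >= 0), all(empirical_counts >= 0))
  if (sum(sim_counts) == 0 || sum(empirical_counts) == 0)
    stop("count totals must be nonzero")
  sim_counts[2] / sum(sim_counts) -
    empirical_counts[2] / sum(empirical_counts)
}

#' Spatial stratification of genotypes along the gradient
#'
#' Mean gradient position per genotype with bootstrap CIs, and a flag
#' that is `TRUE` when the present genotype classes are ordered
#' AA < AB < BB in mean position (any present subset must be ordered).
#'
#' @param positions Gradient positions (e.g. [gradient_position()]).
#' @param genotypes Dosage vector (0/1/2) or AA/AB/BB labels.
#' @param n_boot Bootstrap replicates (default 200).
#' @param min_class_n Classes with fewer members than this are treated
#'   as absent for the ordering flag (default 1: every present class
#'   counts; sweeps use a higher value since the mean position of a
#'   near-empty class is noise).
#' @return List with `mean_y` (named AA/AB/BB, `NA` if absent), `ci`,
#'   and `stratified` (`NA` when fewer than 2 classes present).
#' @export
spatial_stratification <- function(positions, genotypes, n_boot = 200,
                                   min_class_n = 1) {
  if (is.numeric(genotypes))
    genotypes <- c("AA", "AB", "BB")[genotypes + 1]
  lv <- c("AA", "AB", "BB")
  mean_y <- vapply(lv, function(g) {
    v <- positions[genotypes == g]
    if (length(v) >= min_class_n) mean(v) else NA_real_
  }, numeric(1))
  ci <- vapply(lv, function(g) {
    v <- positions[genotypes == g]
    if (length(v) < 2 || n_boot < 1) return(c(NA_real_, NA_real_))
    bs <- replicate(n_boot, mean(sample(v, replace = TRUE)))
    stats::quantile(bs, c(0.025, 0.975), names = FALSE)
  }, numeric(2))
  present <- mean_y[!is.na(mean_y)]
  stratified <- if (length(present) < 2) NA else
    all(diff(present[order(match(names(present), lv))]) > 0)
  list(mean_y = mean_y, ci = ci, stratified = stratified)
}

#' Export end-of-run neutral genotypes as a genotype matrix
#'
#' Turns the neutral loci of a final simulation state into a
#' [genotype_matrix()] so the scan and LD modules can be applied to
#' simulated chromosomes (e.g. to confirm reduced homozygote diversity
#' and elevated LD inside the inversion on stable runs).
#'
#' @param state A `sim_state`.
#' @param config The [sim_config()] that produced it.
#' @param chrom Chromosome name for the export (default "sim1").
#' @return A `genotype_matrix` with one column per polymorphic neutral
#'   locus.
#' @export
state_to_genotypes <- function(state, config, chrom = "sim1") {
  dos <- state$neut1 + state$neut2
  poly <- apply(dos, 2, function(v) length(unique(v)) > 1)
  if (!any(poly)) stop("no polymorphic neutral locus in state")
  variants <- data.frame(chrom = chrom,
                         pos = as.integer(round(
                           config$loci_positions[poly])),
                         ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  genotype_matrix(dos[, poly, drop = FALSE], variants,
                  sprintf("ind%04d", seq_along(state$x)))
}

#' Read/write a flat key = value simulation config file
#'
#' @param path File path.
#' @return For `read_sim_config`, a [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(p) {
    v <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) v else num
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  flat <- config[setdiff(names(config), "loci_positions")]
  writeLines(vapply(names(flat), function(k)
    paste0(k, " = ", paste(flat[[k]], collapse = ",")), character(1)),
    path)
  invisible(path)
}
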