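# The DE-hybridised bees search: initialisation, selection, neighbourhood
# search, full loop. Stochastic checks run under fixed seeds.

sphere_space <- function() {
  # inverted 2-D sphere centred at (0.3, 0.7) in trait units
  structure(list(
    name = "sphere", dimension = 2L, lower = c(0, 0), upper = c(1, 1),
    evaluate = function(x) -sum((x - c(0.3, 0.7))^2),
    known_optimum = 0), class = "benchmark_function")
}

test_that("initialisation respects the knockout probability and cap", {
  m <- branched_toy(4)
  space <- knockout_space(m)
  # zero probability: every bee is the wild type
  cfg0 <- optimizer_config(n_scouts = 10, ko_init_prob = 0, seed = 1)
  set.seed(1)
  pop <- initialize_population(cfg0, space)
  expect_true(all(pop >= 0.5))
  # the cap re-flips excess knockouts
  cfg1 <- optimizer_config(n_scouts = 50, ko_init_prob = 0.9,
                           max_knockouts = 2, seed = 1)
  set.seed(1)
  pop <- initialize_population(cfg1, space)
  expect_true(all(rowSums(pop < 0.5) <= 2))
})

test_that("initial knockout counts follow the binomial expectation", {
  # d = 667, p = 0.004: mean knockouts per bee ~ Binomial(667, 0.004)
  d <- 667
  space <- structure(list(type = "binary", d = d, ids = paste0("r", 1:d),
                          decode = function(tr) as.integer(tr >= 0.5),
                          fitness = function(ph) 0),
                     class = "search_space")
  cfg <- optimizer_config(n_scouts = 2000, ko_init_prob = 0.004,
                          max_knockouts = Inf, seed = 99)
  set.seed(99)
  pop <- initialize_population(cfg, space)
  mean_ko <- mean(rowSums(pop < 0.5))
  expected <- d * 0.004
  band <- 3 * sqrt(d * 0.004 * 0.996 / 2000)
  expect_lt(abs(mean_ko - expected), band)
})

test_that("site selection honours the quarter-population cap", {
  m <- branched_toy(4)
  space <- knockout_space(m)
  mk_pop <- function(n) {
    set.seed(5)
    traits <- initialize_population(optimizer_config(n_scouts = n), space)
    fitness <- seq_len(n)  # distinct, increasing
    list(traits = traits, fitness = fitness)
  }
  p40 <- mk_pop(40)
  sel <- select_sites(p40$traits, p40$fitness,
                      optimizer_config(n_scouts = 40, m_sites = 15), space)
  expect_length(sel, 10)                      # ceil(40/4) < 15
  p100 <- mk_pop(100)
  sel <- select_sites(p100$traits, p100$fitness,
                      optimizer_config(n_scouts = 100, m_sites = 15), space)
  expect_length(sel, 15)                      # m wins below the cap
  expect_equal(sel[1], 100L)                  # best fitness first
})

test_that("equal-fitness ties break by fewer knockouts, deterministically", {
  m <- branched_toy(4)
  space <- knockout_space(m)
  d <- space$d
  traits <- rbind(rep(0.9, d),                     # wild type
                  c(0.1, rep(0.9, d - 1)),         # one knockout
                  c(0.1, 0.1, rep(0.9, d - 2)))    # two knockouts
  fitness <- c(1, 1, 1)
  # population 8 -> quarter cap 2, so m_sites = 2 is effective
  cfg <- optimizer_config(n_scouts = 8, m_sites = 2)
  sel1 <- select_sites(traits, fitness, cfg, space)
  sel2 <- select_sites(traits, fitness, cfg, space)
  expect_identical(sel1, sel2)
  expect_equal(sel1, c(1L, 2L))  # fewer knockouts preferred
})

test_that("phenotype binarisation flips exactly at the 0.5 threshold", {
  m <- branched_toy(4)
  space <- knockout_space(m)
  tr <- rep(0.9, space$d)
  expect_equal(space$decode(tr), rep(1L, space$d))
  tr[3] <- 0.4999
  ph <- space$decode(tr)
  expect_equal(ph[3], 0L)
  expect_equal(sum(ph == 0), 1)
  tr[3] <- 0.5
  expect_equal(space$decode(tr)[3], 1L)
})

test_that("degenerate DE operators behave as identities", {
  # F = 0, CR = 1: the trial equals a pool member; greedy acceptance can
  # therefore never lower any site's fitness
  space <- continuous_space(sphere_space())
  set.seed(7)
  traits <- matrix(runif(10), 5, 2)
  fitness <- apply(traits, 1, function(tr) dbfba:::eval_traits(space, tr))
  cfg <- optimizer_config(n_scouts = 5, F = 0, CR = 1,
                          de_generations = 3)
  out <- de_neighborhood_search(traits, fitness, cfg, space)
  expect_true(all(out$fitness >= fitness - 1e-12))
})

test_that("DE neighbourhood search converges on an inverted sphere", {
  space <- continuous_space(sphere_space())
  set.seed(3)
  traits <- matrix(runif(20), 10, 2)  # a standard small DE pool
  fitness <- apply(traits, 1, function(tr) dbfba:::eval_traits(space, tr))
  cfg <- optimizer_config(n_scouts = 10, F = 1, CR = 0.5,
                          de_generations = 50)
  out <- de_neighborhood_search(traits, fitness, cfg, space)
  expect_gt(max(out$fitness), -1e-3)
  expect_true(all(out$traits >= 0 & out$traits <= 1))
})

test_that("the full loop is elitist, deterministic and bounded", {
  m <- branched_toy(4)
  cfg <- optimizer_config(n_scouts = 20, max_iterations = 15, seed = 42)
  r1 <- run_dbfba(m, cfg)
  r2 <- run_dbfba(m, cfg)
  expect_identical(r1$best_fitness, r2$best_fitness)
  expect_identical(r1$knockout_ids, r2$knockout_ids)
  expect_identical(r1$fitness_history, r2$fitness_history)
  # elitism: the best-so-far trace never decreases
  expect_true(all(diff(r1$fitness_history) >= 0))
  # knockout ids are exactly the phenotype zeros
  ph <- r1$best_genotype$phenotype
  space_ids <- deletable_reactions(m)
  expect_identical(r1$knockout_ids, space_ids[ph == 0L])
})

test_that("zero iterations returns the best of the initial population", {
  m <- branched_toy(4)
  cfg <- optimizer_config(n_scouts = 15, max_iterations = 0, seed = 8)
  r <- run_dbfba(m, cfg)
  expect_length(r$fitness_history, 1)
  expect_equal(r$iterations, 0)
  # reproduce the initial population by hand and compare
  set.seed(8)
  space <- knockout_space(m)
  pop <- initialize_population(cfg, space)
  best <- max(apply(pop, 1, function(tr) dbfba:::eval_traits(space, tr)))
  expect_equal(r$best_fitness, best)
})

test_that("elitism holds across seeds (property sweep)", {
  m <- branched_toy(3)
  for (s in 1:6) {
    cfg <- optimizer_config(n_scouts = 12, max_iterations = 8, seed = s)
    r <- run_dbfba(m, cfg)
    expect_true(all(diff(r$fitness_history) >= 0))
  }
})
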