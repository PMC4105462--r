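# FBA and the BPCY fitness pipeline. Expected values are hand LP solutions
# on the chain / branched toys (see helper-models.R).

test_that("FBA reproduces hand LP solutions on the chain toy", {
  m <- chain_toy()
  r <- solve_fba(m, objective_id = "BIOMASS")
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 10)
  # no input, no flux
  closed <- m
  closed$reactions$EX_glc$upper_bound <- 0
  expect_equal(solve_fba(closed, "BIOMASS")$objective_value, 0)
  # min <= max for the same objective
  mx <- solve_fba(m, "GTOP", direction = "max")$objective_value
  mn <- solve_fba(m, "GTOP", direction = "min")$objective_value
  expect_lte(mn, mx)
})

test_that("optimal FBA solutions satisfy mass balance and bounds", {
  for (m in list(chain_toy(), branched_toy(3), branched_toy(4))) {
    r <- solve_fba(m, objective_id = m$biomass_id)
    expect_equal(r$status, "optimal")
    S <- as.matrix(stoichiometric_matrix(m))
    expect_lt(max(abs(S %*% r$fluxes)), 1e-6)
    b <- dbfba:::bounds_matrix(m)
    expect_true(all(r$fluxes >= b[, "lb"] - 1e-9))
    expect_true(all(r$fluxes <= b[, "ub"] + 1e-9))
  }
})

test_that("yield and BPCY formulas and their guards", {
  expect_equal(production_yield(4, 10), 0.4)
  expect_equal(production_yield(0, 10), 0)
  expect_error(production_yield(4, 0), "degenerate yield")
  expect_equal(bpcy(0.5, 4, 10), 0.2)
  expect_equal(bpcy(0, 4, 10), 0)             # no growth, no coupled yield
  expect_equal(bpcy(0.5, 8, 10), 2 * bpcy(0.5, 4, 10))  # linear in product
  expect_error(bpcy(0.5, 4, 0), "degenerate yield")
})

test_that("two-stage fitness matches the hand solution on the chain toy", {
  f <- evaluate_knockout_fitness(chain_toy())
  expect_true(f$feasible)
  expect_equal(f$mu_max, 10)
  expect_equal(f$growth, 9)         # fixed at 90% of the optimum
  expect_equal(f$product_flux, 1, tolerance = 1e-6)
  expect_equal(f$yield, 0.1, tolerance = 1e-6)
  expect_equal(f$bpcy, 0.9, tolerance = 1e-6)
})

test_that("mutants at or below the viability gate score zero", {
  m <- trickle_toy()
  f <- evaluate_knockout_fitness(m, "MAIN")   # growth capped at 0.05
  expect_false(f$feasible)
  expect_equal(f$bpcy, 0)
  expect_equal(f$mu_max, 0.05, tolerance = 1e-9)
  # the gate is strict: growth exactly at the threshold fails too
  m2 <- trickle_toy()
  m2$reactions$TRICKLE$upper_bound <- 0.1
  f2 <- evaluate_knockout_fitness(m2, "MAIN")
  expect_false(f2$feasible)
})

test_that("product is zero when growth is held at its maximum", {
  f <- evaluate_knockout_fitness(branched_toy(), growth_fraction = 1.0)
  expect_equal(f$product_flux, 0, tolerance = 1e-6)
  expect_equal(f$bpcy, 0, tolerance = 1e-6)
})

test_that("fitness shrinks to zero with the growth fraction", {
  m <- branched_toy()
  f_small <- evaluate_knockout_fitness(m, growth_fraction = 1e-4)
  f_ref <- evaluate_knockout_fitness(m, growth_fraction = 0.9)
  expect_lt(f_small$bpcy, f_ref$bpcy)
  expect_lt(f_small$bpcy, 1e-3)
})

test_that("maximal growth is monotone non-increasing under knockouts", {
  m <- branched_toy(4)
  del <- deletable_reactions(m)
  mu <- function(ko)
    solve_fba(apply_knockouts(m, ko), objective_id = "BIOMASS")$objective_value
  set.seed(42)
  for (i in 1:12) {
    A <- sample(del, sample(0:2, 1))
    extra <- sample(setdiff(del, A), sample(1:2, 1))
    B <- c(A, extra)  # A is a strict subset of B
    expect_lte(mu(B), mu(A) + 1e-6)
  }
})

test_that("flux distributions export as two-column CSV", {
  r <- solve_fba(chain_toy(), "BIOMASS")
  path <- withr::local_tempfile(fileext = ".csv")
  write_fluxes_csv(r, path)
  tab <- utils::read.csv(path)
  expect_identical(names(tab), c("reaction", "flux"))
  expect_equal(nrow(tab), 5)
})
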