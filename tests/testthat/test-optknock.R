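# Bilevel MILP and the validation threshold.

test_that("with no knockouts allowed the MILP returns the wild-type rate", {
  m <- branched_toy()
  ok <- solve_optknock(m, K = 0, growth_floor = 0.1)
  expect_equal(ok$status, "optimal")
  expect_length(ok$knockout_ids, 0)
  # at maximal wild-type growth all substrate feeds biomass: rate 0
  expect_equal(ok$product_rate, 0, tolerance = 1e-9)
})

test_that("MILP matches the exhaustive bilevel oracle for K = 0..3", {
  for (m in list(branched_toy(3), chain_toy())) {
    prev <- -Inf
    for (K in 0:3) {
      ok <- solve_optknock(m, K = K, growth_floor = 0.1)
      bf <- brute_force_bilevel(m, K, growth_floor = 0.1)
      expect_equal(ok$product_rate, bf$product_rate, tolerance = 1e-6)
      # rate is monotone non-decreasing in the knockout budget
      expect_gte(ok$product_rate, prev - 1e-9)
      prev <- ok$product_rate
    }
  }
})

test_that("the planted single knockout is recovered as the K = 1 optimum", {
  m <- branched_toy()
  ok <- solve_optknock(m, K = 1, growth_floor = 0.1)
  expect_identical(ok$knockout_ids, "BIO")
  expect_equal(ok$product_rate, 5, tolerance = 1e-6)
  expect_equal(ok$growth, 5, tolerance = 1e-6)
})

test_that("the inner LP shows no duality gap at the returned solution", {
  m <- branched_toy(4)
  for (K in 0:2) {
    ok <- solve_optknock(m, K = K, growth_floor = 0.1)
    expect_lte(ok$duality_gap, 1e-6)
  }
})

test_that("an unreachable growth floor reports infeasibility", {
  ok <- solve_optknock(branched_toy(), K = 1, growth_floor = 50)
  expect_equal(ok$status, "infeasible")
  expect_true(is.na(ok$product_rate))
})

test_that("non-deletable candidates are refused", {
  expect_error(solve_optknock(branched_toy(), K = 1,
                              candidate_ids = c("BIO", "BIOMASS")),
               "not deletable")
})

test_that("validation accepts the bilevel-optimal design with ~zero gap", {
  m <- branched_toy()
  fit <- evaluate_knockout_fitness(m, "BIO")
  v <- validate_solution(m, "BIO", fit)
  expect_true(v$valid)
  expect_lt(v$difference, 1e-6)
  expect_identical(v$mode, "product_rate")
})

test_that("the acceptance threshold is strictly below 0.001", {
  m <- branched_toy()
  fit <- evaluate_knockout_fitness(m, "BIO")
  ref <- validate_solution(m, "BIO", fit)
  opt <- ref$optknock_value
  craft <- function(delta) {
    f <- fit
    f$product_flux <- opt - delta
    validate_solution(m, "BIO", f)
  }
  expect_true(craft(0.0005)$valid)    # difference 0.0005 -> valid
  expect_false(craft(0.001)$valid)    # difference exactly 0.001 -> invalid
  expect_false(craft(0.002)$valid)
})

test_that("the literal BPCY comparison mode is available", {
  m <- branched_toy()
  fit <- evaluate_knockout_fitness(m, "BIO")
  v <- validate_solution(m, "BIO", fit, mode = "bpcy")
  expect_identical(v$mode, "bpcy")
  expect_equal(v$dbfba_value, fit$bpcy)
  # BPCY (per-substrate, growth-weighted) and a raw rate differ here
  expect_false(v$valid)
})

test_that("the MILP exports as a readable LP-format file", {
  m <- branched_toy()
  path <- withr::local_tempfile(fileext = ".lp")
  write_optknock_lp(m, K = 1, growth_floor = 0.1, path = path)
  txt <- readLines(path)
  expect_identical(txt[2], "Maximize")
  expect_true(any(txt == "Subject To"))
  expect_true(any(txt == "Binary"))
  expect_true(any(grepl("y_BIO", txt)))
  # one row per assembled constraint
  milp <- dbfba:::optknock_milp(m, deletable_reactions(m), 0.1, 1, NULL)
  expect_equal(sum(grepl("^ c[0-9]+:", txt)), nrow(milp$A))
})

test_that("infeasible fitness results cannot be validated", {
  m <- trickle_toy()
  fit <- evaluate_knockout_fitness(m, "MAIN")
  expect_error(validate_solution(m, "MAIN", fit), "infeasible")
})
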