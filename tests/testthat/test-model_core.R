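# Model container: construction, validation, stoichiometric matrix,
# knockouts.

test_that("reaction and model constructors validate their inputs", {
  expect_error(reaction("", c(A = 1)), "non-empty")
  expect_error(reaction("R1", numeric(0)), "stoichiometry")
  expect_error(reaction("R1", c(A = 1, A = 2)), "duplicated")
  expect_error(reaction("R1", c(A = 1), lower_bound = 2, upper_bound = 1),
               "lower_bound > upper_bound")
  # unresolved metabolite reference
  mets <- data.frame(id = "A", name = "A", compartment = "c")
  expect_error(
    metabolic_model(list(reaction("R1", c(B = 1))), metabolites = mets,
                    biomass_id = "R1", substrate_id = "R1",
                    product_id = "R1"),
    "unknown metabolite")
  # designations must resolve
  expect_error(
    metabolic_model(list(reaction("R1", c(B = 1))),
                    biomass_id = "NOPE", substrate_id = "R1",
                    product_id = "R1"),
    "does not resolve")
})

test_that("exchange reactions are inferred from one-sided stoichiometry", {
  ex <- reaction("EX_a", c(A = -1))
  expect_true(ex$is_exchange)
  internal <- reaction("R1", c(A = -1, B = 1))
  expect_false(internal$is_exchange)
})

test_that("stoichiometric matrix matches the hand-written table", {
  m <- chain_toy()
  S <- as.matrix(stoichiometric_matrix(m))
  expected <- chain_S_expected()
  expect_equal(S[rownames(expected), colnames(expected)], expected)
  # column definitions: A -> B gives (-1, +1); exchange gives (+1, 0)
  expect_equal(unname(S[c("G", "X"), "CONV"]), c(-1, 1))
  expect_equal(unname(S[c("G", "X"), "EX_glc"]), c(1, 0))
})

test_that("matrix nonzeros equal the summed stoichiometry sizes", {
  for (m in list(chain_toy(), branched_toy(3), branched_toy(5))) {
    S <- stoichiometric_matrix(m)
    n_nonzero <- Matrix::nnzero(S)
    expect_identical(
      n_nonzero,
      sum(vapply(m$reactions, function(r) length(r$stoichiometry),
                 integer(1))))
  }
})

test_that("knockouts close both bounds and leave the input unchanged", {
  m <- branched_toy()
  km <- apply_knockouts(m, c("BIO", "GTOP"))
  expect_equal(km$reactions$BIO$lower_bound, 0)
  expect_equal(km$reactions$BIO$upper_bound, 0)
  expect_equal(km$reactions$GTOP$upper_bound, 0)
  # original untouched
  expect_equal(m$reactions$BIO$upper_bound, 1000)
  # empty set is the identity
  expect_identical(apply_knockouts(m, character(0)), m)
})

test_that("protected reactions refuse knockout", {
  m <- branched_toy()
  expect_error(apply_knockouts(m, "BIOMASS"), "not deletable")
  expect_error(apply_knockouts(m, "EX_glc"), "not deletable")
  expect_error(apply_knockouts(m, "NO_SUCH"), "unknown reaction")
})

test_that("knockouts are idempotent and commute over disjoint sets", {
  m <- branched_toy()
  once <- apply_knockouts(m, "BIO")
  twice <- apply_knockouts(once, "BIO")
  expect_identical(once$reactions, twice$reactions)
  ab <- apply_knockouts(apply_knockouts(m, "BIO"), "GTOP")
  ba <- apply_knockouts(apply_knockouts(m, "GTOP"), "BIO")
  expect_identical(ab$reactions, ba$reactions)
})

test_that("knocking out the sole biomass-feeding reaction zeroes growth", {
  m <- chain_toy()
  km <- apply_knockouts(m, "CONV")
  r <- solve_fba(km, objective_id = "BIOMASS")
  expect_equal(r$objective_value, 0)
})
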