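# Model reduction: blocked-reaction detection, essentiality screen,
# protection bookkeeping.

orphan_toy <- function() {
  # ORPH consumes a metabolite nothing produces: blocked by construction
  metabolic_model(list(
    reaction("EX_glc", c(G = 1), 0, 10),
    reaction("CONV", c(G = -1, X = 1), 0, 1000),
    reaction("BIOMASS", c(X = -1), 0, 1000,
             is_exchange = FALSE, deletable = FALSE),
    reaction("GTOP", c(G = -1, P = 1), 0, 1000),
    reaction("EX_P", c(P = -1), 0, 1000),
    reaction("ORPH", c(Q = -1, X = 1), 0, 1000)),
    biomass_id = "BIOMASS", substrate_id = "EX_glc", product_id = "EX_P",
    id = "orphan_toy")
}

test_that("blocked-reaction detection flags orphans and only orphans", {
  expect_identical(find_dead_end_reactions(orphan_toy()), "ORPH")
  # a fully coupled chain has no blocked reactions
  expect_length(find_dead_end_reactions(chain_toy()), 0)
})

test_that("blocked detection agrees with an exhaustive FVA oracle", {
  for (m in list(orphan_toy(), branched_toy(3))) {
    found <- find_dead_end_reactions(m)
    S <- as.matrix(stoichiometric_matrix(m))
    b <- dbfba:::bounds_matrix(m)
    oracle <- character(0)
    for (j in seq_along(m$reactions)) {
      obj <- numeric(length(m$reactions)); obj[j] <- 1
      hi <- dbfba:::lp_solve(obj, S, rep("=", nrow(S)), numeric(nrow(S)),
                             b[, "lb"], b[, "ub"], maximize = TRUE)
      lo <- dbfba:::lp_solve(obj, S, rep("=", nrow(S)), numeric(nrow(S)),
                             b[, "lb"], b[, "ub"], maximize = FALSE)
      if (abs(hi$objective) <= 1e-9 && abs(lo$objective) <= 1e-9)
        oracle <- c(oracle, names(m$reactions)[j])
    }
    expect_identical(sort(found), sort(oracle))
  }
})

test_that("removing blocked reactions leaves maximal growth unchanged", {
  m <- orphan_toy()
  mu_before <- solve_fba(m, "BIOMASS")$objective_value
  red <- reduce_model(m)
  mu_after <- solve_fba(red$model, "BIOMASS")$objective_value
  expect_equal(mu_after, mu_before, tolerance = 1e-9)
  p_before <- solve_fba(m, m$product_id)$objective_value
  p_after <- solve_fba(red$model, red$model$product_id)$objective_value
  expect_equal(p_after, p_before, tolerance = 1e-6)
})

test_that("essentiality scan finds the sole biomass-feeding reaction", {
  lethal <- find_lethal_reactions(chain_toy())
  expect_identical(lethal, "CONV")
  # redundant parallel biomass routes are individually dispensable
  lethal_b <- find_lethal_reactions(branched_toy())
  expect_false("BIO" %in% lethal_b)
  expect_false("BIOALT" %in% lethal_b)
})

test_that("an inviable wild type is rejected by the essentiality scan", {
  m <- chain_toy()
  m$reactions$EX_glc$upper_bound <- 0.05
  expect_error(find_lethal_reactions(m), "viability gate")
})

test_that("reduction counts, protection and idempotence", {
  m <- orphan_toy()
  red <- reduce_model(m, user_protected = "GTOP")
  expect_equal(red$report$n_reactions_before, 6)
  expect_equal(red$report$n_reactions_after, 5)
  expect_identical(red$report$removed, "ORPH")
  expect_true("CONV" %in% red$report$lethal)
  # essential and protected sets never overlap the deletable set
  expect_length(intersect(red$report$lethal,
                          deletable_reactions(red$model)), 0)
  expect_false("GTOP" %in% deletable_reactions(red$model))
  # applying the reduction again changes nothing
  red2 <- reduce_model(red$model, user_protected = "GTOP")
  expect_identical(red2$model$reactions, red$model$reactions)
  expect_length(red2$report$removed, 0)
})
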