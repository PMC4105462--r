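# Shared toy fixtures, built in code. Values asserted against them were
# computed by hand from the network stoichiometry (substrate bound 10,
# 90% growth fixation):
#   chain wild type:      mu = 10, fixed 9, product 1, BPCY 0.9
#   branched (byproduct): wild type BPCY 0.9; knocking the efficient
#     biomass route BIO forces the by-product-coupled route (2 G -> X + W,
#     W -> P): mu = 5, fixed 4.5, product 4.5 + 1 = 5.5, BPCY 2.475

chain_toy <- function() make_chain_model()

branched_toy <- function(n = 3) make_branched_model(n, byproduct = TRUE)

branched_plain_toy <- function() make_branched_model(3, byproduct = FALSE)

# chain with a trickle bypass: knocking the main route leaves growth 0.05,
# below the 0.1 viability gate
trickle_toy <- function() {
  metabolic_model(list(
    reaction("EX_glc", c(G = 1), 0, 10),
    reaction("MAIN", c(G = -1, X = 1), 0, 1000),
    reaction("TRICKLE", c(G = -1, X = 1), 0, 0.05),
    reaction("BIOMASS", c(X = -1), 0, 1000,
             is_exchange = FALSE, deletable = FALSE),
    reaction("GTOP", c(G = -1, P = 1), 0, 1000),
    reaction("EX_P", c(P = -1), 0, 1000)),
    biomass_id = "BIOMASS", substrate_id = "EX_glc", product_id = "EX_P",
    id = "trickle_toy")
}

# hand-written stoichiometric table of the chain toy (rows G, X, P)
chain_S_expected <- function() {
  S <- matrix(0, 3, 5,
              dimnames = list(c("G", "X", "P"),
                              c("EX_glc", "CONV", "BIOMASS", "GTOP",
                                "EX_P")))
  S["G", "EX_glc"] <- 1
  S["G", "CONV"] <- -1; S["X", "CONV"] <- 1
  S["X", "BIOMASS"] <- -1
  S["G", "GTOP"] <- -1; S["P", "GTOP"] <- 1
  S["P", "EX_P"] <- -1
  S
}

expect_model_equal <- function(m1, m2) {
  expect_identical(names(m2$reactions), names(m1$reactions))
  for (rid in names(m1$reactions)) {
    r1 <- m1$reactions[[rid]]; r2 <- m2$reactions[[rid]]
    expect_equal(r2$lower_bound, r1$lower_bound)
    expect_equal(r2$upper_bound, r1$upper_bound)
    expect_setequal(names(r2$stoichiometry), names(r1$stoichiometry))
    expect_equal(r2$stoichiometry[names(r1$stoichiometry)],
                 r1$stoichiometry)
  }
  expect_identical(m2$biomass_id, m1$biomass_id)
  expect_identical(m2$substrate_id, m1$substrate_id)
  expect_identical(m2$product_id, m1$product_id)
}
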