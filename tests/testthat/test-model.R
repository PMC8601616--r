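test_that("chain model counts and structure", {
  m <- make_chain_model(2)
  expect_equal(n_reactions(m), 2L)          # [TRIVIAL: constructed input]
  expect_equal(n_metabolites(m), 1L)
  expect_true(all(m$exchange))              # both touch exactly one metabolite
  expect_output(print(m), "2 reactions, 1 metabolites")
})

test_that("exchange detection counts single-metabolite columns", {
  S <- matrix(c(1, 0,   # r1: one metabolite -> exchange
                -1, 1,  # r2: two -> internal
                0, -1), # r3: one -> exchange
              nrow = 2)
  expect_equal(unname(fluxmodules:::detect_exchange(S)), c(TRUE, FALSE, TRUE))
})

test_that("reaction equations render names, compartments and arrows", {
  m <- metabolic_model(
    "toy",
    metabolites = data.frame(id = c("m1", "m2"), name = c("M1", "M2"),
                             compartment = "c"),
    reactions = data.frame(id = c("r1", "r2"), name = c("r1", "r2"),
                           reversible = c(FALSE, TRUE)),
    S = matrix(c(-1, 1, -2, 1), 2), lb = c(0, -10), ub = c(10, 10))
  expect_equal(m$reactions$equation[1], "M1[c] => M2[c]")
  expect_equal(m$reactions$equation[2], "2 M1[c] <=> M2[c]")
})

test_that("model validation rejects malformed input", {
  md <- make_chain_model(2)
  bad <- md; bad$lb["r1"] <- 5; bad$ub["r1"] <- 1
  expect_error(fluxmodules:::validate_model(bad), "lower bound exceeds")
  dup <- md; dup$reactions$id <- c("r1", "r1")
  expect_error(fluxmodules:::validate_model(dup), "duplicate reaction ids")
})

test_that("release reactions are appended with -1/+1 stoichiometry", {
  m <- metabolic_model(
    "toy",
    metabolites = data.frame(id = c("a_c", "b_c", "a_e"),
                             name = c("A", "B", "A"),
                             compartment = c("c", "c", "e")),
    reactions = data.frame(id = "r1", name = "r1", reversible = FALSE),
    S = matrix(c(-1, 1, 0), 3), lb = 0, ub = 10)
  m2 <- add_release_reactions(m, c("a_c", "b_c"))
  expect_equal(n_reactions(m2), 3L)                 # +2 reactions
  expect_true(all(c("EXC_OUT_a_c", "EXC_OUT_b_c") %in% m2$reactions$id))
  # a_c reuses the existing extracellular species; b_c gets a new one
  expect_equal(n_metabolites(m2), 4L)
  expect_equal(unname(m2$S[c("a_c", "a_e"), "EXC_OUT_a_c"]), c(-1, 1))
  expect_equal(unname(m2$S[c("b_c", "b_c_e"), "EXC_OUT_b_c"]), c(-1, 1))
  expect_equal(unname(m2$lb["EXC_OUT_b_c"]), 0)
  expect_equal(unname(m2$ub["EXC_OUT_b_c"]), 1000)
  expect_false(m2$reactions$reversible[m2$reactions$id == "EXC_OUT_b_c"])
  expect_error(add_release_reactions(m2, "zzz"), "not in model")
  expect_error(add_release_reactions(m2, "a_e"), "not cytosolic")
  expect_error(add_release_reactions(m2, "a_c"), "already present")
})

test_that("default bounds follow reversibility", {
  m <- metabolic_model(
    "toy", metabolites = data.frame(id = "m", name = "m", compartment = "c"),
    reactions = data.frame(id = c("r1", "r2"), name = c("r1", "r2"),
                           reversible = c(TRUE, FALSE)),
    S = matrix(c(1, -1), 1), lb = c(-3, 0), ub = c(3, 3))
  sp <- apply_default_bounds(m)
  expect_equal(unname(sp$model$lb), c(-1000, 0))
  expect_equal(unname(sp$model$ub), c(1000, 1000))
  expect_equal(sp$condition_label, "default")
})

test_that("block_reactions zeroes bounds and records overrides", {
  sp <- apply_default_bounds(make_chain_model(3))
  b <- block_reactions(sp, "r2", condition_label = "no_r2")
  expect_equal(unname(b$model$lb["r2"]), 0)
  expect_equal(unname(b$model$ub["r2"]), 0)
  expect_equal(b$applied_overrides$r2, c(lb = 0, ub = 0))
  expect_equal(b$condition_label, "no_r2")
  expect_error(block_reactions(sp, "nope"), "unknown reaction")
})

test_that("model tables and JSON summary are written", {
  m <- make_triangle_model()
  rp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  rt <- write_model_tables(m, rp, mp)
  back <- read.delim(rp)
  expect_equal(back$id, m$reactions$id)
  expect_equal(back$lb, unname(m$lb))
  js <- jsonlite::fromJSON(model_summary_json(m))
  expect_equal(js$n_reactions, 3L)
  expect_equal(js$n_metabolites, 1L)
})
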