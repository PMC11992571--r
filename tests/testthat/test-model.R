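test_that("validate_model catches structural errors", {
  good <- mini_gpr_model()
  expect_s3_class(good, "metabolic_model")

  dup_met <- function() {
    rx <- list(rxn_row("SRC", c("a[c]" = 1), exchange = TRUE),
               rxn_row("DM", c("a[c]" = -1)))
    assemble_model(c("a[c]", "a[c]"), rx, character(0), "DM", "DM")
  }
  expect_error(dup_met(), "duplicate metabolite")

  expect_error(
    assemble_model("a[x]",
                   list(rxn_row("SRC", c("a[x]" = 1), exchange = TRUE),
                        rxn_row("SRC", c("a[x]" = -1), exchange = TRUE)),
                   character(0), "SRC", "SRC"),
    "duplicate reaction")

  # compartment suffix must match the declared compartment
  bad_comp <- function() {
    mets <- data.frame(id = "a[c]", name = "a", compartment = "x",
                       stringsAsFactors = FALSE)
    rdf <- data.frame(id = "DM", lb = 0, ub = 1, reversible = FALSE,
                      subsystem = "", gpr = "", exchange = FALSE,
                      transport = FALSE, stringsAsFactors = FALSE)
    rdf$stoich <- list(c("a[c]" = -1))
    metabolic_model(mets, rdf, character(0), "DM", "DM")
  }
  expect_error(bad_comp(), "compartment suffix")

  expect_error(
    assemble_model("a[c]",
                   list(rxn_row("R", c("a[c]" = 0))),
                   character(0), "R", "R"),
    "zero coefficient")

  expect_error(
    assemble_model("a[c]",
                   list(rxn_row("R", c("a[c]" = -1, "zz[c]" = 1))),
                   character(0), "R", "R"),
    "undeclared metabolite")

  expect_error(
    assemble_model(c("a[c]", "b[c]"),
                   list(rxn_row("EX", c("a[c]" = -1, "b[c]" = 1),
                                exchange = TRUE)),
                   character(0), "EX", "EX"),
    "exactly one metabolite")

  expect_error(
    assemble_model("a[c]",
                   list(rxn_row("R", c("a[c]" = -1), lb = 2, ub = 1)),
                   character(0), "R", "R"),
    "lower bound exceeds")

  expect_error(
    assemble_model("a[c]",
                   list(rxn_row("R", c("a[c]" = -1), gpr = "GX")),
                   character(0), "R", "R"),
    "undeclared gene")

  expect_error(
    assemble_model("a[c]",
                   list(rxn_row("R", c("a[c]" = -1))),
                   character(0), "NOPE", "R"),
    "objective")
})

test_that("stoich_matrix lays out coefficients correctly", {
  m <- mini_gpr_model()
  S <- stoich_matrix(m)
  expect_s4_class(S, "dgCMatrix")
  expect_equal(dim(S), c(2, 5))
  expect_equal(S["a[c]", "SRC"], 1)
  expect_equal(S["a[c]", "R_or"], -1)
  expect_equal(S["b[c]", "R_or"], 1)
  expect_equal(S["b[c]", "DM_b"], -1)
  expect_equal(S["b[c]", "SRC"], 0)
})

test_that("model JSON round-trips through write_model/load_model", {
  m <- make_toy_network()$model
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lb, m$reactions$lb)
  expect_equal(m2$reactions$ub, m$reactions$ub)
  expect_equal(m2$reactions$gpr, m$reactions$gpr)
  expect_equal(m2$reactions$subsystem, m$reactions$subsystem)
  expect_equal(m2$metabolites$id, m$metabolites$id)
  expect_equal(sort(m2$genes), sort(m$genes))
  expect_equal(m2$objective_id, m$objective_id)
  expect_equal(m2$atp_demand_id, m$atp_demand_id)
  for (k in seq_len(nrow(m$reactions))) {
    expect_equal(m2$reactions$stoich[[k]], m$reactions$stoich[[k]])
  }
  # a second write is byte-identical (canonical key order)
  f2 <- tempfile(fileext = ".json")
  write_model(m2, f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2))
})

test_that("load_model applies bound defaults and validates schema", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "a[c]")),
    reactions = list(
      list(id = "EX_a", stoich = list(`a[c]` = -1), exchange = TRUE,
           reversible = TRUE),
      list(id = "DM_a", stoich = list(`a[c]` = -1))
    ),
    genes = list(),
    objective_id = "DM_a", atp_demand_id = "DM_a"
  ), f, auto_unbox = TRUE)
  m <- load_model(f)
  expect_equal(m$reactions$lb, c(-1000, 0))
  expect_equal(m$reactions$ub, c(1000, 1000))
  expect_equal(m$reactions$reversible, c(TRUE, FALSE))
  unlink(f)

  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(metabolites = list(), reactions = list()), f2,
                       auto_unbox = TRUE)
  expect_error(load_model(f2), "missing key")
  unlink(f2)
  expect_error(load_model(tempfile()), "not found")
})

test_that("split_reversible produces a correct irreversible pair", {
  rx <- list(
    rxn_row("EX_a", c("a[c]" = -1), exchange = TRUE, lb = -5, ub = 3),
    rxn_row("R1", c("a[c]" = -1, "b[c]" = 1), lb = -4, ub = 7),
    rxn_row("DM_b", c("b[c]" = -1))
  )
  m <- assemble_model(c("a[c]", "b[c]"), rx, character(0), "DM_b", "DM_b")
  s <- split_reversible(m)
  expect_true(all(s$reactions$lb >= 0))
  expect_setequal(s$reactions$id,
                  c("EX_a_f", "EX_a_b", "R1_f", "R1_b", "DM_b"))
  r1f <- s$reactions[s$reactions$id == "R1_f", ]
  r1b <- s$reactions[s$reactions$id == "R1_b", ]
  expect_equal(c(r1f$lb, r1f$ub), c(0, 7))
  expect_equal(c(r1b$lb, r1b$ub), c(0, 4))
  expect_equal(r1b$stoich[[1]], c("a[c]" = 1, "b[c]" = -1))
  # optimum preserved
  expect_equal(fba(s)$objective, fba(m)$objective)
})

test_that("split_reversible renames the objective when it splits", {
  rx <- list(
    rxn_row("EX_a", c("a[c]" = -1), exchange = TRUE, lb = -5, ub = 3),
    rxn_row("DM_a", c("a[c]" = -1))
  )
  m <- assemble_model("a[c]", rx, character(0), "EX_a", "DM_a")
  s <- split_reversible(m)
  expect_equal(s$objective_id, "EX_a_f")
  expect_equal(s$atp_demand_id, "DM_a")
})

test_that("dead_end_metabolites flags unbalanced metabolites", {
  rx <- list(
    rxn_row("SRC", c("a[c]" = 1), exchange = TRUE, ub = 5),
    rxn_row("R1", c("a[c]" = -1, "b[c]" = 1)),
    rxn_row("DM_a", c("a[c]" = -1))
  )
  m <- assemble_model(c("a[c]", "b[c]"), rx, character(0), "DM_a", "DM_a")
  de <- dead_end_metabolites(m)
  expect_false(de[["a[c]"]])
  expect_true(de[["b[c]"]])   # produced but never consumed
})
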