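write_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("read_kinetics parses and validates", {
  f <- write_tsv(data.frame(reaction_id = c("R1", "R2"), kcat = c(2, 0.5)))
  k <- read_kinetics(f)
  expect_equal(k, c(R1 = 2, R2 = 0.5))
  unlink(f)
  f2 <- write_tsv(data.frame(reaction_id = "R1", kcat = -1))
  expect_error(read_kinetics(f2), "positive")
  unlink(f2)
  f3 <- write_tsv(data.frame(id = "R1", value = 1))
  expect_error(read_kinetics(f3), "columns")
  unlink(f3)
  expect_error(read_kinetics(tempfile()), "not found")
})

test_that("read_medium parses and validates", {
  f <- write_tsv(data.frame(exchange_id = "EX_glc", max_uptake = 10))
  expect_equal(read_medium(f), c(EX_glc = 10))
  unlink(f)
  f2 <- write_tsv(data.frame(exchange_id = "EX_glc", max_uptake = -1))
  expect_error(read_medium(f2), "nonnegative")
  unlink(f2)
})

test_that("read_expression wires matrix and metadata together", {
  fe <- write_tsv(data.frame(gene = c("G1", "G2"), s1 = c(1, 2), s2 = c(3, 4)))
  fm <- write_tsv(data.frame(sample_id = c("s2", "s1"), study_id = "st1",
                             group = c("senescent", "proliferative")))
  es <- read_expression(fe, fm)
  expect_s3_class(es, "expression_set")
  # columns follow metadata order
  expect_equal(colnames(es$values), c("s2", "s1"))
  expect_equal(es$values["G2", "s2"], 4)
  expect_true("passage" %in% names(es$samples))
  unlink(c(fe, fm))
})

test_that("expression_set validates inputs", {
  m <- matrix(1:4, 2, dimnames = list(c("G1", "G2"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s3"), study_id = "st")
  expect_error(expression_set(m, meta), "missing from expression")
  expect_error(expression_set(-m, data.frame(sample_id = "s1", study_id = "st")),
               "nonnegative")
})

test_that("enzyme_abundance evaluates rules with the NA sentinel", {
  m <- mini_gpr_model()
  ab <- enzyme_abundance(m, c(G1 = 1, G2 = 2, G3 = 3, G4 = 0.5))
  expect_true(is.na(ab[["SRC"]]))
  expect_equal(ab[["R_or"]], 3)
  expect_equal(ab[["R_and"]], 0.5)
  expect_warning(enzyme_abundance(m, c(G1 = 1)), "G2")
})

test_that("vmax_bounds multiplies kcat, abundance, and sigma", {
  ab <- c(R1 = 2, R2 = NA, R3 = 4)
  kin <- c(R1 = 3, R3 = 0.5)
  v <- vmax_bounds(ab, kin, sigma = 2)
  expect_equal(v[["R1"]], 12)
  expect_true(is.na(v[["R2"]]))
  expect_equal(v[["R3"]], 4)
})

test_that("build_sample_model caps bounds and applies the medium", {
  m <- mini_gpr_model()
  kin <- c(R_or = 1, R_and = 1)
  expr <- c(G1 = 2, G2 = 1, G3 = 5, G4 = 4)
  med <- c(SRC = 7)   # SRC is the only exchange
  # make SRC a conventional uptake exchange (stoich -1, uptake negative)
  m$reactions$stoich[[1]] <- c("a[c]" = -1)
  b <- build_sample_model(m, expr, kin, med)
  expect_equal(b$reactions$ub[b$reactions$id == "R_or"], 3)   # 2+1
  expect_equal(b$reactions$ub[b$reactions$id == "R_and"], 4)  # min(5,4)
  expect_equal(b$reactions$lb[b$reactions$id == "SRC"], -7)
  # input untouched (pure function)
  expect_equal(m$reactions$ub[m$reactions$id == "R_or"], 1000)
  # abundance attribute carried for knockouts
  expect_equal(attr(b, "abundance"), expr)
})

test_that("non-medium exchanges lose uptake but keep secretion", {
  m <- make_toy_network()$model
  b <- build_sample_model(m, stats::setNames(rep(64, length(m$genes)), m$genes),
                          default_kinetics(m), c(EX_glc = 10))
  ex <- b$reactions[b$reactions$exchange, ]
  expect_equal(ex$lb[ex$id == "EX_glc"], -10)
  expect_true(all(ex$lb[ex$id != "EX_glc"] >= 0))
  expect_true(all(ex$ub > 0))
})

test_that("build_sample_model rejects medium entries that are not exchanges", {
  m <- mini_gpr_model()
  expect_error(
    build_sample_model(m, c(G1 = 1, G2 = 1, G3 = 1, G4 = 1),
                       c(R_or = 1), c(R_or = 5)),
    "non-exchange")
})
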