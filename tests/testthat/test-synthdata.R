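test_that("synth_spec validates its knobs", {
  expect_s3_class(synth_spec(), "synth_spec")
  expect_error(synth_spec(n_studies = 1), "n_studies")
  expect_error(synth_spec(samples_per_group = 1), "samples_per_group")
  expect_error(synth_spec(passages = c(1, 1, 1)), "distinct")
  expect_error(synth_spec(noise_sd = 0), "noise_sd")
})

test_that("the toy network is a valid, growing model", {
  net <- make_toy_network()
  m <- net$model
  expect_s3_class(m, "metabolic_model")
  expect_true(all(net$truth$planted_down_genes %in% m$genes))
  expect_true(all(net$truth$planted_agonist_metabolites %in% m$metabolites$id))
  expect_true(all(net$truth$planted_down_subsystems %in% m$reactions$subsystem))

  # with uniform expression the model grows and meets maintenance
  expr <- stats::setNames(rep(64, length(m$genes)), m$genes)
  km <- prepare_sample_model(m, expr, default_kinetics(m), default_medium())
  expect_length(attr(km, "maintenance_flags"), 0)
  r <- fba(km)
  expect_equal(r$status, "optimal")
  expect_gt(r$objective, 1)
})

test_that("single knockouts are lethal exactly along the planted pathway", {
  net <- make_toy_network()
  m <- net$model
  expr <- stats::setNames(rep(64, length(m$genes)), m$genes)
  km <- prepare_sample_model(m, expr, default_kinetics(m), default_medium())
  base <- profile_of_model(km)
  ko <- gene_ko_matrix(km, base)
  lethal <- names(which(ko$infeasible))
  expect_setequal(lethal, net$truth$planted_down_genes)
})

test_that("simulate_expression is deterministic and honors the design", {
  net <- make_toy_network()
  spec <- synth_spec(n_studies = 2, samples_per_group = 3)
  e1 <- simulate_expression(net$model, net$truth, spec)
  e2 <- simulate_expression(net$model, net$truth, spec)
  expect_identical(e1$values, e2$values)
  e3 <- simulate_expression(net$model, net$truth, spec, seed = 99)
  expect_false(identical(e1$values, e3$values))

  expect_equal(dim(e1$values), c(length(net$model$genes), 2 * 2 * 3))
  expect_equal(sort(unique(e1$samples$study_id)), c("study1", "study2"))
  expect_equal(sum(e1$samples$group == "senescent"), 6)

  # planted genes are lower in senescent samples by about effect_lfc
  sen <- e1$samples$group == "senescent"
  pl <- rownames(e1$values) %in% net$truth$planted_down_genes
  lfc <- log2(rowMeans(e1$values[pl, sen]) / rowMeans(e1$values[pl, !sen]))
  expect_true(all(lfc < -0.5))
  # non-planted genes only fluctuate with sampling noise (6 vs 6 samples)
  lfc0 <- log2(rowMeans(e1$values[!pl, sen]) / rowMeans(e1$values[!pl, !sen]))
  expect_true(all(abs(lfc0) < 0.8))
  expect_lt(mean(abs(lfc0)), 0.3)
})

test_that("time-series expression declines linearly for planted genes", {
  net <- make_toy_network()
  spec <- synth_spec(noise_sd = 0.05)
  e <- simulate_expression(net$model, net$truth, spec, mode = "timeseries")
  expect_equal(ncol(e$values),
               length(spec$passages) * spec$replicates_per_passage)
  expect_true(all(!is.na(e$samples$passage)))
  pl <- net$truth$planted_down_genes[1]
  first <- e$samples$passage == min(spec$passages)
  last <- e$samples$passage == max(spec$passages)
  drop <- log2(mean(e$values[pl, last]) / mean(e$values[pl, first]))
  expect_lt(drop, -0.6)   # ~ effect_lfc at the last passage
})

test_that("with_seed restores the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(senflux:::with_seed(5, runif(10)))
  expect_identical(.Random.seed, before)
})

test_that("make_chain_model is the documented analytic fixture", {
  m <- make_chain_model(cap = 4, uptake = 9, demand_cap = 1)
  expect_equal(fba(m)$objective, 4)
  m2 <- make_chain_model(cap = 20, uptake = 9, demand_cap = 0)
  expect_equal(fba(m2)$objective, 9)
})

test_that("write_synthetic_inputs materializes a loadable bundle", {
  dir <- tempfile("synth")
  spec <- synth_spec(n_studies = 2, samples_per_group = 2)
  write_synthetic_inputs(spec, dir)
  expect_true(all(file.exists(file.path(
    dir, c("model.json", "expression.tsv", "samples.tsv",
           "kinetics.tsv", "medium.tsv", "truth.json")))))
  m <- load_model(file.path(dir, "model.json"))
  expect_equal(nrow(m$reactions), nrow(make_toy_network()$model$reactions))
  es <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "samples.tsv"))
  expect_equal(nrow(es$values), length(m$genes))
  kin <- read_kinetics(file.path(dir, "kinetics.tsv"))
  med <- read_medium(file.path(dir, "medium.tsv"))
  expect_true(all(names(med) %in% m$reactions$id[m$reactions$exchange]))
  expect_true(all(names(kin) %in% m$reactions$id))
  unlink(dir, recursive = TRUE)
})
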