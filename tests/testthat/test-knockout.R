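prepared_mini <- function() {
  m <- mini_gpr_model()
  expr <- c(G1 = 3, G2 = 2, G3 = 4, G4 = 5)
  prepare_sample_model(m, expr, c(R_or = 1, R_and = 1), medium = numeric(0))
}

test_that("gene knockouts respect isozymes and complexes", {
  km <- prepared_mini()
  base <- profile_of_model(km)
  ko <- gene_ko_matrix(km, base, drop_transport = FALSE)
  expect_s3_class(ko, "knockout_matrix")
  expect_equal(ko$kind, "gene")

  # G1 alone: isozyme G2 keeps R_or alive -> no effect anywhere
  expect_true(all(ko$effects["G1", ] == 0))
  expect_false(ko$infeasible[["G1"]])

  # G3: complex partner missing kills R_and; biomass must fall
  expect_equal(ko$effects["G3", "R_and"], -1L)
  expect_equal(ko$effects["G3", "DM_b"], -1L)
  expect_true(ko$infeasible[["G3"]])   # maintained biomass bound relaxed
  expect_identical(ko$effects["G3", ], ko$effects["G4", ])
})

test_that("gene_ko_matrix demands the abundance attribute", {
  m <- mini_gpr_model()
  base <- profile_of_model(m)
  expect_error(gene_ko_matrix(m, base), "abundance")
})

test_that("metabolite knockouts zero every touching reaction", {
  km <- prepared_mini()
  base <- profile_of_model(km)
  ko <- metabolite_ko_matrix(km, base, drop_transport = FALSE)
  expect_equal(ko$kind, "metabolite")
  # killing b removes both conversion routes and the sink
  expect_equal(ko$effects["b[c]", "R_or"], -1L)
  expect_equal(ko$effects["b[c]", "R_and"], -1L)
  expect_equal(ko$effects["b[c]", "DM_b"], -1L)
  # killing a removes everything (source too)
  expect_true(all(ko$effects["a[c]", c("SRC", "R_or", "R_and", "DM_b", "DM_a")] == -1L))
  expect_true(ko$infeasible[["a[c]"]])
})

test_that("transport columns are dropped when requested", {
  net <- make_toy_network()
  m <- net$model
  expr <- stats::setNames(rep(64, length(m$genes)), m$genes)
  km <- prepare_sample_model(m, expr, default_kinetics(m), default_medium())
  base <- profile_of_model(km)
  ko <- gene_ko_matrix(km, base, genes = "HMGCR", drop_transport = TRUE)
  expect_false(any(grepl("^T_", colnames(ko$effects))))
  ko2 <- gene_ko_matrix(km, base, genes = "HMGCR", drop_transport = FALSE)
  expect_true(any(grepl("^T_", colnames(ko2$effects))))
})

fake_ko <- function(effects, kind = "gene") {
  structure(list(kind = kind, effects = effects,
                 infeasible = stats::setNames(rep(FALSE, nrow(effects)),
                                              rownames(effects))),
            class = "knockout_matrix")
}

test_that("effective_scores matches hand computation", {
  eff <- rbind(gA = c(-1L, -1L, 0L, 1L),
               gB = c(0L, 1L, -1L, 0L))
  colnames(eff) <- paste0("r", 1:4)
  ko <- fake_ko(eff)
  diff <- data.frame(reaction_id = paste0("r", 1:4),
                     effect = c(-2, 1, -3, 0.1),
                     p = c(0.01, 0.01, 0.2, 0.01))
  # L = (1, 1, 0, 0); sgn = (-1, 1, -1, 1)
  s <- effective_scores(ko, diff)
  expect_equal(s$score, c((-1) * (-1) + (-1) * 1, 0 * (-1) + 1 * 1))
  expect_error(effective_scores(ko, diff, p_thresh = 0), "p_thresh")
  expect_error(effective_scores(ko, diff, lfc_thresh = -1), "positive")
  expect_error(effective_scores(ko, diff[1:2, ]), "does not cover")
})

test_that("norm_background_p applies the two-sided normal tail", {
  s <- c(10, rep(0, 10), -2)
  r <- norm_background_p(s)
  mu <- mean(s); sg <- sd(s)
  expect_equal(r$p, 2 * pnorm(-abs(s - mu) / sg))
  expect_equal(r$fdr, p.adjust(r$p, "BH"))
  s2 <- c(seq_len(11), 30)
  rb <- norm_background_p(s2, robust = TRUE)
  expect_equal(rb$p, 2 * pnorm(-abs(s2 - median(s2)) / mad(s2)))
  expect_error(norm_background_p(1:5), "at least 10")
  expect_error(norm_background_p(rep(1, 12)), "zero spread")
})

test_that("meta_scores averages scores and Stouffer-combines p-values", {
  t1 <- data.frame(entity_id = c("a", "b", "c"), kind = "gene",
                   score = c(4, 0, -3), p = c(0.01, 0.9, 0.04),
                   fdr = NA, stringsAsFactors = FALSE)
  t2 <- data.frame(entity_id = c("a", "b", "c"), kind = "gene",
                   score = c(6, 0, -1), p = c(0.02, 0.8, 0.5),
                   fdr = NA, stringsAsFactors = FALSE)
  ms <- meta_scores(list(t1, t2))
  expect_equal(ms$meta_score[ms$entity_id == "a"], 5)
  z_a <- (qnorm(1 - 0.01 / 2) + qnorm(1 - 0.02 / 2)) / sqrt(2)
  expect_equal(ms$meta_z[ms$entity_id == "a"], z_a, tolerance = 1e-12)
  # zero scores contribute zero z regardless of p
  expect_equal(ms$meta_z[ms$entity_id == "b"], 0)
  z_c <- -(qnorm(1 - 0.04 / 2) + qnorm(1 - 0.5 / 2)) / sqrt(2)
  expect_equal(ms$meta_z[ms$entity_id == "c"], z_c, tolerance = 1e-12)
  expect_equal(ms$n_studies, rep(2L, 3))
  expect_error(meta_scores(list(t1)), "at least 2")
})

test_that("meta_scores handles entities missing from a study", {
  t1 <- data.frame(entity_id = c("a", "b"), kind = "gene",
                   score = c(2, 1), p = c(0.1, 0.2), fdr = NA,
                   stringsAsFactors = FALSE)
  t2 <- data.frame(entity_id = "a", kind = "gene",
                   score = 4, p = 0.1, fdr = NA, stringsAsFactors = FALSE)
  ms <- meta_scores(list(t1, t2))
  expect_equal(ms$n_studies[ms$entity_id == "b"], 1L)
  expect_equal(ms$meta_score[ms$entity_id == "b"], 1)
})
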