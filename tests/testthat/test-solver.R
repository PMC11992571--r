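test_that("fba solves the chain model analytically", {
  m <- make_chain_model(cap = 14, uptake = 10, demand_cap = 0)
  r <- fba(m)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective, 10)          # min(uptake, cap)
  expect_equal(unname(r$fluxes["R1"]), 10)
  expect_equal(unname(r$fluxes["EX_A"]), -10)

  m2 <- make_chain_model(cap = 6, uptake = 10, demand_cap = 0)
  expect_equal(fba(m2)$objective, 6)
  expect_error(fba(m, "NOPE"), "unknown objective")
})

test_that("fba agrees with the boot::simplex oracle on random networks", {
  for (seed in 1:25) {
    m <- random_network(seed)
    mine <- fba(m)
    obj <- as.numeric(m$reactions$id == m$objective_id)
    orc <- oracle_lp(stoich_matrix(m), m$reactions$lb, m$reactions$ub, obj)
    expect_equal(mine$status, orc$status, info = paste("seed", seed))
    expect_equal(mine$objective, orc$objective, tolerance = 1e-7,
                 info = paste("seed", seed))
  }
})

test_that("fba reports infeasibility", {
  # demand forces more flux than the source can supply
  rx <- list(rxn_row("SRC", c("a[c]" = 1), exchange = TRUE, ub = 2),
             rxn_row("DM", c("a[c]" = -1), lb = 5, ub = 10))
  m <- assemble_model("a[c]", rx, character(0), "DM", "DM")
  r <- fba(m)
  expect_equal(r$status, "infeasible")
  expect_true(is.na(r$objective))
})

test_that("apply_maintenance pins lexicographic lower bounds", {
  m <- make_chain_model(cap = 14, uptake = 10, demand_cap = 2)
  mm <- apply_maintenance(m, fraction = 0.9)
  rl <- function(mod, id) mod$reactions$lb[mod$reactions$id == id]
  expect_equal(rl(mm, "DM_A"), 1.8)             # 0.9 * 2
  expect_equal(rl(mm, "EX_B"), 0.9 * 8.2)       # biomass under ATP bound
  expect_length(attr(mm, "maintenance_flags"), 0)

  # zero ATP optimum is flagged, not fatal
  m0 <- make_chain_model(demand_cap = 0)
  mm0 <- apply_maintenance(m0)
  expect_true("atp_demand_zero" %in% attr(mm0, "maintenance_flags"))
  expect_equal(rl(mm0, "DM_A"), 0)
  expect_equal(rl(mm0, "EX_B"), 9)
})

test_that("fva matches the oracle and rounds small values to zero", {
  for (seed in c(3, 11, 17)) {
    m <- random_network(seed)
    f <- fva(m)
    expect_equal(f$status, "optimal")
    S <- as.matrix(stoich_matrix(m))
    for (j in seq_len(nrow(m$reactions))) {
      obj <- as.numeric(seq_len(nrow(m$reactions)) == j)
      lo <- oracle_lp(S, m$reactions$lb, m$reactions$ub, obj, maximize = FALSE)
      hi <- oracle_lp(S, m$reactions$lb, m$reactions$ub, obj, maximize = TRUE)
      lov <- lo$objective; if (abs(lov) < 1e-6) lov <- 0
      hiv <- hi$objective; if (abs(hiv) < 1e-6) hiv <- 0
      expect_equal(unname(f$fva_min[j]), lov, tolerance = 1e-7)
      expect_equal(unname(f$fva_max[j]), hiv, tolerance = 1e-7)
    }
  }
})

test_that("relax_to_feasible drops biomass first, then ATP", {
  m <- make_chain_model(cap = 14, uptake = 10, demand_cap = 2)
  mm <- apply_maintenance(m)
  # cutting the conversion step kills biomass but not the ATP demand
  k <- which(mm$reactions$id == "R1")
  m2 <- mm; m2$reactions$ub[k] <- 0
  r <- senflux:::relax_to_feasible(m2)
  expect_identical(r$flags, "biomass_lb_relaxed")
  # cutting the uptake kills both
  k2 <- which(mm$reactions$id == "EX_A")
  m3 <- mm; m3$reactions$lb[k2] <- 0
  r3 <- senflux:::relax_to_feasible(m3)
  expect_identical(r3$flags, c("biomass_lb_relaxed", "atp_lb_relaxed"))
  # feasible model untouched
  r0 <- senflux:::relax_to_feasible(mm)
  expect_length(r0$flags, 0)
})

test_that("flux_profile is deterministic and summary options differ sanely", {
  net <- make_toy_network()
  m <- net$model
  expr <- stats::setNames(rep(64, length(m$genes)), m$genes)
  p1 <- flux_profile(m, expr, default_kinetics(m), default_medium(), "s1")
  p2 <- flux_profile(m, expr, default_kinetics(m), default_medium(), "s1")
  expect_identical(p1$values, p2$values)
  expect_true(all(p1$values >= 0))            # split model
  expect_true(all(p1$fva_min <= p1$fva_max + 1e-9))
  pv <- flux_profile(m, expr, default_kinetics(m), default_medium(), "s1",
                     summary = "fba_vertex")
  # the vertex solution also lies within the FVA band
  expect_true(all(pv$values >= p1$fva_min - 1e-6 &
                  pv$values <= p1$fva_max + 1e-6))
})

test_that("profiles_to_matrix assembles dimensions and names", {
  m <- split_reversible(make_chain_model())
  p1 <- profile_of_model(apply_maintenance(m), sample_id = "a")
  p2 <- profile_of_model(apply_maintenance(m), sample_id = "b")
  mat <- profiles_to_matrix(list(p1, p2))
  expect_equal(dim(mat), c(5, 2))   # EX_A splits into _f/_b
  expect_equal(colnames(mat), c("a", "b"))
  expect_identical(mat[, "a"], mat[, "b"])
})
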