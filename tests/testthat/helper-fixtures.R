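# Shared fixtures: hand-built models and a random-network generator.

rxn_row <- function(id, stoich, gpr = "", subsystem = "", exchange = FALSE,
                    transport = FALSE, lb = 0, ub = 1000) {
  list(id = id, stoich = stoich, gpr = gpr, subsystem = subsystem,
       exchange = exchange, transport = transport, lb = lb, ub = ub,
       reversible = lb < 0)
}

assemble_model <- function(met_ids, rx, genes, objective_id, atp_demand_id) {
  mets <- data.frame(id = met_ids, name = met_ids,
                     compartment = sub("^.*\\[([^]]*)\\]$", "\\1", met_ids),
                     stringsAsFactors = FALSE)
  rdf <- data.frame(
    id = vapply(rx, `[[`, "", "id"),
    lb = vapply(rx, `[[`, 0, "lb"),
    ub = vapply(rx, `[[`, 0, "ub"),
    reversible = vapply(rx, `[[`, TRUE, "reversible"),
    subsystem = vapply(rx, `[[`, "", "subsystem"),
    gpr = vapply(rx, `[[`, "", "gpr"),
    exchange = vapply(rx, `[[`, TRUE, "exchange"),
    transport = vapply(rx, `[[`, TRUE, "transport"),
    stringsAsFactors = FALSE
  )
  rdf$stoich <- lapply(rx, `[[`, "stoich")
  metabolic_model(mets, rdf, genes, objective_id, atp_demand_id)
}

# A tiny two-path network with isozyme (OR) and complex (AND) rules:
#   SRC -> a;  a -> b via R_or (G1 or G2) or via R_and (G3 and G4);
#   DM_b (objective), DM_a (atp stand-in).
mini_gpr_model <- function(src_ub = 10, or_ub = 1000, and_ub = 1000) {
  rx <- list(
    rxn_row("SRC", c("a[c]" = 1), exchange = TRUE, ub = src_ub),
    rxn_row("R_or", c("a[c]" = -1, "b[c]" = 1), gpr = "G1 or G2", ub = or_ub,
            subsystem = "path1"),
    rxn_row("R_and", c("a[c]" = -1, "b[c]" = 1), gpr = "G3 and G4", ub = and_ub,
            subsystem = "path2"),
    rxn_row("DM_b", c("b[c]" = -1), subsystem = "sink"),
    rxn_row("DM_a", c("a[c]" = -1), ub = 2, subsystem = "sink")
  )
  assemble_model(c("a[c]", "b[c]"), rx, c("G1", "G2", "G3", "G4"),
                 objective_id = "DM_b", atp_demand_id = "DM_a")
}

# Random feasible irreversible DAG network, <= 20 reactions. All bounds are
# integers and all coefficients unit, so LP optima are exact rationals and
# sign comparisons are numerically safe.
random_network <- function(seed) {
  set.seed(seed)
  nm <- sample(4:7, 1)
  met_ids <- sprintf("m%d[c]", seq_len(nm))
  ngene <- sample(3:6, 1)
  genes <- sprintf("G%d", seq_len(ngene))
  rand_gpr <- function() {
    kind <- sample(c("none", "single", "or", "and"), 1,
                   prob = c(0.2, 0.4, 0.2, 0.2))
    if (kind == "none") return("")
    g <- sample(genes, min(2, ngene))
    switch(kind,
           single = g[1],
           or = paste(g[1], "or", g[2]),
           and = paste(g[1], "and", g[2]))
  }
  rx <- list(rxn_row("SRC1", c("m1[c]" = 1), exchange = TRUE,
                     ub = sample(4:10, 1)))
  if (nm >= 5 && runif(1) < 0.5) {
    rx <- c(rx, list(rxn_row("SRC2", c("m2[c]" = 1), exchange = TRUE,
                             ub = sample(4:10, 1))))
  }
  k <- 0L
  for (j in 2:nm) {
    for (rep in seq_len(sample(1:2, 1))) {
      k <- k + 1L
      from <- sample(seq_len(j - 1), 1)
      rx <- c(rx, list(rxn_row(
        sprintf("R%02d", k),
        stats::setNames(c(-1, 1), c(met_ids[from], met_ids[j])),
        gpr = rand_gpr(), ub = sample(2:10, 1),
        subsystem = sample(c("s1", "s2", "s3"), 1))))
    }
  }
  rx <- c(rx, list(
    rxn_row("DM_obj", stats::setNames(-1, met_ids[nm]), subsystem = "sink"),
    rxn_row("DM_alt", stats::setNames(-1, met_ids[sample(seq_len(nm), 1)]),
            ub = sample(1:3, 1), subsystem = "sink")
  ))
  model <- assemble_model(met_ids, rx, genes, "DM_obj", "DM_alt")
  abundance <- stats::setNames(round(runif(ngene, 0.5, 3), 3), genes)
  attr(model, "abundance") <- abundance
  model
}
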