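# Run an expression with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Specification for the synthetic senescence benchmark
#'
#' Defaults emulate the multi-study case-control design and the replicative
#' passage series the pipeline is meant for: 5 studies of 5 proliferative
#' vs 5 senescent samples, a planted two-fold down-regulation
#' (`effect_lfc = -1`) of the mevalonate-pathway genes with lognormal
#' expression noise (`noise_sd = 0.3`), and a 9-point passage series with
#' duplicate samples.
#'
#' @param n_studies number of case-control studies (>= 2).
#' @param samples_per_group samples per group per study (>= 2).
#' @param passages passage numbers for time-series mode (>= 3 distinct).
#' @param replicates_per_passage samples per passage point.
#' @param effect_lfc planted log2 effect on targeted genes in senescent
#'   samples (default -1).
#' @param study_jitter_sd between-study sd of the planted effect.
#' @param noise_sd sdlog of the multiplicative lognormal expression noise.
#' @param seed integer seed for the simulators.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_studies = 5, samples_per_group = 5,
                       passages = seq(13, 37, by = 3),
                       replicates_per_passage = 2,
                       effect_lfc = -1, study_jitter_sd = 0.1,
                       noise_sd = 0.3, seed = 1L) {
  if (n_studies < 2) stop("n_studies must be >= 2")
  if (samples_per_group < 2) stop("samples_per_group must be >= 2")
  if (length(unique(passages)) < 3) stop("need >= 3 distinct passages")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_studies = n_studies, samples_per_group = samples_per_group,
                 passages = passages,
                 replicates_per_passage = replicates_per_passage,
                 effect_lfc = effect_lfc, study_jitter_sd = study_jitter_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

toy_rxn <- function(id, stoich, gpr = "", subsystem = "", exchange = FALSE,
                    transport = FALSE, lb = 0, ub = SFX_DEFAULT_BOUND) {
  list(id = id, stoich = stoich, gpr = gpr, subsystem = subsystem,
       exchange = exchange, transport = transport, lb = lb, ub = ub,
       reversible = lb < 0)
}

#' Build the toy senescence network
#'
#' A deterministic stoichiometric model with: two interchangeable carbon
#' sources (glucose- and acetate-like) feeding an acetyl-CoA hub; an ATP
#' demand capped at a fixed maintenance rate; a six-step mevalonate-like
#' chain (genes HMGCR, MVK, PMVK, MVD, FDPS, FDFT1 - one per step, mirroring
#' the canonical rate-limiting enzymes) feeding a lipid subsystem of four
#' redundant two-step branches that converge on a lipid pool; the pool is
#' biomass-essential and can also be exported to two storage sinks; a
#' nucleotide-like biomass precursor with isozyme-protected synthesis; and
#' three decoy pathways with independent genes that carry expression noise
#' but no planted effect. Every essential non-mevalonate enzymatic step is
#' isozyme-protected (OR rules), so single-gene knockouts are only lethal
#' along the planted pathway.
#'
#' @param spec a [synth_spec()] (only network-size knobs are read; the
#'   default network is fixed).
#' @return list with `model` (a `metabolic_model`) and `truth` (planted
#'   ground-truth sets).
#' @export
make_toy_network <- function(spec = synth_spec()) {
  met <- function(id, name = id) {
    data.frame(id = id, name = name,
               compartment = sub("^.*\\[([^]]*)\\]$", "\\1", id),
               stringsAsFactors = FALSE)
  }
  mets <- do.call(rbind, lapply(c(
    "glc[x]", "glc[c]", "ac[x]", "ac[c]", "accoa[c]", "atp[c]", "nuc[c]",
    "mev_R[c]", "5pmev[c]", "5dpmev[c]", "ipdp[c]", "frdp[c]", "sql[c]",
    "lipa[c]", "lipb[c]", "lipc[c]", "lipd[c]", "lip_pool[c]",
    "stora[x]", "storb[x]",
    "da1[c]", "da2[c]", "da3[c]", "da3[x]",
    "db1[c]", "db2[c]", "db3[c]", "db3[x]",
    "dc1[c]", "dc2[c]", "dc3[c]", "dc3[x]"
  ), met))

  rx <- list(
    toy_rxn("EX_glc", c("glc[x]" = -1), exchange = TRUE, subsystem = "exchange"),
    toy_rxn("T_glc", c("glc[x]" = -1, "glc[c]" = 1), transport = TRUE,
            subsystem = "transport", lb = -SFX_DEFAULT_BOUND),
    toy_rxn("EX_ac", c("ac[x]" = -1), exchange = TRUE, subsystem = "exchange"),
    toy_rxn("T_ac", c("ac[x]" = -1, "ac[c]" = 1), transport = TRUE,
            subsystem = "transport"),
    toy_rxn("R_glyc", c("glc[c]" = -1, "accoa[c]" = 1), gpr = "GLY1 or GLY2",
            subsystem = "glycolysis"),
    toy_rxn("R_acs", c("ac[c]" = -1, "accoa[c]" = 1), gpr = "ACS1 or ACS2",
            subsystem = "glycolysis"),
    toy_rxn("R_atp", c("accoa[c]" = -1, "atp[c]" = 1), gpr = "ATPG1 or ATPG2",
            subsystem = "energy"),
    toy_rxn("DM_atp", c("atp[c]" = -1), subsystem = "energy", ub = 10),
    toy_rxn("R_nuc", c("accoa[c]" = -1, "nuc[c]" = 1), gpr = "NUC1 or NUC2",
            subsystem = "nucleotide"),
    # mevalonate-like chain, one gene per step
    toy_rxn("R_HMGCR", c("accoa[c]" = -1, "mev_R[c]" = 1), gpr = "HMGCR",
            subsystem = "mevalonate"),
    toy_rxn("R_MVK", c("mev_R[c]" = -1, "5pmev[c]" = 1), gpr = "MVK",
            subsystem = "mevalonate"),
    toy_rxn("R_PMVK", c("5pmev[c]" = -1, "5dpmev[c]" = 1), gpr = "PMVK",
            subsystem = "mevalonate"),
    toy_rxn("R_MVD", c("5dpmev[c]" = -1, "ipdp[c]" = 1), gpr = "MVD",
            subsystem = "mevalonate"),
    toy_rxn("R_FDPS", c("ipdp[c]" = -1, "frdp[c]" = 1), gpr = "FDPS",
            subsystem = "mevalonate"),
    toy_rxn("R_FDFT1", c("frdp[c]" = -1, "sql[c]" = 1), gpr = "FDFT1",
            subsystem = "mevalonate"),
    # lipid branch: four redundant two-step routes into one pool
    toy_rxn("R_LIPA1", c("sql[c]" = -1, "lipa[c]" = 1), gpr = "LIPA1", subsystem = "lipid"),
    toy_rxn("R_LIPA2", c("lipa[c]" = -1, "lip_pool[c]" = 1), gpr = "LIPA2", subsystem = "lipid"),
    toy_rxn("R_LIPB1", c("sql[c]" = -1, "lipb[c]" = 1), gpr = "LIPB1", subsystem = "lipid"),
    toy_rxn("R_LIPB2", c("lipb[c]" = -1, "lip_pool[c]" = 1), gpr = "LIPB2", subsystem = "lipid"),
    toy_rxn("R_LIPC1", c("sql[c]" = -1, "lipc[c]" = 1), gpr = "LIPC1", subsystem = "lipid"),
    toy_rxn("R_LIPC2", c("lipc[c]" = -1, "lip_pool[c]" = 1), gpr = "LIPC2", subsystem = "lipid"),
    toy_rxn("R_LIPD1", c("sql[c]" = -1, "lipd[c]" = 1), gpr = "LIPD1", subsystem = "lipid"),
    toy_rxn("R_LIPD2", c("lipd[c]" = -1, "lip_pool[c]" = 1), gpr = "LIPD2", subsystem = "lipid"),
    # two redundant storage sinks for excess lipid
    toy_rxn("T_storA", c("lip_pool[c]" = -1, "stora[x]" = 1), transport = TRUE,
            subsystem = "transport"),
    toy_rxn("EX_storA", c("stora[x]" = -1), exchange = TRUE, subsystem = "exchange"),
    toy_rxn("T_storB", c("lip_pool[c]" = -1, "storb[x]" = 1), transport = TRUE,
            subsystem = "transport"),
    toy_rxn("EX_storB", c("storb[x]" = -1), exchange = TRUE, subsystem = "exchange"),
    toy_rxn("biomass", c("accoa[c]" = -0.2, "lip_pool[c]" = -1, "nuc[c]" = -0.1),
            subsystem = "biomass")
  )
  for (d in c("a", "b", "c")) {
    g <- toupper(d)
    rx <- c(rx, list(
      toy_rxn(paste0("R_D", d, "1"),
              stats::setNames(c(-1, 1), c("glc[c]", paste0("d", d, "1[c]"))),
              gpr = paste0("DEC", g, "1"), subsystem = paste0("decoy_", d)),
      toy_rxn(paste0("R_D", d, "2"),
              stats::setNames(c(-1, 1), paste0("d", d, c("1[c]", "2[c]"))),
              gpr = paste0("DEC", g, "2"), subsystem = paste0("decoy_", d)),
      toy_rxn(paste0("R_D", d, "3"),
              stats::setNames(c(-1, 1), paste0("d", d, c("2[c]", "3[c]"))),
              gpr = paste0("DEC", g, "3"), subsystem = paste0("decoy_", d)),
      toy_rxn(paste0("T_D", d),
              stats::setNames(c(-1, 1), paste0("d", d, c("3[c]", "3[x]"))),
              transport = TRUE, subsystem = "transport"),
      toy_rxn(paste0("EX_d", d, "3"),
              stats::setNames(-1, paste0("d", d, "3[x]")),
              exchange = TRUE, subsystem = "exchange")
    ))
  }

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

  planted_genes <- c("HMGCR", "MVK", "PMVK", "MVD", "FDPS", "FDFT1")
  other_genes <- c("GLY1", "GLY2", "ACS1", "ACS2", "ATPG1", "ATPG2",
                   "NUC1", "NUC2",
                   "LIPA1", "LIPA2", "LIPB1", "LIPB2", "LIPC1", "LIPC2",
                   "LIPD1", "LIPD2",
                   "DECA1", "DECA2", "DECA3", "DECB1", "DECB2", "DECB3",
                   "DECC1", "DECC2", "DECC3")
  model <- metabolic_model(mets, rdf, c(planted_genes, other_genes),
                           objective_id = "biomass", atp_demand_id = "DM_atp")
  truth <- list(
    planted_down_genes = planted_genes,
    planted_down_subsystems = c("mevalonate", "lipid"),
    planted_agonist_metabolites = c("mev_R[c]", "5pmev[c]", "5dpmev[c]",
                                    "ipdp[c]", "frdp[c]", "sql[c]"),
    neutral_genes = other_genes,
    neutral_subsystems = c("decoy_a", "decoy_b", "decoy_c")
  )
  list(model = model, truth = truth)
}

#' Default kinetic table for a model
#'
#' All-ones kcat for every GPR-bearing reaction, so expression alone drives
#' capacity differences.
#' @param model a `metabolic_model`.
#' @return named numeric vector (reaction id -> kcat).
#' @export
default_kinetics <- function(model) {
  has <- nzchar(model$reactions$gpr)
  stats::setNames(rep(1, sum(has)), model$reactions$id[has])
}

#' Default medium for the toy network
#'
#' Generous uptake of both carbon sources, leaving the network
#' enzyme-limited.
#' @param glc,ac maximal uptake rates.
#' @return named numeric vector over exchange ids.
#' @export
default_medium <- function(glc = 500, ac = 500) {
  c(EX_glc = glc, EX_ac = ac)
}

#' Simulate expression profiles over the toy network
#'
#' Baseline gene means are drawn log-uniform: planted (mevalonate) genes
#' from `2^[4, 5]` and all other genes from `2^[5.6, 6.6]`, so the planted
#' pathway is the rate-limiting step of its branch, mimicking the role of
#' the rate-limiting mevalonate enzymes. Sample values are
#' `mean * 2^group_effect * exp(N(0, noise_sd))` (multiplicative lognormal
#' noise, positive support like FPKM). In case-control mode the planted
#' genes carry `effect_lfc` (with per-study jitter, sd 0.1) in senescent
#' samples; in time-series mode the effect grows linearly from 0 at the
#' first passage to `effect_lfc` at the last.
#'
#' @param model the toy `metabolic_model`.
#' @param truth ground-truth list from [make_toy_network()].
#' @param spec a [synth_spec()].
#' @param mode `"case_control"` or `"timeseries"`.
#' @param seed integer seed (default from `spec`).
#' @return an `expression_set` covering all studies (case-control) or the
#'   passage series (one study, `study_id = "hdf_ts"`).
#' @export
simulate_expression <- function(model, truth, spec = synth_spec(),
                                mode = c("case_control", "timeseries"),
                                seed = spec$seed) {
  mode <- match.arg(mode)
  genes <- model$genes
  planted <- truth$planted_down_genes
  with_seed(seed, {
    means <- stats::setNames(numeric(length(genes)), genes)
    is_pl <- genes %in% planted
    means[is_pl] <- 2^runif(sum(is_pl), 4, 5)
    means[!is_pl] <- 2^runif(sum(!is_pl), 5.6, 6.6)

    if (mode == "case_control") {
      cols <- list()
      meta <- list()
      for (s in seq_len(spec$n_studies)) {
        eff <- stats::setNames(numeric(length(genes)), genes)
        eff[is_pl] <- rnorm(sum(is_pl), spec$effect_lfc, spec$study_jitter_sd)
        for (grp in c("proliferative", "senescent")) {
          for (i in seq_len(spec$samples_per_group)) {
            sample_id <- sprintf("study%d_%s_%d", s, substr(grp, 1, 3), i)
            shift <- if (grp == "senescent") eff else 0 * eff
            vals <- means * 2^shift * exp(rnorm(length(genes), 0, spec$noise_sd))
            cols[[sample_id]] <- vals
            meta[[sample_id]] <- data.frame(
              sample_id = sample_id, study_id = sprintf("study%d", s),
              group = grp, passage = NA_integer_, stringsAsFactors = FALSE)
          }
        }
      }
      mat <- do.call(cbind, cols)
      rownames(mat) <- genes
      expression_set(mat, do.call(rbind, unname(meta)))
    } else {
      pas <- spec$passages
      prange <- max(pas) - min(pas)
      cols <- list()
      meta <- list()
      for (p in pas) {
        frac <- (p - min(pas)) / prange
        for (r in seq_len(spec$replicates_per_passage)) {
          sample_id <- sprintf("p%02d_r%d", p, r)
          shift <- stats::setNames(numeric(length(genes)), genes)
          shift[is_pl] <- spec$effect_lfc * frac
          vals <- means * 2^shift * exp(rnorm(length(genes), 0, spec$noise_sd))
          cols[[sample_id]] <- vals
          meta[[sample_id]] <- data.frame(
            sample_id = sample_id, study_id = "hdf_ts",
            group = NA_character_, passage = as.integer(p),
            stringsAsFactors = FALSE)
        }
      }
      mat <- do.call(cbind, cols)
      rownames(mat) <- genes
      expression_set(mat, do.call(rbind, unname(meta)))
    }
  })
}

#' Build a linear chain toy model
#'
#' Minimal fixture: `EX_A` imports metabolite A (uptake up to
#' `uptake`), `R1` converts A to B with capacity `cap`, and `EX_B` secretes
#' B (the objective). `DM_A` serves as a (trivial) ATP-demand stand-in with
#' capacity `demand_cap`. Used for analytically solvable checks.
#'
#' @param cap capacity (upper bound) of the conversion step.
#' @param uptake maximal uptake of A.
#' @param demand_cap upper bound of the demand used as ATP stand-in.
#' @return a `metabolic_model`.
#' @export
make_chain_model <- function(cap = 14, uptake = 10, demand_cap = 2) {
  mets <- data.frame(id = c("A[c]", "B[c]"), name = c("A", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- list(
    toy_rxn("EX_A", c("A[c]" = -1), exchange = TRUE, lb = -uptake,
            subsystem = "exchange"),
    toy_rxn("R1", c("A[c]" = -1, "B[c]" = 1), ub = cap, subsystem = "chain"),
    toy_rxn("EX_B", c("B[c]" = -1), exchange = TRUE, subsystem = "exchange"),
    toy_rxn("DM_A", c("A[c]" = -1), ub = demand_cap, subsystem = "demand")
  )
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
  metabolic_model(mets, rdf, character(0), objective_id = "EX_B",
                  atp_demand_id = "DM_A")
}
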