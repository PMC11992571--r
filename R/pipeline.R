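#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow in one validated
#' object; the effective configuration is persisted next to any outputs so
#' a run can be reproduced exactly.
#'
#' @param fdr_thresh FDR significance threshold (default 0.05).
#' @param p_thresh raw p-value gate for the significance logical `L`
#'   (default 0.05).
#' @param lfc_thresh absolute log2FC gate for `L` (default 0.5).
#' @param maintenance_fraction ATP/biomass maintenance fraction (default 0.9).
#' @param bootstrap_B DA bootstrap iterations (default 1000).
#' @param min_subsystem_size smallest subsystem scored for significance.
#' @param sigma abundance-to-flux conversion constant.
#' @param seed root seed; stage seeds are derived as small fixed offsets.
#' @param moderated use limma moderation in case-control tests.
#' @param summary flux summary, `"midpoint"` or `"fba_vertex"`.
#' @return a `run_config` list.
#' @export
run_config <- function(fdr_thresh = 0.05, p_thresh = 0.05, lfc_thresh = 0.5,
                       maintenance_fraction = 0.9, bootstrap_B = 1000,
                       min_subsystem_size = 3, sigma = 1, seed = 1L,
                       moderated = TRUE,
                       summary = c("midpoint", "fba_vertex")) {
  stopifnot(fdr_thresh > 0, fdr_thresh < 1, p_thresh > 0, p_thresh < 1,
            lfc_thresh > 0, maintenance_fraction > 0, maintenance_fraction <= 1,
            bootstrap_B >= 100, min_subsystem_size >= 1, sigma > 0)
  structure(list(fdr_thresh = fdr_thresh, p_thresh = p_thresh,
                 lfc_thresh = lfc_thresh,
                 maintenance_fraction = maintenance_fraction,
                 bootstrap_B = bootstrap_B,
                 min_subsystem_size = min_subsystem_size, sigma = sigma,
                 seed = as.integer(seed), moderated = moderated,
                 summary = match.arg(summary)),
            class = "run_config")
}

sfx_write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

sfx_write_matrix <- function(m, path, id_col = "reaction_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  sfx_write_tsv(df, path)
}

# Fit the normal background when it is fittable; otherwise leave p/fdr NA
# (e.g. a run where every knockout score is identical).
safe_background <- function(es) {
  if (length(es$score) >= 10 && stats::sd(es$score) > 0) {
    norm_background_p(es)
  } else {
    es
  }
}

geometric_mean_expression <- function(values) {
  exp(rowMeans(log(values + 1e-9)))
}

subsystem_map <- function(model) {
  stats::setNames(model$reactions$subsystem, model$reactions$id)
}

#' Flux profiles for a set of samples
#'
#' @param model a `metabolic_model` (unsplit).
#' @param expr an `expression_set`.
#' @param kinetics,medium constraint inputs.
#' @param config a [run_config()].
#' @return list of `flux_profile` objects, one per sample.
#' @export
sample_profiles <- function(model, expr, kinetics, medium,
                            config = run_config()) {
  lapply(seq_len(ncol(expr$values)), function(i) {
    flux_profile(model, expr$values[, i], kinetics, medium,
                 sample_id = colnames(expr$values)[i], sigma = config$sigma,
                 maintenance_fraction = config$maintenance_fraction,
                 summary = config$summary)
  })
}

#' Run the full per-study workflow
#'
#' Per-sample constrained flux profiles, case-control differential flux,
#' pathway DA with bootstrap significance, and gene/metabolite knockout
#' effective scores (knockouts are computed on a study-representative model
#' built from the geometric-mean expression across the study's samples).
#' When `out_dir` is given, all tables are written as TSV plus a manifest
#' and the effective configuration as JSON.
#'
#' @param model a `metabolic_model`.
#' @param expr an `expression_set` (may span several studies).
#' @param study_id the study to run.
#' @param kinetics,medium constraint inputs (defaults: all-ones kcat and
#'   the toy medium).
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return a `study_result` list: `study_id`, `fluxes` (matrix), `profiles`,
#'   `diff`, `da`, `ko_gene`, `ko_met`, `scores_gene`, `scores_met`.
#' @export
run_study <- function(model, expr, study_id,
                      kinetics = default_kinetics(model),
                      medium = default_medium(), config = run_config(),
                      out_dir = NULL) {
  keep <- expr$samples$study_id == study_id
  if (!any(keep)) stop("no samples for study '", study_id, "'")
  sub <- expression_set(expr$values[, expr$samples$sample_id[keep], drop = FALSE],
                        expr$samples[keep, , drop = FALSE])
  profiles <- sample_profiles(model, sub, kinetics, medium, config)
  fluxes <- profiles_to_matrix(profiles)
  diff <- case_control_diff(fluxes, sub$samples$group,
                            moderated = config$moderated, study_id = study_id)

  split_model <- split_reversible(model)
  subs <- subsystem_map(split_model)
  sets <- significant_sets(diff, config$p_thresh, config$lfc_thresh)
  da <- da_score(sets$up, sets$down, subs, min_size = config$min_subsystem_size)
  da <- da_significance(da, subs, B = config$bootstrap_B,
                        seed = config$seed + 11L)

  gm <- geometric_mean_expression(sub$values)
  komodel <- prepare_sample_model(model, gm, kinetics, medium,
                                  sigma = config$sigma,
                                  maintenance_fraction = config$maintenance_fraction)
  kobase <- profile_of_model(komodel, sample_id = paste0(study_id, "_rep"),
                             summary = config$summary)
  ko_gene <- gene_ko_matrix(komodel, kobase)
  ko_met <- metabolite_ko_matrix(komodel, kobase)
  scores_gene <- safe_background(
    effective_scores(ko_gene, diff, config$p_thresh, config$lfc_thresh))
  scores_met <- safe_background(
    effective_scores(ko_met, diff, config$p_thresh, config$lfc_thresh))

  res <- list(study_id = study_id, fluxes = fluxes, profiles = profiles,
              diff = diff, da = da, ko_gene = ko_gene, ko_met = ko_met,
              scores_gene = scores_gene, scores_met = scores_met)
  class(res) <- "study_result"
  if (!is.null(out_dir)) write_study_outputs(res, config, out_dir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result '", x$study_id, "': ", ncol(x$fluxes), " samples, ",
      nrow(x$fluxes), " reactions\n", sep = "")
  invisible(x)
}

write_study_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sfx_write_matrix(res$fluxes, file.path(out_dir, "fluxes.tsv"))
  fmin <- vapply(res$profiles, function(p) p$fva_min, res$profiles[[1]]$fva_min)
  fmax <- vapply(res$profiles, function(p) p$fva_max, res$profiles[[1]]$fva_max)
  colnames(fmin) <- colnames(fmax) <- colnames(res$fluxes)
  sfx_write_matrix(fmin, file.path(out_dir, "fva_min.tsv"))
  sfx_write_matrix(fmax, file.path(out_dir, "fva_max.tsv"))
  sfx_write_tsv(as.data.frame(res$diff), file.path(out_dir, "diff.tsv"))
  sfx_write_tsv(as.data.frame(res$da), file.path(out_dir, "da.tsv"))
  sfx_write_matrix(res$ko_gene$effects, file.path(out_dir, "ko_gene.tsv"),
                   id_col = "entity_id")
  sfx_write_matrix(res$ko_met$effects, file.path(out_dir, "ko_met.tsv"),
                   id_col = "entity_id")
  sfx_write_tsv(as.data.frame(res$scores_gene),
                file.path(out_dir, "scores_gene.tsv"))
  sfx_write_tsv(as.data.frame(res$scores_met),
                file.path(out_dir, "scores_met.tsv"))
  flags <- lapply(res$profiles, `[[`, "flags")
  names(flags) <- colnames(res$fluxes)
  jsonlite::write_json(flags, file.path(out_dir, "flags.json"))
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(study_id = res$study_id,
                   files = c("fluxes.tsv", "fva_min.tsv", "fva_max.tsv",
                             "diff.tsv", "da.tsv", "ko_gene.tsv", "ko_met.tsv",
                             "scores_gene.tsv", "scores_met.tsv",
                             "flags.json", "config.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Combine per-study results into meta-level tables
#'
#' Fixed-effects meta flux analysis, meta-level pathway DA from the
#' combined significant sets, and Stouffer-combined knockout effective
#' scores.
#'
#' @param studies list of `study_result` objects (>= 2).
#' @param model the `metabolic_model` shared by the studies.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list: `meta` (a `meta_result`), `meta_da` (a `pathway_da`),
#'   `meta_scores_gene`, `meta_scores_met`.
#' @export
run_meta <- function(studies, model, config = run_config(), out_dir = NULL) {
  if (length(studies) < 2) stop("need at least 2 study results")
  diffs <- lapply(studies, `[[`, "diff")
  meta <- meta_table(diffs, fdr_thresh = config$fdr_thresh)
  subs <- subsystem_map(split_reversible(model))
  mda <- meta_da(meta, subs, B = config$bootstrap_B,
                 seed = config$seed + 23L,
                 min_size = config$min_subsystem_size)
  msg <- meta_scores(lapply(studies, `[[`, "scores_gene"))
  msm <- meta_scores(lapply(studies, `[[`, "scores_met"))
  res <- list(meta = meta, meta_da = mda, meta_scores_gene = msg,
              meta_scores_met = msm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sfx_write_tsv(as.data.frame(meta), file.path(out_dir, "meta_flux.tsv"))
    sfx_write_tsv(as.data.frame(mda), file.path(out_dir, "meta_da.tsv"))
    sfx_write_tsv(msg, file.path(out_dir, "meta_scores_gene.tsv"))
    sfx_write_tsv(msm, file.path(out_dir, "meta_scores_met.tsv"))
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Run the passage time-series workflow
#'
#' Per-sample flux profiles, the per-reaction linear trend
#' (`flux ~ passage`), the biomass-versus-passage Spearman trajectory, a
#' per-passage-contrast DA trajectory (each passage against the first), and
#' knockout effective scores driven by the trend signs.
#'
#' @param model a `metabolic_model`.
#' @param expr an `expression_set` whose samples carry `passage` metadata.
#' @param kinetics,medium,config,out_dir as in [run_study()].
#' @return list: `fluxes`, `diff` (slopes), `biomass_trajectory`
#'   (`rho`, `p`), `da_trajectory` (long data.frame), `scores_gene`,
#'   `scores_met`.
#' @export
run_timeseries <- function(model, expr,
                           kinetics = default_kinetics(model),
                           medium = default_medium(), config = run_config(),
                           out_dir = NULL) {
  pas <- expr$samples$passage
  if (any(is.na(pas))) stop("all samples need passage metadata")
  if (length(unique(pas)) < 3) stop("need >= 3 distinct passages")
  profiles <- sample_profiles(model, expr, kinetics, medium, config)
  fluxes <- profiles_to_matrix(profiles)
  diff <- timeseries_diff(fluxes, pas, study_id = "timeseries")

  split_model <- split_reversible(model)
  biomass_id <- if (model$objective_id %in% rownames(fluxes))
    model$objective_id else paste0(model$objective_id, "_f")
  # correlate passage-level biomass (replicates averaged) with passage
  bm <- tapply(fluxes[biomass_id, ], pas, mean)
  traj <- spearman_trajectory(as.numeric(bm), as.numeric(names(bm)))

  subs <- subsystem_map(split_model)
  p0 <- min(pas)
  da_rows <- list()
  for (p in sort(unique(pas))) {
    if (p == p0) {
      d0 <- da_score(character(0), character(0), subs,
                     min_size = config$min_subsystem_size)
      d0$passage <- p
      da_rows[[as.character(p)]] <- as.data.frame(d0)
      next
    }
    sel <- pas %in% c(p0, p)
    dd <- case_control_diff(fluxes[, sel, drop = FALSE],
                            ifelse(pas[sel] == p0, "start", "later"),
                            case = "later", moderated = config$moderated,
                            study_id = sprintf("p%s_vs_p%s", p, p0))
    ss <- significant_sets(dd, config$p_thresh, config$lfc_thresh)
    dsc <- da_score(ss$up, ss$down, subs, min_size = config$min_subsystem_size)
    dsc$passage <- p
    da_rows[[as.character(p)]] <- as.data.frame(dsc)
  }
  da_traj <- do.call(rbind, da_rows)
  rownames(da_traj) <- NULL

  gm <- geometric_mean_expression(expr$values)
  komodel <- prepare_sample_model(model, gm, kinetics, medium,
                                  sigma = config$sigma,
                                  maintenance_fraction = config$maintenance_fraction)
  kobase <- profile_of_model(komodel, sample_id = "ts_rep",
                             summary = config$summary)
  ko_gene <- gene_ko_matrix(komodel, kobase)
  ko_met <- metabolite_ko_matrix(komodel, kobase)
  # time-series effects are raw slopes, not log2FCs, so the magnitude gate
  # reduces to "non-zero slope" at flux tolerance; p does the selection
  scores_gene <- safe_background(
    effective_scores(ko_gene, diff, config$p_thresh, SFX_FLUX_TOL))
  scores_met <- safe_background(
    effective_scores(ko_met, diff, config$p_thresh, SFX_FLUX_TOL))

  res <- list(fluxes = fluxes, diff = diff, biomass_trajectory = traj,
              da_trajectory = da_traj, scores_gene = scores_gene,
              scores_met = scores_met)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sfx_write_matrix(fluxes, file.path(out_dir, "fluxes.tsv"))
    sfx_write_tsv(as.data.frame(diff), file.path(out_dir, "beta.tsv"))
    sfx_write_tsv(da_traj, file.path(out_dir, "da_trajectory.tsv"))
    sfx_write_tsv(as.data.frame(scores_gene),
                  file.path(out_dir, "scores_gene.tsv"))
    sfx_write_tsv(as.data.frame(scores_met),
                  file.path(out_dir, "scores_met.tsv"))
    jsonlite::write_json(list(rho = traj$rho, p = traj$p),
                         file.path(out_dir, "biomass_trajectory.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Write a full synthetic input bundle to disk
#'
#' Materializes the toy model JSON, expression and metadata TSVs, kinetics
#' and medium TSVs, and the ground-truth JSON - the on-disk interface the
#' command-line entry point consumes.
#'
#' @param spec a [synth_spec()].
#' @param out_dir output directory.
#' @param mode `"case_control"` or `"timeseries"`.
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_inputs <- function(spec = synth_spec(), out_dir,
                                   mode = "case_control") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net <- make_toy_network(spec)
  write_model(net$model, file.path(out_dir, "model.json"))
  expr <- simulate_expression(net$model, net$truth, spec, mode = mode)
  edf <- data.frame(gene = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  sfx_write_tsv(edf, file.path(out_dir, "expression.tsv"))
  sfx_write_tsv(expr$samples, file.path(out_dir, "samples.tsv"))
  kin <- default_kinetics(net$model)
  sfx_write_tsv(data.frame(reaction_id = names(kin), kcat = unname(kin)),
                file.path(out_dir, "kinetics.tsv"))
  med <- default_medium()
  sfx_write_tsv(data.frame(exchange_id = names(med), max_uptake = unname(med)),
                file.path(out_dir, "medium.tsv"))
  jsonlite::write_json(net$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = FALSE)
  invisible(out_dir)
}
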