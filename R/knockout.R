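#' All-against-all gene knockout matrix
#'
#' For each gene, zeroes the capacity of every reaction whose GPR rule
#' evaluates to 0 once that gene's abundance is set to 0 (isozymes survive
#' through OR-sums), recomputes the flux profile on the maintained model,
#' and records the ternary effect `sign(v_ko - v_baseline)` per reaction
#' (zero within tolerance `1e-6`). Knockouts that make the maintained model
#' infeasible are relaxed (biomass lower bound first, then ATP) and
#' flagged rather than failing, so lethal knockouts yield defined effect
#' vectors. Transport-reaction columns are dropped by default because
#' transport fluxes carry no enzyme-capacity constraint.
#'
#' @param model a maintained sample model from [prepare_sample_model()],
#'   which carries the gene abundances used to build it.
#' @param baseline the model's own `flux_profile` (see [profile_of_model()]).
#' @param genes genes to knock out (default: all model genes).
#' @param drop_transport drop transport columns (default TRUE).
#' @return a `knockout_matrix`: list with `kind = "gene"`, `effects`
#'   (entities x reactions integer matrix in \{-1, 0, 1\}), and
#'   `infeasible` (named logical: knockout needed relaxation).
#' @export
gene_ko_matrix <- function(model, baseline, genes = model$genes,
                           drop_transport = TRUE) {
  ab <- attr(model, "abundance")
  if (is.null(ab)) {
    stop("model carries no abundance attribute; build it with prepare_sample_model()")
  }
  trees <- model$gpr_trees
  gene_rxns <- lapply(genes, function(g) {
    which(vapply(trees, function(t) g %in% gpr_genes(t), logical(1)))
  })
  names(gene_rxns) <- genes
  effects <- matrix(0L, nrow = length(genes), ncol = nrow(model$reactions),
                    dimnames = list(genes, model$reactions$id))
  infeasible <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (g in genes) {
    idx <- gene_rxns[[g]]
    if (length(idx) == 0) next
    ab2 <- ab
    ab2[g] <- 0
    dead <- idx[vapply(idx, function(k) {
      gpr_eval_tree(trees[[k]], ab2) <= 1e-12
    }, logical(1))]
    if (length(dead) == 0) next
    r <- ko_effect_row(model, baseline, dead)
    effects[g, ] <- r$effect
    infeasible[g] <- r$infeasible
  }
  finalize_ko(effects, infeasible, "gene", model, drop_transport)
}

#' All-against-all metabolite knockout matrix
#'
#' For each metabolite, zero-bounds every reaction whose stoichiometry
#' involves it (including exchanges and transports, so knocking out an
#' extracellular metabolite disables its import), then recomputes the flux
#' profile; effects are recorded as in [gene_ko_matrix()].
#'
#' @inheritParams gene_ko_matrix
#' @param metabolites metabolite ids to knock out (default: all).
#' @return a `knockout_matrix` with `kind = "metabolite"`.
#' @export
metabolite_ko_matrix <- function(model, baseline,
                                 metabolites = model$metabolites$id,
                                 drop_transport = TRUE) {
  S <- stoich_matrix(model)
  effects <- matrix(0L, nrow = length(metabolites), ncol = nrow(model$reactions),
                    dimnames = list(metabolites, model$reactions$id))
  infeasible <- stats::setNames(rep(FALSE, length(metabolites)), metabolites)
  for (m in metabolites) {
    dead <- which(S[m, ] != 0)
    if (length(dead) == 0) next
    r <- ko_effect_row(model, baseline, dead)
    effects[m, ] <- r$effect
    infeasible[m] <- r$infeasible
  }
  finalize_ko(effects, infeasible, "metabolite", model, drop_transport)
}

# Zero the given reaction columns, re-solve (with maintenance relaxation if
# needed), and return the ternary effect row vs the baseline midpoints.
ko_effect_row <- function(model, baseline, dead_idx) {
  m2 <- model
  m2$reactions$ub[dead_idx] <- 0
  m2$reactions$lb[dead_idx] <- pmin(m2$reactions$lb[dead_idx], 0)
  rel <- relax_to_feasible(m2)
  f <- fva(rel$model)
  if (identical(f$status, "infeasible")) {
    v <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  } else {
    v <- (f$fva_min + f$fva_max) / 2
    v[abs(v) < SFX_FLUX_TOL] <- 0
  }
  d <- v - baseline$values[model$reactions$id]
  eff <- integer(length(d))
  eff[d > SFX_FLUX_TOL] <- 1L
  eff[d < -SFX_FLUX_TOL] <- -1L
  list(effect = eff, infeasible = length(rel$flags) > 0)
}

finalize_ko <- function(effects, infeasible, kind, model, drop_transport) {
  if (drop_transport) {
    keep <- !model$reactions$transport
    effects <- effects[, keep, drop = FALSE]
  }
  structure(list(kind = kind, effects = effects, infeasible = infeasible),
            class = "knockout_matrix")
}

#' @export
print.knockout_matrix <- function(x, ...) {
  cat("knockout_matrix (", x$kind, "): ", nrow(x$effects), " entities x ",
      ncol(x$effects), " reactions; ", sum(x$infeasible),
      " knockout(s) needed relaxation\n", sep = "")
  invisible(x)
}

#' Effective scores for knockout entities
#'
#' The effective score of entity i is
#' `sum_j effects[i, j] * sign(effect_j) * L_j`, where `effect_j` is the
#' study's flux log2FC (or time-series slope) and `L_j` is 1 when reaction
#' j passes the significance gate (`p < p_thresh` and
#' `|effect| > lfc_thresh`). A positive score means the knockout pushes the
#' significant fluxes in the same direction the condition does.
#'
#' @param ko a `knockout_matrix`.
#' @param diff a `diff_result` covering the knockout matrix's reactions.
#' @param p_thresh raw p-value gate, in (0, 1) (default 0.05).
#' @param lfc_thresh absolute effect gate, > 0 (default 0.5).
#' @return an `effective_scores` data.frame: `entity_id`, `kind`, `score`,
#'   `p`, `fdr` (p/fdr filled by [norm_background_p()]).
#' @export
effective_scores <- function(ko, diff, p_thresh = 0.05, lfc_thresh = 0.5) {
  if (p_thresh <= 0 || p_thresh >= 1) stop("p_thresh must lie in (0, 1)")
  if (lfc_thresh <= 0) stop("lfc_thresh must be positive")
  idx <- match(colnames(ko$effects), diff$reaction_id)
  if (anyNA(idx)) {
    stop("differential result does not cover knockout reactions: ",
         paste(colnames(ko$effects)[is.na(idx)][1:5], collapse = ", "))
  }
  L <- as.numeric(diff$p[idx] < p_thresh & abs(diff$effect[idx]) > lfc_thresh)
  sgn <- sign(diff$effect[idx])
  score <- as.numeric(ko$effects %*% (sgn * L))
  res <- data.frame(entity_id = rownames(ko$effects), kind = ko$kind,
                    score = score, p = NA_real_, fdr = NA_real_,
                    stringsAsFactors = FALSE)
  class(res) <- c("effective_scores", "data.frame")
  res
}

#' Normal-background significance for effective scores
#'
#' Fits a normal distribution to all entity scores of the run (mean/sd, or
#' median/MAD with `robust = TRUE`) and assigns each entity the two-sided
#' tail probability `2 * (1 - pnorm(|score - mu| / sigma))`, plus BH FDR.
#'
#' @param scores an `effective_scores` data.frame or a numeric vector.
#' @param robust use median/MAD location and scale (default FALSE).
#' @return the input with `p` and `fdr` filled (or a list for a vector).
#' @export
norm_background_p <- function(scores, robust = FALSE) {
  s <- if (is.data.frame(scores)) scores$score else scores
  if (length(s) < 10) stop("need at least 10 entities to fit the background")
  mu <- if (robust) median(s) else mean(s)
  sg <- if (robust) mad(s) else sd(s)
  if (!is.finite(sg) || sg <= 0) stop("degenerate background: zero spread")
  p <- 2 * pnorm(-abs(s - mu) / sg)
  fdr <- bh_fdr(p)
  if (is.data.frame(scores)) {
    scores$p <- p
    scores$fdr <- fdr
    scores
  } else {
    list(p = p, fdr = fdr)
  }
}

#' Meta-combination of per-study effective scores
#'
#' The meta score is the arithmetic mean of per-study scores; the meta
#' p-value combines per-study normal-background p-values by signed Stouffer
#' weighting (`z_i = qnorm(1 - p_i/2) * sign(score_i)`,
#' `Z = sum(z_i) / sqrt(k)`), preserving direction; BH FDR across entities.
#' Entities absent from a study are excluded from that study's
#' contribution.
#'
#' @param tables list of `effective_scores` (p filled) from >= 2 studies.
#' @return a data.frame `entity_id`, `kind`, `meta_score`, `meta_z`,
#'   `meta_p`, `meta_fdr`, `n_studies`, plus per-study score columns.
#' @export
meta_scores <- function(tables) {
  if (length(tables) < 2) stop("need at least 2 studies")
  ids <- sort(unique(unlist(lapply(tables, `[[`, "entity_id"))))
  k <- length(tables)
  smat <- vapply(tables, function(t) t$score[match(ids, t$entity_id)],
                 numeric(length(ids)))
  pmat <- vapply(tables, function(t) t$p[match(ids, t$entity_id)],
                 numeric(length(ids)))
  if (length(ids) == 1) { smat <- matrix(smat, 1); pmat <- matrix(pmat, 1) }
  pmat <- pmin(pmax(pmat, 1e-300), 1)
  zmat <- qnorm(1 - pmat / 2) * sign(smat)
  zmat[!is.na(smat) & smat == 0] <- 0
  n_st <- rowSums(!is.na(smat))
  Z <- rowSums(zmat, na.rm = TRUE) / sqrt(pmax(n_st, 1))
  meta_p <- 2 * pnorm(-abs(Z))
  kind <- tables[[1]]$kind[match(ids, tables[[1]]$entity_id)]
  kind[is.na(kind)] <- tables[[1]]$kind[1]
  out <- data.frame(entity_id = ids, kind = kind,
                    meta_score = rowMeans(smat, na.rm = TRUE),
                    meta_z = Z, meta_p = meta_p, meta_fdr = bh_fdr(meta_p),
                    n_studies = n_st, stringsAsFactors = FALSE)
  for (i in seq_len(k)) out[[paste0("score_", i)]] <- smat[, i]
  out
}
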