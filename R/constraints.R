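#' Read a kinetic table
#'
#' Tab-separated table with columns `reaction_id` and `kcat` (turnover
#' numbers, events per unit time; any unit, as long as it is consistent
#' with the abundance-to-flux scale `sigma`).
#'
#' @param path TSV path.
#' @return named numeric vector of kcat values keyed by reaction id.
#' @export
read_kinetics <- function(path) {
  if (!file.exists(path)) stop("kinetics file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "kcat") %in% names(tab))) {
    stop("kinetics TSV must have columns 'reaction_id' and 'kcat'")
  }
  if (any(tab$kcat <= 0)) stop("kcat values must be positive")
  stats::setNames(tab$kcat, tab$reaction_id)
}

#' Read a medium specification
#'
#' Tab-separated table with columns `exchange_id` and `max_uptake`
#' (nonnegative maximal uptake rates in flux units).
#'
#' @param path TSV path.
#' @return named numeric vector of uptake bounds keyed by exchange id.
#' @export
read_medium <- function(path) {
  if (!file.exists(path)) stop("medium file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("exchange_id", "max_uptake") %in% names(tab))) {
    stop("medium TSV must have columns 'exchange_id' and 'max_uptake'")
  }
  if (any(tab$max_uptake < 0)) stop("uptake rates must be nonnegative")
  stats::setNames(tab$max_uptake, tab$exchange_id)
}

#' Read an expression matrix with sample metadata
#'
#' The expression TSV has genes as rows (first column `gene`) and samples
#' as columns, holding FPKM-like nonnegative values. The metadata TSV has
#' columns `sample_id`, `study_id`, and `group`
#' (`proliferative`/`senescent`) and/or `passage` (integer).
#'
#' @param expr_path expression TSV path.
#' @param meta_path sample metadata TSV path.
#' @return an `expression_set`: list with `values` (genes x samples matrix)
#'   and `samples` (metadata data.frame).
#' @export
read_expression <- function(expr_path, meta_path) {
  if (!file.exists(expr_path)) stop("expression file not found: ", expr_path)
  if (!file.exists(meta_path)) stop("sample metadata file not found: ", meta_path)
  tab <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- tab[[1]]
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- genes
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "study_id") %in% names(meta))) {
    stop("metadata TSV must have columns 'sample_id' and 'study_id'")
  }
  if (!"group" %in% names(meta)) meta$group <- NA_character_
  if (!"passage" %in% names(meta)) meta$passage <- NA_integer_
  expression_set(mat, meta)
}

#' Construct an expression set
#' @param values genes x samples numeric matrix (nonnegative).
#' @param samples data.frame with `sample_id`, `study_id`, and `group`
#'   and/or `passage`.
#' @return an object of class `expression_set`.
#' @export
expression_set <- function(values, samples) {
  if (any(values < 0)) stop("expression values must be nonnegative")
  miss <- setdiff(samples$sample_id, colnames(values))
  if (length(miss) > 0) {
    stop("samples missing from expression matrix: ", paste(miss, collapse = ", "))
  }
  structure(list(values = values[, samples$sample_id, drop = FALSE],
                 samples = samples),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$values), "genes x", ncol(x$values), "samples;",
      length(unique(x$samples$study_id)), "study(ies)\n")
  invisible(x)
}

#' Per-reaction enzyme abundance from an expression profile
#'
#' Evaluates each reaction's GPR rule against the gene abundances
#' (AND = min across complex subunits, OR = sum across isozymes). Reactions
#' without a rule get `NA`, the unconstrained sentinel.
#'
#' @param model a `metabolic_model`.
#' @param expr named numeric vector of gene abundances for one sample.
#' @return named numeric vector over reaction ids.
#' @export
enzyme_abundance <- function(model, expr) {
  out <- vapply(model$gpr_trees, function(tree) {
    if (is.null(tree)) NA_real_ else gpr_eval_tree(tree, expr)
  }, numeric(1))
  missing <- setdiff(unique(unlist(lapply(model$gpr_trees, gpr_genes))),
                     names(expr))
  if (length(missing) > 0) {
    warning("genes absent from expression profile treated as 0: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  stats::setNames(out, model$reactions$id)
}

#' Michaelis-Menten capacity bounds
#'
#' The maximal catalytic rate of reaction j is `Vmax_j = kcat_j *
#' abundance_j * sigma`, the saturated limit of Michaelis-Menten kinetics.
#' Reactions absent from the kinetic table, or with the unconstrained
#' abundance sentinel (`NA`), keep their default upper bound.
#'
#' @param abundance named vector from [enzyme_abundance()].
#' @param kinetics named kcat vector (see [read_kinetics()]).
#' @param sigma global abundance-to-flux conversion constant (default 1).
#'   A single constant preserves all the rank and ratio structure the
#'   downstream statistics use.
#' @return named numeric vector of upper bounds; `NA` where no capacity
#'   bound applies.
#' @export
vmax_bounds <- function(abundance, kinetics, sigma = 1) {
  v <- rep(NA_real_, length(abundance))
  names(v) <- names(abundance)
  has <- names(abundance) %in% names(kinetics) & !is.na(abundance)
  v[has] <- kinetics[names(abundance)[has]] * abundance[has] * sigma
  v
}

#' Build a per-sample constrained model
#'
#' Applies (i) Vmax upper bounds to GPR-bearing reactions (capping both
#' directions of reversible reactions), (ii) uptake bounds from the medium
#' to the listed exchange reactions, and (iii) zero uptake for every other
#' exchange; secretion stays unrestricted. Uptake is the negative-flux
#' direction of an exchange written as `met ->`. The input model is not
#' modified.
#'
#' @param model a `metabolic_model`.
#' @param expr named numeric gene-abundance vector for one sample.
#' @param kinetics named kcat vector.
#' @param medium named max-uptake vector over exchange ids.
#' @param sigma abundance-to-flux constant passed to [vmax_bounds()].
#' @return a constrained `metabolic_model` carrying the gene abundances in
#'   attribute `"abundance"` (used by the knockout routines).
#' @export
build_sample_model <- function(model, expr, kinetics, medium, sigma = 1) {
  rxn <- model$reactions
  bad <- setdiff(names(medium), rxn$id[rxn$exchange])
  if (length(bad) > 0) {
    stop("medium references non-exchange reaction(s): ",
         paste(bad, collapse = ", "))
  }
  ab <- suppressWarnings(enzyme_abundance(model, expr))
  vmax <- vmax_bounds(ab, kinetics, sigma)
  out <- model
  capped <- !is.na(vmax)
  out$reactions$ub[capped] <- pmin(out$reactions$ub[capped], vmax[capped])
  out$reactions$lb[capped] <- pmax(out$reactions$lb[capped], -vmax[capped])

  ex <- out$reactions$exchange
  # default: no uptake (lower bound at zero), secretion unrestricted
  out$reactions$lb[ex] <- pmax(out$reactions$lb[ex], 0)
  if (length(medium) > 0) {
    idx <- match(names(medium), out$reactions$id)
    out$reactions$lb[idx] <- -unname(medium)
  }
  out$reactions$reversible <- out$reactions$lb < 0
  attr(out, "abundance") <- expr
  attr(out, "sigma") <- sigma
  attr(out, "kinetics") <- kinetics
  validate_model(out)
  out
}
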