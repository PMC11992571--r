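#' @useDynLib senflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median p.adjust pnorm pt qnorm rnorm runif sd mad cor.test rbinom
#' @importFrom utils read.delim write.table
NULL

# Default flux bound used when no constraint applies. Finite on purpose:
# the simplex works with finite boxes, and 1000 flux units is far above any
# capacity the kinetic bounds produce, so it never binds in practice.
SFX_DEFAULT_BOUND <- 1000

#' Construct a stoichiometric metabolic model
#'
#' The in-memory representation used throughout the package. Metabolite ids
#' carry a bracketed compartment suffix (e.g. `"mev_R[c]"`, `"5pmev[x]"`).
#' Exchange reactions touch exactly one metabolite and encode the system
#' boundary: negative flux is uptake, positive flux secretion.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `reversible`,
#'   `subsystem`, `gpr`, `exchange`, `transport`, and a list-column `stoich`
#'   of named numeric vectors (metabolite id -> signed coefficient).
#' @param genes character vector of gene ids.
#' @param objective_id id of the biomass reaction.
#' @param atp_demand_id id of the ATP maintenance demand reaction.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes, objective_id,
                            atp_demand_id) {
  m <- structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      genes = genes,
      objective_id = objective_id,
      atp_demand_id = atp_demand_id
    ),
    class = "metabolic_model"
  )
  m$gpr_trees <- lapply(reactions$gpr, parse_gpr)
  names(m$gpr_trees) <- reactions$id
  validate_model(m)
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,", length(x$genes), "genes\n")
  cat("  objective:", x$objective_id, " ATP demand:", x$atp_demand_id, "\n")
  invisible(x)
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, compartment suffix consistency, nonzero
#' stoichiometric coefficients, bound ordering, single-metabolite exchanges,
#' that GPR rules only reference declared genes, and that the objective and
#' ATP demand reactions exist.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with an informative error otherwise.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  }
  suffix <- sub("^.*\\[([^]]*)\\]$", "\\1", met$id)
  bad <- suffix != met$compartment
  if (any(bad)) {
    stop("compartment suffix mismatch for metabolite(s): ",
         paste(met$id[bad], collapse = ", "))
  }
  for (k in seq_len(nrow(rxn))) {
    s <- rxn$stoich[[k]]
    if (length(s) == 0) stop("reaction '", rxn$id[k], "' has empty stoichiometry")
    if (any(s == 0)) stop("reaction '", rxn$id[k], "' has zero coefficient(s)")
    unknown <- setdiff(names(s), met$id)
    if (length(unknown) > 0) {
      stop("reaction '", rxn$id[k], "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    if (rxn$exchange[k] && length(s) != 1L) {
      stop("exchange reaction '", rxn$id[k], "' must touch exactly one metabolite")
    }
  }
  if (any(rxn$lb > rxn$ub)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(rxn$id[rxn$lb > rxn$ub], collapse = ", "))
  }
  for (k in seq_len(nrow(rxn))) {
    gg <- gpr_genes(model$gpr_trees[[k]])
    unknown <- setdiff(gg, model$genes)
    if (length(unknown) > 0) {
      stop("reaction '", rxn$id[k], "' GPR references undeclared gene(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!model$objective_id %in% rxn$id) {
    stop("objective reaction '", model$objective_id, "' not in model")
  }
  if (!model$atp_demand_id %in% rxn$id) {
    stop("ATP demand reaction '", model$atp_demand_id, "' not in model")
  }
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return a sparse `dgCMatrix` (metabolites x reactions) with dimnames.
#' @export
stoich_matrix <- function(model) {
  rxn <- model$reactions
  i <- integer(0); j <- integer(0); v <- numeric(0)
  midx <- seq_len(nrow(model$metabolites))
  names(midx) <- model$metabolites$id
  for (k in seq_len(nrow(rxn))) {
    s <- rxn$stoich[[k]]
    i <- c(i, midx[names(s)])
    j <- c(j, rep.int(k, length(s)))
    v <- c(v, unname(s))
  }
  Matrix::sparseMatrix(
    i = i, j = j, x = v,
    dims = c(nrow(model$metabolites), nrow(rxn)),
    dimnames = list(model$metabolites$id, rxn$id)
  )
}

#' Load a metabolic model from JSON
#'
#' The schema has top-level keys `metabolites` (objects with `id`, `name`,
#' `compartment`), `reactions` (objects with `id`, `stoich` map, `gpr`,
#' `subsystem`, `exchange`, `transport`, `lb`, `ub`), `genes`,
#' `objective_id` and `atp_demand_id`. Missing `lb`/`ub` default to
#' `-1000/1000` for reversible and `0/1000` for irreversible reactions;
#' `reversible` defaults to `lb < 0`.
#'
#' @param path path to a model JSON file.
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- jsonlite::read_json(path)
  need <- c("metabolites", "reactions", "genes", "objective_id", "atp_demand_id")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) stop("model JSON missing key(s): ", paste(miss, collapse = ", "))

  mets <- do.call(rbind, lapply(raw$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite record without 'id' in ", path)
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment))
                 sub("^.*\\[([^]]*)\\]$", "\\1", m$id) else m$compartment,
               stringsAsFactors = FALSE)
  }))

  rxns <- lapply(raw$reactions, function(r) {
    if (is.null(r$id)) stop("reaction record without 'id' in ", path)
    if (is.null(r$stoich) || length(r$stoich) == 0) {
      stop("reaction '", r$id, "' has no stoichiometry")
    }
    s <- unlist(r$stoich)
    lb <- if (is.null(r$lb)) NA_real_ else as.numeric(r$lb)
    ub <- if (is.null(r$ub)) SFX_DEFAULT_BOUND else as.numeric(r$ub)
    rev <- if (is.null(r$reversible)) NA else isTRUE(r$reversible)
    if (is.na(lb)) lb <- if (isTRUE(rev)) -SFX_DEFAULT_BOUND else 0
    if (is.na(rev)) rev <- lb < 0
    list(id = r$id, stoich = s,
         gpr = if (is.null(r$gpr)) "" else r$gpr,
         subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
         exchange = isTRUE(r$exchange), transport = isTRUE(r$transport),
         lb = lb, ub = ub, reversible = rev)
  })
  rdf <- data.frame(
    id = vapply(rxns, `[[`, "", "id"),
    lb = vapply(rxns, `[[`, 0, "lb"),
    ub = vapply(rxns, `[[`, 0, "ub"),
    reversible = vapply(rxns, `[[`, TRUE, "reversible"),
    subsystem = vapply(rxns, `[[`, "", "subsystem"),
    gpr = vapply(rxns, `[[`, "", "gpr"),
    exchange = vapply(rxns, `[[`, TRUE, "exchange"),
    transport = vapply(rxns, `[[`, TRUE, "transport"),
    stringsAsFactors = FALSE
  )
  rdf$stoich <- lapply(rxns, `[[`, "stoich")

  metabolic_model(
    metabolites = mets,
    reactions = rdf,
    genes = unlist(raw$genes),
    objective_id = raw$objective_id,
    atp_demand_id = raw$atp_demand_id
  )
}

#' Write a metabolic model to JSON
#'
#' Keys are emitted in a fixed canonical order so that
#' `write_model(load_model(f))` is byte-stable.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(k) {
    r <- model$reactions[k, ]
    s <- r$stoich[[1]]
    list(id = r$id, stoich = as.list(s), gpr = r$gpr, subsystem = r$subsystem,
         exchange = r$exchange, transport = r$transport,
         reversible = r$reversible, lb = r$lb, ub = r$ub)
  })
  obj <- list(metabolites = mets, reactions = rxns,
              genes = as.list(model$genes),
              objective_id = model$objective_id,
              atp_demand_id = model$atp_demand_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Split reversible reactions into irreversible pairs
#'
#' Each reversible reaction `R` (with `lb < 0`) becomes a forward reaction
#' `R_f` with bounds `(max(0, lb), max(0, ub))` and a backward reaction
#' `R_b` with negated stoichiometry and bounds `(max(0, -ub), -lb)`. Net
#' flux is `v(R_f) - v(R_b)`, and any LP optimum over the original model is
#' preserved. Downstream statistics work on the nonnegative split fluxes so
#' that log fold changes are well defined.
#'
#' @param model a `metabolic_model`.
#' @return a `metabolic_model` whose reactions all satisfy `lb >= 0`.
#' @export
split_reversible <- function(model) {
  rxn <- model$reactions
  rev <- which(rxn$lb < 0)
  if (length(rev) == 0) return(model)
  rows <- vector("list", nrow(rxn) + length(rev))
  nxt <- 1L
  for (k in seq_len(nrow(rxn))) {
    r <- rxn[k, ]
    if (r$lb >= 0) {
      rows[[nxt]] <- r; nxt <- nxt + 1L
    } else {
      fwd <- r
      fwd$id <- paste0(r$id, "_f")
      fwd$lb <- max(0, r$lb)
      fwd$ub <- max(0, r$ub)
      fwd$reversible <- FALSE
      bwd <- r
      bwd$id <- paste0(r$id, "_b")
      bwd$stoich <- list(-r$stoich[[1]])
      bwd$lb <- max(0, -r$ub)
      bwd$ub <- -r$lb
      bwd$reversible <- FALSE
      rows[[nxt]] <- fwd
      rows[[nxt + 1L]] <- bwd
      nxt <- nxt + 2L
    }
  }
  rxn2 <- do.call(rbind, rows)
  rownames(rxn2) <- NULL
  obj <- model$objective_id
  atp <- model$atp_demand_id
  rename <- function(id) if (id %in% rxn$id[rev]) paste0(id, "_f") else id
  metabolic_model(model$metabolites, rxn2, model$genes, rename(obj), rename(atp))
}

#' Flag dead-end metabolites
#'
#' A metabolite is a dead end if it lacks either a producing or a consuming
#' reaction (accounting for reversibility).
#'
#' @param model a `metabolic_model`.
#' @return named logical vector over metabolite ids.
#' @export
dead_end_metabolites <- function(model) {
  S <- as.matrix(stoich_matrix(model))
  rev <- model$reactions$lb < 0
  producible <- rowSums(S > 0 | (S != 0 & rep(rev, each = nrow(S)))) > 0
  consumable <- rowSums(S < 0 | (S != 0 & rep(rev, each = nrow(S)))) > 0
  stats::setNames(!(producible & consumable), model$metabolites$id)
}
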