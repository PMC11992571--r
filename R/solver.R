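# LP tolerances: optimality/feasibility 1e-9 inside the simplex; fluxes
# smaller than SFX_FLUX_TOL in absolute value are treated as zero.
SFX_FLUX_TOL <- 1e-6

lp_parts <- function(model) {
  list(A = as.matrix(stoich_matrix(model)),
       b = rep(0, nrow(model$metabolites)),
       lb = model$reactions$lb,
       ub = model$reactions$ub)
}

#' Flux balance analysis
#'
#' Maximizes the flux of one reaction subject to steady state (`S v = 0`)
#' and the model's flux bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction to maximize; defaults to the model's
#'   biomass objective.
#' @return list with `status` (`"optimal"` or `"infeasible"`), `objective`
#'   (optimum, `NA` if infeasible), and `fluxes` (named vector at one
#'   optimal vertex).
#' @export
fba <- function(model, objective_id = model$objective_id) {
  p <- lp_parts(model)
  j <- match(objective_id, model$reactions$id)
  if (is.na(j)) stop("unknown objective reaction: ", objective_id)
  cvec <- rep(0, ncol(p$A))
  cvec[j] <- 1
  r <- .lp_solve_cpp(p$A, p$b, p$lb, p$ub, cvec, TRUE)
  if (r$status == 1L) {
    return(list(status = "infeasible", objective = NA_real_, fluxes = NULL))
  }
  if (r$status != 0L) stop("LP solver failed to converge (status ", r$status, ")")
  fl <- stats::setNames(r$x, model$reactions$id)
  list(status = "optimal", objective = r$objective, fluxes = fl)
}

#' Apply maintenance constraints
#'
#' Lexicographically fixes baseline energy and growth requirements: first
#' maximize the ATP demand flux and set its lower bound to
#' `fraction x optimum`; then, under that constraint, maximize biomass and
#' set its lower bound to `fraction x optimum`. A zero optimum leaves the
#' corresponding bound at zero and records a flag.
#'
#' @param model a constrained `metabolic_model`.
#' @param fraction maintenance fraction (default 0.9).
#' @param biomass_fraction apply the biomass bound as well (default TRUE).
#' @return the model with updated lower bounds and an attribute
#'   `"maintenance_flags"` (character vector of degeneracies).
#' @export
apply_maintenance <- function(model, fraction = 0.9, biomass_fraction = TRUE) {
  flags <- character(0)
  out <- model
  r1 <- fba(out, out$atp_demand_id)
  if (r1$status != "optimal" || r1$objective <= SFX_FLUX_TOL) {
    flags <- c(flags, "atp_demand_zero")
  } else {
    j <- match(out$atp_demand_id, out$reactions$id)
    out$reactions$lb[j] <- fraction * r1$objective
  }
  if (biomass_fraction) {
    r2 <- fba(out, out$objective_id)
    if (r2$status != "optimal" || r2$objective <= SFX_FLUX_TOL) {
      flags <- c(flags, "biomass_zero")
    } else {
      j <- match(out$objective_id, out$reactions$id)
      out$reactions$lb[j] <- fraction * r2$objective
    }
  }
  attr(out, "maintenance_flags") <- flags
  out
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum attainable flux under all model
#' constraints (typically after [apply_maintenance()]).
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to analyze (default all).
#' @return list with `fva_min`, `fva_max` (named vectors) and `status`.
#' @export
fva <- function(model, reactions = model$reactions$id) {
  p <- lp_parts(model)
  cols <- match(reactions, model$reactions$id)
  if (anyNA(cols)) stop("unknown reaction id(s) in fva()")
  r <- .fva_cpp(p$A, p$b, p$lb, p$ub, as.integer(cols))
  if (r$status != 0L) {
    return(list(status = "infeasible", fva_min = NULL, fva_max = NULL))
  }
  lo <- r$range[, 1]
  hi <- r$range[, 2]
  lo[abs(lo) < SFX_FLUX_TOL] <- 0
  hi[abs(hi) < SFX_FLUX_TOL] <- 0
  list(status = "optimal",
       fva_min = stats::setNames(lo, reactions),
       fva_max = stats::setNames(hi, reactions))
}

#' Relax maintenance bounds until feasible
#'
#' Used for knockouts that make the maintained model infeasible: first the
#' biomass lower bound is dropped to zero, then the ATP demand lower bound.
#' Returns the relaxed model plus the flags that were needed.
#' @keywords internal
relax_to_feasible <- function(model) {
  flags <- character(0)
  p <- lp_parts(model)
  feasible <- function(m) {
    q <- lp_parts(m)
    r <- .lp_solve_cpp(q$A, q$b, q$lb, q$ub, rep(0, ncol(q$A)), TRUE)
    r$status == 0L
  }
  r0 <- .lp_solve_cpp(p$A, p$b, p$lb, p$ub, rep(0, ncol(p$A)), TRUE)
  if (r0$status == 0L) return(list(model = model, flags = flags))
  j <- match(model$objective_id, model$reactions$id)
  if (model$reactions$lb[j] > 0 && model$reactions$ub[j] >= 0) {
    model$reactions$lb[j] <- 0
    flags <- c(flags, "biomass_lb_relaxed")
    if (feasible(model)) return(list(model = model, flags = flags))
  }
  j <- match(model$atp_demand_id, model$reactions$id)
  if (model$reactions$lb[j] > 0 && model$reactions$ub[j] >= 0) {
    model$reactions$lb[j] <- 0
    flags <- c(flags, "atp_lb_relaxed")
    if (feasible(model)) return(list(model = model, flags = flags))
  }
  flags <- c(flags, "infeasible_after_relaxation")
  list(model = model, flags = flags)
}

#' Summarize an FVA result as a flux profile
#' @keywords internal
fva_to_profile <- function(sample_id, f, reactions, flags = character(0),
                           summary = c("midpoint", "fba_vertex"),
                           model = NULL) {
  summary <- match.arg(summary)
  if (identical(f$status, "infeasible")) {
    z <- stats::setNames(rep(0, length(reactions)), reactions)
    return(structure(list(sample_id = sample_id, values = z, fva_min = z,
                          fva_max = z, flags = c(flags, "infeasible")),
                     class = "flux_profile"))
  }
  mid <- (f$fva_min + f$fva_max) / 2
  if (summary == "fba_vertex" && !is.null(model)) {
    v <- fba(model)
    mid <- v$fluxes[reactions]
  }
  mid[abs(mid) < SFX_FLUX_TOL] <- 0
  structure(list(sample_id = sample_id, values = mid, fva_min = f$fva_min,
                 fva_max = f$fva_max, flags = flags),
            class = "flux_profile")
}

#' @export
print.flux_profile <- function(x, ...) {
  cat("flux_profile '", x$sample_id, "': ", length(x$values), " reactions",
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Prepare a sample-constrained, split, maintained model
#'
#' Convenience composition: [build_sample_model()] then
#' [split_reversible()] then [apply_maintenance()]. All downstream
#' statistics and knockouts operate on this representation, whose fluxes
#' are all nonnegative.
#'
#' @inheritParams build_sample_model
#' @param maintenance_fraction fraction for [apply_maintenance()].
#' @param biomass_fraction apply the biomass maintenance bound.
#' @return a maintained `metabolic_model`.
#' @export
prepare_sample_model <- function(model, expr, kinetics, medium, sigma = 1,
                                 maintenance_fraction = 0.9,
                                 biomass_fraction = TRUE) {
  m <- build_sample_model(model, expr, kinetics, medium, sigma = sigma)
  m2 <- split_reversible(m)
  m2 <- apply_maintenance(m2, fraction = maintenance_fraction,
                          biomass_fraction = biomass_fraction)
  attr(m2, "abundance") <- attr(m, "abundance")
  attr(m2, "sigma") <- attr(m, "sigma")
  attr(m2, "kinetics") <- attr(m, "kinetics")
  m2
}

#' Per-sample flux profile
#'
#' Builds the constrained model for one sample and summarizes each
#' reaction's flux as the midpoint of its FVA interval (a symmetric summary
#' that avoids arbitrary-vertex artifacts; set `summary = "fba_vertex"` for
#' the plain FBA solution). Deterministic given its inputs.
#'
#' @inheritParams prepare_sample_model
#' @param sample_id label stored in the profile.
#' @param summary `"midpoint"` (default) or `"fba_vertex"`.
#' @return a `flux_profile` over the split model's reaction ids.
#' @export
flux_profile <- function(model, expr, kinetics, medium, sample_id = "sample",
                         sigma = 1, maintenance_fraction = 0.9,
                         biomass_fraction = TRUE,
                         summary = c("midpoint", "fba_vertex")) {
  m <- prepare_sample_model(model, expr, kinetics, medium, sigma = sigma,
                            maintenance_fraction = maintenance_fraction,
                            biomass_fraction = biomass_fraction)
  profile_of_model(m, sample_id = sample_id, summary = summary)
}

#' Flux profile of an already-prepared model
#' @param model a maintained `metabolic_model` (see [prepare_sample_model()]).
#' @inheritParams flux_profile
#' @return a `flux_profile`.
#' @export
profile_of_model <- function(model, sample_id = "sample",
                             summary = c("midpoint", "fba_vertex")) {
  f <- fva(model)
  fva_to_profile(sample_id, f, model$reactions$id,
                 flags = attr(model, "maintenance_flags") %||% character(0),
                 summary = summary, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble flux profiles into a reactions x samples matrix
#' @param profiles list of `flux_profile` objects.
#' @return numeric matrix (reactions x samples).
#' @export
profiles_to_matrix <- function(profiles) {
  ids <- names(profiles[[1]]$values)
  out <- vapply(profiles, function(p) p$values[ids], numeric(length(ids)))
  rownames(out) <- ids
  colnames(out) <- vapply(profiles, `[[`, "", "sample_id")
  out
}
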