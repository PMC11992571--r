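# Independent LP / FVA / knockout oracles built on boot::simplex.
#
# boot::simplex requires nonnegative right-hand sides, so variables are
# shifted to y = v - lb >= 0 and equality rows with negative rhs are negated
# before the call (equalities are sign-invariant).

oracle_lp <- function(S, lb, ub, obj, maximize = TRUE) {
  S <- as.matrix(S)
  n <- ncol(S)
  b <- as.numeric(-S %*% lb)
  # all-zero rows (metabolites left without reactions) are vacuous when
  # their rhs is 0, and boot::simplex cannot pivot on them
  zero_row <- apply(S, 1, function(r) all(r == 0))
  if (any(zero_row & abs(b) > 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_))
  }
  S <- S[!zero_row, , drop = FALSE]
  b <- b[!zero_row]
  if (nrow(S) == 0) {
    # box-only LP: each variable sits at whichever bound its objective favors
    sgn <- if (maximize) obj else -obj
    v <- ifelse(sgn > 0, ub, lb)
    return(list(status = "optimal", objective = sum(obj * v), fluxes = v))
  }
  if (all(b == 0) && all(lb == 0)) {
    # presolve: with zero rhs and nonnegative variables, any balance row whose
    # nonzero coefficients share one sign forces those variables to zero
    active <- rep(TRUE, ncol(S))
    repeat {
      Ss <- S[, active, drop = FALSE]
      fixed <- rep(FALSE, ncol(Ss))
      for (i in seq_len(nrow(Ss))) {
        nz <- which(Ss[i, ] != 0)
        if (length(nz) > 0 && (all(Ss[i, nz] > 0) || all(Ss[i, nz] < 0))) {
          fixed[nz] <- TRUE
        }
      }
      if (!any(fixed)) break
      active[which(active)[fixed]] <- FALSE
    }
    if (!all(active)) {
      v <- numeric(ncol(S))
      if (!any(active)) {
        return(list(status = "optimal", objective = 0, fluxes = v))
      }
      sub <- oracle_lp(S[, active, drop = FALSE], lb[active], ub[active],
                       obj[active], maximize)
      if (sub$status != "optimal") return(sub)
      v[active] <- sub$fluxes
      return(list(status = "optimal", objective = sub$objective, fluxes = v))
    }
  }
  if (all(b == 0)) {
    # homogeneous system: dependent rows are vacuous; reduce to a full-rank
    # row set (boot::simplex mishandles redundant equalities)
    q <- qr(t(S))
    keep_rows <- sort(q$pivot[seq_len(q$rank)])
    S <- S[keep_rows, , drop = FALSE]
    b <- b[keep_rows]
    if (nrow(S) == ncol(S)) {
      # unique solution v = 0 (bounds include 0 since lb <= 0 <= ub here)
      v <- numeric(ncol(S))
      return(list(status = "optimal", objective = 0, fluxes = v))
    }
  }
  neg <- b < 0
  A3 <- S
  A3[neg, ] <- -A3[neg, ]
  b3 <- abs(b)
  r <- tryCatch(
    boot::simplex(a = if (maximize) obj else -obj,
                  A1 = diag(n), b1 = ub - lb, A3 = A3, b3 = b3,
                  maxi = TRUE, eps = 1e-10),
    error = function(e) NULL)
  if (is.null(r) || r$solved != 1) {
    # boot::simplex errors out on degenerate systems; fall back to exhaustive
    # vertex enumeration (exact for these small test LPs)
    return(oracle_lp_brute(S, b, lb, ub, obj, maximize))
  }
  v <- lb + as.numeric(r$soln)
  list(status = "optimal", objective = sum(obj * v), fluxes = v)
}

# Exhaustive vertex enumeration for {S y = b, 0 <= y <= ub - lb} shifted back
# to v = lb + y. A vertex fixes n - rank(S) variables at a bound and solves
# the remaining square equality system. Exponential, but only used as a
# fallback on the tiny degenerate LPs boot::simplex cannot handle.
oracle_lp_brute <- function(S, b, lb, ub, obj, maximize = TRUE) {
  n <- ncol(S)
  rk <- qr(S)$rank
  k <- n - rk
  tol <- 1e-7
  best_obj <- NA_real_
  best_v <- NULL
  sets <- if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
  for (nb in sets) {
    basic <- setdiff(seq_len(n), nb)
    grid <- if (k == 0) matrix(0, nrow = 1, ncol = 0) else
      as.matrix(expand.grid(lapply(nb, function(j) c(lb[j], ub[j]))))
    for (gi in seq_len(nrow(grid))) {
      v <- numeric(n)
      if (k > 0) v[nb] <- grid[gi, ]
      rhs <- b - if (k > 0) as.numeric(S[, nb, drop = FALSE] %*% v[nb]) else 0
      sol <- tryCatch(qr.solve(S[, basic, drop = FALSE], rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v[basic] <- sol
      if (max(abs(as.numeric(S %*% v) - b)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      ob <- sum(obj * v)
      if (is.na(best_obj) ||
          (maximize && ob > best_obj) || (!maximize && ob < best_obj)) {
        best_obj <- ob
        best_v <- v
      }
    }
  }
  if (is.na(best_obj)) return(list(status = "infeasible", objective = NA_real_))
  list(status = "optimal", objective = best_obj, fluxes = best_v)
}

oracle_fva_mid <- function(model) {
  S <- as.matrix(stoich_matrix(model))
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  n <- ncol(S)
  lo <- hi <- numeric(n)
  for (j in seq_len(n)) {
    obj <- numeric(n)
    obj[j] <- 1
    lo[j] <- oracle_lp(S, lb, ub, obj, maximize = FALSE)$objective
    hi[j] <- oracle_lp(S, lb, ub, obj, maximize = TRUE)$objective
  }
  tol <- 1e-6
  lo[abs(lo) < tol] <- 0
  hi[abs(hi) < tol] <- 0
  mid <- (lo + hi) / 2
  mid[abs(mid) < tol] <- 0
  stats::setNames(mid, model$reactions$id)
}

# Independent GPR evaluation for the restricted grammar the random networks
# use: "", "G", "G1 or G2", "G1 and G2".
oracle_gpr_value <- function(gpr, ab) {
  if (!nzchar(gpr)) return(NA_real_)
  if (grepl(" or ", gpr, fixed = TRUE)) {
    return(sum(ab[strsplit(gpr, " or ", fixed = TRUE)[[1]]]))
  }
  if (grepl(" and ", gpr, fixed = TRUE)) {
    return(min(ab[strsplit(gpr, " and ", fixed = TRUE)[[1]]]))
  }
  unname(ab[gpr])
}

oracle_gpr_genes <- function(gpr) {
  if (!nzchar(gpr)) return(character(0))
  strsplit(gpr, " or | and ")[[1]]
}

# Reaction-removal knockout: physically drop the dead reactions, recompute
# FVA midpoints with boot::simplex, report ternary signs vs. the baseline.
oracle_ko_effects <- function(model, baseline_mid, dead_ids) {
  keep <- !(model$reactions$id %in% dead_ids)
  v <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  if (any(keep)) {
    sub <- model
    sub$reactions <- model$reactions[keep, , drop = FALSE]
    sub$gpr_trees <- model$gpr_trees[keep]
    v[sub$reactions$id] <- oracle_fva_mid(sub)
  }
  d <- v - baseline_mid[names(v)]
  eff <- integer(length(d))
  eff[d > 1e-6] <- 1L
  eff[d < -1e-6] <- -1L
  stats::setNames(eff, names(v))
}

oracle_gene_ko <- function(model, baseline_mid) {
  ab <- attr(model, "abundance")
  gprs <- model$reactions$gpr
  out <- matrix(0L, nrow = length(model$genes), ncol = nrow(model$reactions),
                dimnames = list(model$genes, model$reactions$id))
  for (g in model$genes) {
    ab2 <- ab
    ab2[g] <- 0
    dead <- model$reactions$id[vapply(gprs, function(x) {
      g %in% oracle_gpr_genes(x) && {
        val <- oracle_gpr_value(x, ab2)
        !is.na(val) && val <= 1e-12
      }
    }, logical(1))]
    if (length(dead) > 0) out[g, ] <- oracle_ko_effects(model, baseline_mid, dead)
  }
  out
}

oracle_metabolite_ko <- function(model, baseline_mid) {
  S <- as.matrix(stoich_matrix(model))
  mets <- model$metabolites$id
  out <- matrix(0L, nrow = length(mets), ncol = nrow(model$reactions),
                dimnames = list(mets, model$reactions$id))
  for (m in mets) {
    dead <- model$reactions$id[S[m, ] != 0]
    if (length(dead) > 0) out[m, ] <- oracle_ko_effects(model, baseline_mid, dead)
  }
  out
}
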