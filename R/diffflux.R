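# Pseudocount for log-ratios: scale-free fraction of the mean nonzero flux,
# so results do not depend on the (arbitrary) flux unit.
sfx_epsilon <- function(fluxes) {
  nz <- fluxes[fluxes > 0]
  if (length(nz) == 0) return(1e-6)
  1e-6 * mean(nz)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, the step-up false
#' discovery rate control used throughout the pipeline.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, order-preserving.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Case-control differential flux for one study
#'
#' Per reaction, the effect is the log2 ratio of (pseudocounted) group
#' means, `log2((mean_case + eps) / (mean_control + eps))`; the p-value
#' comes from a two-group linear model on `log2(flux + eps)` with
#' empirical-Bayes variance moderation (limma), or a plain unmoderated
#' t-test when `moderated = FALSE`. Reactions with zero flux everywhere get
#' effect 0 and p 1.
#'
#' @param fluxes reactions x samples numeric matrix.
#' @param groups factor/character per sample: `"proliferative"` (control)
#'   or `"senescent"` (case); or any two levels, the second level sorted
#'   alphabetically being the case unless a `senescent` level is present.
#' @param case name of the case level; default `"senescent"` if present.
#' @param moderated use limma empirical-Bayes moderation (default TRUE).
#' @param study_id label stored with the result.
#' @return a `diff_result` data.frame with columns `reaction_id`, `effect`
#'   (log2FC), `se`, `p`, `fdr`, `mean_case`, `mean_control`.
#' @export
case_control_diff <- function(fluxes, groups, case = NULL, moderated = TRUE,
                              study_id = "study") {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups are required")
  if (is.null(case)) case <- if ("senescent" %in% lev) "senescent" else lev[2]
  ctrl <- setdiff(lev, case)
  if (sum(groups == case) < 2 || sum(groups == ctrl) < 2) {
    stop("each group needs at least 2 samples")
  }
  eps <- sfx_epsilon(fluxes)
  mean_case <- rowMeans(fluxes[, groups == case, drop = FALSE])
  mean_ctrl <- rowMeans(fluxes[, groups == ctrl, drop = FALSE])
  effect <- log2((mean_case + eps) / (mean_ctrl + eps))

  y <- log2(fluxes + eps)
  design <- cbind(Intercept = 1, case = as.numeric(groups == case))
  constant <- apply(fluxes, 1, function(r) max(r) - min(r)) < SFX_FLUX_TOL

  fit <- limma::lmFit(y, design)
  if (moderated) {
    fit2 <- limma::eBayes(fit[!constant, ])
    p <- rep(1, nrow(fluxes))
    se <- rep(NA_real_, nrow(fluxes))
    p[!constant] <- fit2$p.value[, "case"]
    se[!constant] <- fit2$stdev.unscaled[, "case"] * sqrt(fit2$s2.post)
  } else {
    tt <- fit$coefficients[, "case"] / (fit$stdev.unscaled[, "case"] * fit$sigma)
    p <- 2 * pt(-abs(tt), df = fit$df.residual)
    se <- fit$stdev.unscaled[, "case"] * fit$sigma
    p[constant] <- 1
    se[constant] <- NA_real_
  }
  # fallback se for constant rows: effect is 0 there, give a unit se so
  # standardized effects are defined (and zero)
  se[is.na(se) | se < 1e-12] <- 1
  effect[constant] <- 0

  res <- data.frame(reaction_id = rownames(fluxes), effect = unname(effect),
                    se = unname(se), p = unname(p), fdr = bh_fdr(unname(p)),
                    mean_case = unname(mean_case),
                    mean_control = unname(mean_ctrl),
                    stringsAsFactors = FALSE)
  attr(res, "study_id") <- study_id
  attr(res, "type") <- "case_control"
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Time-series differential flux
#'
#' Ordinary least-squares fit of `flux ~ passage` per reaction; `effect` is
#' the slope (beta), with a two-sided t-test p-value. Downstream target
#' scoring uses `sign(beta)` where case-control analyses use
#' `sign(log2FC)`.
#'
#' @param fluxes reactions x samples matrix.
#' @param passages integer passage number per sample (>= 3 distinct values).
#' @param study_id label stored with the result.
#' @return a `diff_result` with `effect` = slope.
#' @export
timeseries_diff <- function(fluxes, passages, study_id = "timeseries") {
  passages <- as.numeric(passages)
  if (length(unique(passages)) < 3) {
    stop("time-series analysis needs at least 3 distinct passage values")
  }
  n <- length(passages)
  xc <- passages - mean(passages)
  sxx <- sum(xc^2)
  beta <- as.numeric(fluxes %*% xc) / sxx
  rss <- rowSums((fluxes - rowMeans(fluxes) - outer(beta, xc))^2)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  tt <- beta / se
  p <- 2 * pt(-abs(tt), df = df)
  constant <- apply(fluxes, 1, function(r) max(r) - min(r)) < SFX_FLUX_TOL
  p[constant | !is.finite(p)] <- 1
  beta[constant] <- 0
  se[is.na(se) | se < 1e-12] <- 1
  mean_case <- rowMeans(fluxes[, passages >= stats::median(passages), drop = FALSE])
  mean_ctrl <- rowMeans(fluxes[, passages < stats::median(passages), drop = FALSE])
  res <- data.frame(reaction_id = rownames(fluxes), effect = unname(beta),
                    se = unname(se), p = unname(p), fdr = bh_fdr(unname(p)),
                    mean_case = unname(mean_case),
                    mean_control = unname(mean_ctrl),
                    stringsAsFactors = FALSE)
  attr(res, "study_id") <- study_id
  attr(res, "type") <- "timeseries"
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Spearman correlation of a per-sample quantity with a covariate
#'
#' Rank correlation (average ranks on ties) with the p-value from
#' `stats::cor.test`, used e.g. for biomass-versus-passage trajectories.
#'
#' @param values numeric per-sample values (n >= 4).
#' @param covariate numeric per-sample covariate.
#' @return list with `rho` and `p`.
#' @export
spearman_trajectory <- function(values, covariate) {
  if (length(values) < 4) stop("need at least 4 samples")
  ct <- suppressWarnings(cor.test(values, covariate, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
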