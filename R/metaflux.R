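#' Fixed-effects inverse-variance combination
#'
#' Combines per-study effects `d_i` with variances `var_i` using weights
#' `w_i = 1/var_i`: the pooled effect is `dbar = sum(w d) / sum(w)` and the
#' combined statistic `Z = dbar * sqrt(sum(w))`, referred to a standard
#' normal (two-sided).
#'
#' @param effects numeric per-study effects (>= 1; >= 2 for a true
#'   meta-analysis, a single study degenerates to a one-sample z).
#' @param variances positive per-study variances.
#' @return list with `dbar`, `Z`, `p`.
#' @export
fem_combine <- function(effects, variances) {
  if (length(effects) != length(variances)) {
    stop("effects and variances must have equal length")
  }
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    stop("variances must be positive and finite")
  }
  w <- 1 / variances
  dbar <- sum(w * effects) / sum(w)
  Z <- dbar * sqrt(sum(w))
  list(dbar = dbar, Z = Z, p = 2 * pnorm(-abs(Z)))
}

#' Fixed-effects meta-analysis of differential flux results
#'
#' Per reaction, each study contributes the standardized effect
#' `d_i = effect_i / se_i` (unit variance), and the studies are combined by
#' [fem_combine()]. The meta log2FC is the arithmetic mean of the per-study
#' effects. Reactions present in fewer than `min_studies` studies are
#' classified `ns` and flagged. Directions: `up` if `fdr < fdr_thresh` and
#' `Z > 0`, `down` if `fdr < fdr_thresh` and `Z < 0`, else `ns`.
#'
#' @param diffresults list of `diff_result` objects (one per study).
#' @param fdr_thresh significance threshold on the BH FDR (default 0.05).
#' @param min_studies minimum studies per reaction (default 2).
#' @return a `meta_result` data.frame: `reaction_id`, `meta_log2fc`, `z`,
#'   `p`, `fdr`, `n_studies`, `direction`.
#' @export
meta_table <- function(diffresults, fdr_thresh = 0.05, min_studies = 2) {
  if (length(diffresults) < 2) stop("need at least 2 studies")
  ids <- sort(unique(unlist(lapply(diffresults, `[[`, "reaction_id"))))
  eff <- vapply(diffresults, function(d) {
    d$effect[match(ids, d$reaction_id)]
  }, numeric(length(ids)))
  ses <- vapply(diffresults, function(d) {
    d$se[match(ids, d$reaction_id)]
  }, numeric(length(ids)))
  if (length(ids) == 1) { eff <- matrix(eff, nrow = 1); ses <- matrix(ses, nrow = 1) }

  n_studies <- rowSums(!is.na(eff))
  meta_lfc <- rowMeans(eff, na.rm = TRUE)
  z <- p <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    ok <- !is.na(eff[k, ]) & !is.na(ses[k, ]) & ses[k, ] > 0
    if (sum(ok) < min_studies) next
    d <- eff[k, ok] / ses[k, ok]
    fc <- fem_combine(d, rep(1, sum(ok)))
    z[k] <- fc$Z
    p[k] <- fc$p
  }
  fdr <- rep(NA_real_, length(ids))
  fdr[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  direction <- rep("ns", length(ids))
  direction[!is.na(fdr) & fdr < fdr_thresh & z > 0] <- "up"
  direction[!is.na(fdr) & fdr < fdr_thresh & z < 0] <- "down"
  res <- data.frame(reaction_id = ids, meta_log2fc = meta_lfc, z = z, p = p,
                    fdr = fdr, n_studies = n_studies, direction = direction,
                    stringsAsFactors = FALSE)
  class(res) <- c("meta_result", "data.frame")
  res
}
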