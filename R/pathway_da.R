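#' Differential-abundance (DA) score per subsystem
#'
#' For each pathway (subsystem) i the DA score is
#' `(n_up_i - n_down_i) / n_total_i`, where `n_up_i`/`n_down_i` count the
#' significantly up-/down-regulated reactions in the subsystem and
#' `n_total_i` is the subsystem size. Ranges over `[-1, 1]`: +1 means every
#' reaction in the pathway is significantly up, -1 every reaction down.
#'
#' @param sig_up character vector of significantly up-regulated reaction ids.
#' @param sig_down character vector of significantly down-regulated ids
#'   (disjoint from `sig_up`).
#' @param subsystems named character vector: reaction id -> subsystem label
#'   (the reaction universe).
#' @param min_size subsystems smaller than this get `p = NA` downstream
#'   (default 3); their score is still reported.
#' @return a `pathway_da` data.frame: `subsystem`, `da`, `n_up`, `n_down`,
#'   `n_total`, `p`, `fdr` (p/fdr `NA` until [da_significance()]).
#' @export
da_score <- function(sig_up, sig_down, subsystems, min_size = 3) {
  if (length(intersect(sig_up, sig_down)) > 0) {
    stop("sig_up and sig_down must be disjoint")
  }
  bad <- setdiff(c(sig_up, sig_down), names(subsystems))
  if (length(bad) > 0) {
    stop("significant reactions outside the universe: ",
         paste(bad, collapse = ", "))
  }
  labs <- sort(unique(unname(subsystems)))
  n_total <- as.vector(table(factor(subsystems, levels = labs)))
  n_up <- as.vector(table(factor(subsystems[sig_up], levels = labs)))
  n_down <- as.vector(table(factor(subsystems[sig_down], levels = labs)))
  res <- data.frame(subsystem = labs,
                    da = (n_up - n_down) / n_total,
                    n_up = n_up, n_down = n_down, n_total = n_total,
                    p = NA_real_, fdr = NA_real_,
                    stringsAsFactors = FALSE)
  attr(res, "min_size") <- min_size
  class(res) <- c("pathway_da", "data.frame")
  res
}

#' Bootstrap-without-replacement significance for DA scores
#'
#' Conditions on the observed totals of significant reactions: each of `B`
#' iterations draws `n_up_total + n_down_total` reactions without
#' replacement from the universe, randomly splits them into "up"
#' (`n_up_total`) and "down" (`n_down_total`), and recomputes the DA score
#' of every subsystem. Two-sided p-values use the plus-one rule
#' `p = (1 + #\{|DA_boot| >= |DA_obs|\}) / (B + 1)`, so the smallest
#' attainable p is `1/(B+1)`. Subsystems below `min_size` keep `p = NA`.
#'
#' @param result a `pathway_da` from [da_score()].
#' @param subsystems the same reaction universe used for the scores.
#' @param n_up_total,n_down_total observed significant counts; defaults are
#'   taken from `result`.
#' @param B bootstrap iterations (>= 100; default 1000).
#' @param seed integer seed for reproducibility.
#' @return the `pathway_da` with `p` and `fdr` filled in.
#' @export
da_significance <- function(result, subsystems, n_up_total = sum(result$n_up),
                            n_down_total = sum(result$n_down), B = 1000,
                            seed = 1L) {
  if (B < 100) stop("B must be at least 100")
  n_sig <- n_up_total + n_down_total
  if (n_sig > length(subsystems)) {
    stop("more significant reactions than reactions in the universe")
  }
  min_size <- attr(result, "min_size") %||% 3
  labs <- result$subsystem
  sub_f <- factor(unname(subsystems), levels = labs)
  nlab <- length(labs)
  n_total <- result$n_total

  exceed <- integer(nlab)
  obs <- abs(result$da)
  if (n_sig > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    })
    for (b in seq_len(B)) {
      draw <- sample.int(length(subsystems), n_sig)
      up <- draw[seq_len(n_up_total)]
      down <- if (n_down_total > 0) draw[(n_up_total + 1):n_sig] else integer(0)
      cu <- tabulate(sub_f[up], nbins = nlab)
      cd <- tabulate(sub_f[down], nbins = nlab)
      dab <- (cu - cd) / n_total
      exceed <- exceed + (abs(dab) >= obs - 1e-12)
    }
    p <- (1 + exceed) / (B + 1)
  } else {
    p <- rep(1, nlab)
  }
  p[n_total < min_size] <- NA_real_
  result$p <- p
  result$fdr <- NA_real_
  ok <- !is.na(p)
  result$fdr[ok] <- bh_fdr(p[ok])
  result
}

#' Meta-level pathway DA analysis
#'
#' Applies [da_score()] and [da_significance()] to the significant up/down
#' reaction sets of a fixed-effects meta-analysis result.
#'
#' @param meta a `meta_result` from [meta_table()].
#' @param subsystems named character vector: reaction id -> subsystem.
#' @param B,seed,min_size passed through to the DA routines.
#' @return a `pathway_da` with p and fdr filled.
#' @export
meta_da <- function(meta, subsystems, B = 1000, seed = 1L, min_size = 3) {
  up <- meta$reaction_id[meta$direction == "up"]
  down <- meta$reaction_id[meta$direction == "down"]
  up <- intersect(up, names(subsystems))
  down <- intersect(down, names(subsystems))
  res <- da_score(up, down, subsystems, min_size = min_size)
  da_significance(res, subsystems, B = B, seed = seed)
}

#' Significant reaction sets from one study's differential result
#'
#' Helper selecting up/down reactions at `p < p_thresh` and
#' `|effect| > lfc_thresh` (the same gate the effective scores use).
#' @param diff a `diff_result`.
#' @param p_thresh raw p-value threshold (default 0.05).
#' @param lfc_thresh absolute effect threshold (default 0.5).
#' @return list with `up` and `down` character vectors.
#' @export
significant_sets <- function(diff, p_thresh = 0.05, lfc_thresh = 0.5) {
  sig <- diff$p < p_thresh & abs(diff$effect) > lfc_thresh
  list(up = diff$reaction_id[sig & diff$effect > 0],
       down = diff$reaction_id[sig & diff$effect < 0])
}
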