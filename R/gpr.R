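#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with `and`/`or`
#' operators (case-insensitive) and parentheses, e.g.
#' `"(HK1 and HK2) or GCK"`. `and` models enzyme complexes (all subunits
#' required), `or` models isozymes (either enzyme suffices).
#'
#' @param gpr a single GPR string; `""` or `NA` denotes "no rule".
#' @return a parse tree: a gene id (character scalar), or a list with
#'   elements `op` (`"and"`/`"or"`) and `args` (list of subtrees); `NULL`
#'   for an empty rule.
#' @export
parse_gpr <- function(gpr) {
  if (is.null(gpr) || length(gpr) == 0 || is.na(gpr) || !nzchar(trimws(gpr))) {
    return(NULL)
  }
  toks <- gpr_tokens(gpr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule '", gpr, "': unexpected token '",
         st$toks[st$pos], "'", call. = FALSE)
  }
  tree
}

gpr_tokens <- function(gpr) {
  s <- gsub("([()])", " \\1 ", gpr)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("malformed GPR rule: unexpected end of input", call. = FALSE)
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("malformed GPR rule: missing ')'", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("malformed GPR rule: unexpected token '", tok, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tok
}

#' Genes referenced by a GPR parse tree
#' @param tree output of [parse_gpr()].
#' @return character vector of gene ids (possibly empty).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR rule against gene abundances
#'
#' `and` nodes return the minimum of their children (complex limited by the
#' scarcest subunit); `or` nodes return the sum (isozyme abundances add).
#' Genes missing from `abundance` contribute 0 with a warning, so a reaction
#' whose only enzyme is undetected becomes capacity-blocked rather than
#' raising an error. An empty rule returns `NA`, the "unconstrained"
#' sentinel: no enzyme-capacity bound applies.
#'
#' @param gpr a GPR string or a tree from [parse_gpr()].
#' @param abundance named numeric vector of nonnegative gene abundances.
#' @return nonnegative numeric scalar, or `NA_real_` for an empty rule.
#' @export
evaluate_gpr <- function(gpr, abundance) {
  tree <- if (is.character(gpr) && length(gpr) == 1L) parse_gpr(gpr) else gpr
  if (is.null(tree)) return(NA_real_)
  missing <- setdiff(gpr_genes(tree), names(abundance))
  if (length(missing) > 0) {
    warning("genes absent from abundance profile treated as 0: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  gpr_eval_tree(tree, abundance)
}

gpr_eval_tree <- function(tree, abundance) {
  if (is.character(tree)) {
    v <- abundance[tree]
    if (is.na(v)) return(0)
    return(unname(v))
  }
  vals <- vapply(tree$args, gpr_eval_tree, numeric(1), abundance = abundance)
  if (tree$op == "and") min(vals) else sum(vals)
}
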