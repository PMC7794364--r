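#' Genes referenced by a gene-protein-reaction rule
#'
#' Rules are infix boolean expressions over bare gene symbols with `and`,
#' `or` and parentheses; `and` encodes complex subunits (all required), `or`
#' encodes isozymes (any suffices).
#'
#' @param gpr Rule string; `""` means no gene association.
#' @return Character vector of gene symbols (may be empty).
#' @export
gpr_genes <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character())
  toks <- gpr_tokens(gpr)
  unique(toks[!toks %in% c("and", "or", "(", ")")])
}

gpr_tokens <- function(gpr) {
  toks <- regmatches(gpr, gregexpr("[A-Za-z0-9_.:-]+|\\(|\\)", gpr))[[1]]
  bad <- grepl("^(AND|OR)$", toks)
  toks[bad] <- tolower(toks[bad])
  toks
}

#' Evaluate a GPR rule under a set of inactivated genes
#'
#' A reaction is impaired when its rule evaluates to `FALSE` once every gene
#' in `inactive_genes` is set `FALSE` and all other genes `TRUE`. An empty
#' rule always evaluates `TRUE` (no gene association, never impaired).
#'
#' @param gpr Rule string.
#' @param inactive_genes Character vector of genes considered non-functional.
#' @return Logical scalar: is the reaction still active?
#' @export
gpr_active <- function(gpr, inactive_genes = character()) {
  genes <- gpr_genes(gpr)
  if (length(genes) == 0) return(TRUE)
  toks <- gpr_tokens(gpr)
  mapped <- vapply(toks, function(tk) {
    if (tk == "and") "&" else if (tk == "or") "|"
    else if (tk %in% c("(", ")")) tk
    else if (tk %in% inactive_genes) "FALSE" else "TRUE"
  }, character(1))
  expr_text <- paste(mapped, collapse = " ")
  ok <- tryCatch(eval(parse(text = expr_text)[[1]], envir = baseenv()),
                 error = function(e) abort(sprintf("cannot parse GPR rule '%s'", gpr)))
  isTRUE(ok)
}
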