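#' Gene-reaction rule parsing and evaluation
#'
#' Gene-reaction rules are boolean expressions over gene identifiers with
#' \code{and} (enzyme complex: all subunits required) and \code{or}
#' (isoenzymes: any one suffices) connectives and parentheses, e.g.
#' \code{"(PYC1 or PYC2)"}. An empty rule means no gene association.
#' \code{parseGeneRule} returns an AST (nested lists); \code{evalGeneRule}
#' evaluates it with the listed genes deleted (absent) and all other genes
#' present. Evaluation is deterministic for any gene set.
#'
#' @param rule character rule string ('and'/'or', case-insensitive)
#' @param ast parsed rule as returned by \code{parseGeneRule}
#' @param deletedGenes character vector of deleted gene ids; genes not in the
#'   model simply never match
#' @return \code{parseGeneRule}: an AST, or \code{NULL} for an empty rule;
#'   \code{evalGeneRule}: logical, is the reaction still active;
#'   \code{ruleGenes}: character vector of genes referenced
#' @examples
#' evalGeneRule(parseGeneRule("PYC1 or PYC2"), "PYC1")   # TRUE: isoenzyme left
#' evalGeneRule(parseGeneRule("A and B"), "A")           # FALSE: complex broken
#' @export
parseGeneRule <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- .tokenizeRule(rule)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  ast <- .parseOr(st)
  if (st$pos <= length(st$tokens))
    stop("malformed gene rule: unexpected token '",
         st$tokens[st$pos], "' in \"", rule, "\"")
  ast
}

.tokenizeRule <- function(rule) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, rule)[[1]]
  if (m[1] == -1) stop("malformed gene rule: \"", rule, "\"")
  substring(rule, m, m + attr(m, "match.length") - 1L)
}

.peek <- function(st) if (st$pos <= length(st$tokens)) st$tokens[st$pos] else NA_character_

.parseOr <- function(st) {
  args <- list(.parseAnd(st))
  while (!is.na(.peek(st)) && tolower(.peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.parseAnd(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "or", args = args)
}

.parseAnd <- function(st) {
  args <- list(.parseAtom(st))
  while (!is.na(.peek(st)) && tolower(.peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.parseAtom(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "and", args = args)
}

.parseAtom <- function(st) {
  tok <- .peek(st)
  if (is.na(tok)) stop("malformed gene rule: unexpected end of expression")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- .parseOr(st)
    if (!identical(.peek(st), ")")) stop("malformed gene rule: missing ')'")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or"))
    stop("malformed gene rule: unexpected token '", tok, "'")
  st$pos <- st$pos + 1L
  list(gene = tok)
}

#' @rdname parseGeneRule
#' @export
evalGeneRule <- function(ast, deletedGenes = character()) {
  if (is.null(ast)) return(TRUE)  # no gene association: never disabled
  if (!is.null(ast$gene)) return(!(ast$gene %in% deletedGenes))
  vals <- vapply(ast$args, evalGeneRule, logical(1),
                 deletedGenes = deletedGenes)
  if (identical(ast$op, "and")) all(vals) else any(vals)
}

#' @rdname parseGeneRule
#' @export
ruleGenes <- function(ast) {
  if (is.null(ast)) return(character())
  if (!is.null(ast$gene)) return(ast$gene)
  unique(unlist(lapply(ast$args, ruleGenes)))
}

#' Map gene deletions to disabled reactions
#'
#' Returns exactly the reactions whose gene rule evaluates to false when every
#' listed gene is deleted and all others are present. Reactions with an empty
#' rule are never returned: without a gene association there is nothing to
#' delete. Deleting a single member of an isoenzyme pair (an \code{or} rule)
#' leaves the reaction active.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param deletedGenes character vector of gene ids (unknown genes are
#'   silently inert)
#' @return character vector of disabled reaction ids
#' @seealso [applyKnockouts()], [knockoutGenes()]
#' @export
reactionsDisabledByGenes <- function(model, deletedGenes) {
  rules <- model@reactions$geneRule
  hit <- vapply(rules, function(r) {
    if (!nzchar(r)) return(FALSE)
    !evalGeneRule(parseGeneRule(r), deletedGenes)
  }, logical(1))
  model@reactions$id[hit]
}

#' Apply reaction knockouts
#'
#' Returns a copy of the model in which the listed reactions have both flux
#' bounds set to zero; everything else is unchanged. Idempotent; the input
#' model is never modified.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param reactionIds character vector of reaction ids to delete (may be
#'   empty)
#' @return the knocked-out model
#' @examples
#' m <- makeChainModel(2)
#' ko <- applyKnockouts(m, "R1")
#' lowerBounds(ko)[["R1"]]  # 0
#' @export
applyKnockouts <- function(model, reactionIds) {
  reactionIds <- unique(as.character(reactionIds))
  if (!length(reactionIds)) return(model)
  unknown <- setdiff(reactionIds, model@reactions$id)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  .setBoundsFast(model, reactionIds, lb = 0, ub = 0)
}

#' Apply gene-level knockouts
#'
#' Convenience wrapper mapping gene deletions through
#' [reactionsDisabledByGenes()] and then applying the resulting reaction
#' knockouts.
#'
#' @inheritParams reactionsDisabledByGenes
#' @return the knocked-out model
#' @export
knockoutGenes <- function(model, deletedGenes) {
  applyKnockouts(model, reactionsDisabledByGenes(model, deletedGenes))
}
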