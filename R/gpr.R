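# Gene-protein-reaction rules: parse / evaluate / print.
#
# Grammar: infix "and" / "or" with parentheses, case-insensitive keywords,
# "&&", "&", "||", "|" accepted as synonyms; genes are whitespace-delimited
# tokens.  Expressions are stored as nested lists:
#   leaf:     list(op = "gene", gene = "g1")
#   internal: list(op = "and" | "or", args = list(...))

#' Parse a GPR string into a boolean expression tree
#'
#' @param text rule such as \code{"(g1 and g2) or g3"}; \code{""} or
#'   \code{NA} yields \code{NULL} (no rule).
#' @return nested-list expression tree, or \code{NULL}.
#' @examples
#' tree <- parseGpr("(g1 and g2) or g3")
#' gprEval(tree, c("g3"))
#' @export
parseGpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) ||
      !nzchar(trimws(text))) return(NULL)
  toks <- gprTokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  expr <- gprParseOr(st)
  if (st$pos <= length(st$toks))
    stop("malformed GPR near '", st$toks[st$pos], "' in: ", text)
  expr
}

gprTokenize <- function(text) {
  text <- gsub("\\(", " ( ", text)
  text <- gsub("\\)", " ) ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  low <- tolower(toks)
  toks[low %in% c("and", "&", "&&")] <- "and"
  toks[low %in% c("or", "|", "||")] <- "or"
  toks
}

gprPeek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else ""
gprTake <- function(st) { t <- gprPeek(st); st$pos <- st$pos + 1L; t }

gprParseOr <- function(st) {
  args <- list(gprParseAnd(st))
  while (gprPeek(st) == "or") { gprTake(st); args <- c(args, list(gprParseAnd(st))) }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gprParseAnd <- function(st) {
  args <- list(gprParseAtom(st))
  while (gprPeek(st) == "and") { gprTake(st); args <- c(args, list(gprParseAtom(st))) }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gprParseAtom <- function(st) {
  t <- gprTake(st)
  if (t == "(") {
    e <- gprParseOr(st)
    if (gprTake(st) != ")") stop("unbalanced parentheses in GPR")
    return(e)
  }
  if (t %in% c("", ")", "and", "or")) stop("malformed GPR: unexpected '", t, "'")
  list(op = "gene", gene = t)
}

#' Genes referenced by a GPR expression tree
#' @param expr tree from \code{\link{parseGpr}} (or \code{NULL}).
#' @return character vector (possibly empty).
#' @export
gprGenes <- function(expr) {
  if (is.null(expr)) return(character(0))
  if (expr$op == "gene") return(expr$gene)
  unique(unlist(lapply(expr$args, gprGenes), use.names = FALSE))
}

#' Evaluate a GPR expression under a gene-presence assignment
#' @param expr tree from \code{\link{parseGpr}}.
#' @param present character vector of genes considered present.
#' @return logical; \code{NULL} rules evaluate to \code{TRUE} (a reaction
#'   without a rule is never gene-disabled).
#' @export
gprEval <- function(expr, present) {
  if (is.null(expr)) return(TRUE)
  switch(expr$op,
    gene = expr$gene %in% present,
    and  = all(vapply(expr$args, gprEval, logical(1), present = present)),
    or   = any(vapply(expr$args, gprEval, logical(1), present = present)),
    stop("unknown GPR node type: ", expr$op))
}

#' Render a GPR expression tree back to rule text
#' @param expr tree from \code{\link{parseGpr}}.
#' @return character scalar ("" for \code{NULL}).
#' @export
gprToString <- function(expr) {
  if (is.null(expr)) return("")
  if (expr$op == "gene") return(expr$gene)
  parts <- vapply(expr$args, function(a) {
    s <- gprToString(a)
    if (a$op %in% c("and", "or") && a$op != expr$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", expr$op, " "))
}
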