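#' Construct a MetabolicNetwork
#'
#' @param S stoichiometric matrix (metabolites x reactions); dense or sparse.
#' @param metabolites,reactions identifiers; taken from \code{dimnames(S)}
#'   when omitted.
#' @param lb,ub flux bounds per reaction.  When \code{NULL}, conventional
#'   defaults are applied: reversible reactions get -1000..1000 and
#'   irreversible ones 0..1000, driven by \code{reversible}.
#' @param reversible logical per reaction, only consulted when bounds are
#'   omitted (default: all reversible).
#' @param gpr named list (reaction id -> rule) of GPR strings or parsed
#'   trees; empty strings are dropped.
#' @param compartments named character metabolite id -> compartment tag;
#'   unspecified metabolites default to \code{"c"}.
#' @return validated \code{\linkS4class{MetabolicNetwork}}.
#' @examples
#' S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("in_A", "out_A")))
#' net <- metabolicNetwork(S, lb = c(0, 0), ub = c(10, 10))
#' reactionIds(net)
#' @export
metabolicNetwork <- function(S, metabolites = rownames(S),
                             reactions = colnames(S),
                             lb = NULL, ub = NULL, reversible = NULL,
                             gpr = list(), compartments = NULL) {
  S <- Matrix::Matrix(as.matrix(S), sparse = TRUE)
  dimnames(S) <- list(metabolites, reactions)
  n <- ncol(S)
  if (is.null(lb) || is.null(ub)) {
    if (is.null(reversible)) reversible <- rep(TRUE, n)
    lb <- ifelse(reversible, -1000, 0)
    ub <- rep(1000, n)
  }
  gpr <- gpr[vapply(gpr, function(g)
    !is.null(g) && (!is.character(g) || nzchar(trimws(g))), logical(1))]
  gpr <- lapply(gpr, function(g) if (is.character(g)) parseGpr(g) else g)
  genes <- sort(unique(unlist(lapply(gpr, gprGenes), use.names = FALSE)))
  if (is.null(compartments)) compartments <- character(0)
  miss <- setdiff(metabolites, names(compartments))
  compartments[miss] <- "c"
  new("MetabolicNetwork", S = S, lb = as.numeric(lb), ub = as.numeric(ub),
      gpr = gpr, genes = as.character(genes),
      compartments = compartments[metabolites])
}

#' @rdname metabolicNetwork
#' @param net a \code{MetabolicNetwork}.
#' @export
reactionIds <- function(net) colnames(net@S)

#' @rdname metabolicNetwork
#' @export
metaboliteIds <- function(net) rownames(net@S)

#' @rdname metabolicNetwork
#' @export
stoichMatrix <- function(net) net@S

#' @rdname metabolicNetwork
#' @export
lowerBounds <- function(net) stats::setNames(net@lb, reactionIds(net))

#' @rdname metabolicNetwork
#' @export
upperBounds <- function(net) stats::setNames(net@ub, reactionIds(net))

#' @rdname metabolicNetwork
#' @export
geneIds <- function(net) net@genes

#' @rdname metabolicNetwork
#' @export
gprRules <- function(net) net@gpr

#' Reactions irreversible in the stated forward direction
#'
#' A reaction belongs to the irreversible set exactly when its lower bound is
#' zero and its upper bound positive.
#' @param net a \code{MetabolicNetwork}.
#' @return character vector of reaction identifiers.
#' @export
irreversibleReactions <- function(net)
  reactionIds(net)[net@lb == 0 & net@ub > 0]

#' Reactions whose GPR mentions a gene
#'
#' Association is syntactic: a reaction is associated with a gene when the
#' gene appears anywhere in its rule, including inside an OR alternative.
#' @param net a \code{MetabolicNetwork}.
#' @param gene gene identifier.
#' @return character vector of reaction identifiers.
#' @export
reactionsOfGene <- function(net, gene) {
  hit <- vapply(net@gpr, function(g) gene %in% gprGenes(g), logical(1))
  names(net@gpr)[hit]
}

setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork:", ncol(object@S), "reactions,",
      nrow(object@S), "metabolites,", length(object@genes), "genes\n")
  cat("  irreversible:", length(irreversibleReactions(object)),
      " with GPR:", length(object@gpr), "\n")
})

setMethod("show", "UniversalSet", function(object) {
  cat("UniversalSet (", object@mode, "): ", ncol(object@U),
      " candidates over ", nrow(object@U), " metabolites\n", sep = "")
})

setMethod("show", "CouplingTable", function(object) {
  cat("CouplingTable:", nrow(object@pairs), "pairs,",
      length(object@blocked), "blocked reactions\n")
  print(table(object@pairs$relation))
})

setMethod("show", "InconsistencyInstance", function(object) {
  cat("InconsistencyInstance: |L| =", nrow(object@L),
      " |H| =", nrow(object@H),
      sprintf(" (thresholds %.2f / %.2f)\n", object@low, object@high))
})

setMethod("show", "GapFillSolution", function(object) {
  cat("GapFillSolution (", object@mode, "): Z* = ", object@ZStar,
      ", N* = ", object@NStar, "\n", sep = "")
  if (any(object@b > 0.5))
    cat("  added:", paste(names(object@b)[object@b > 0.5], collapse = ", "), "\n")
  if (any(object@h > 0.5))
    cat("  made reversible:",
        paste(names(object@h)[object@h > 0.5], collapse = ", "), "\n")
})

# internal: append columns to a network, preserving existing reactions
appendReactions <- function(net, ids, cols, lb, ub, newMets = character(0)) {
  S <- net@S
  if (length(newMets)) {
    extra <- Matrix::Matrix(0, length(newMets), ncol(S), sparse = TRUE,
                            dimnames = list(newMets, colnames(S)))
    S <- rbind(S, extra)
  }
  mets <- rownames(S)
  newcols <- Matrix::Matrix(0, length(mets), length(ids), sparse = TRUE,
                            dimnames = list(mets, ids))
  for (k in seq_along(ids)) {
    col <- cols[[k]]
    newcols[names(col), k] <- col
  }
  comp <- net@compartments
  comp[newMets] <- "c"
  metabolicNetwork(cbind(S, newcols), lb = c(net@lb, lb), ub = c(net@ub, ub),
                   gpr = net@gpr, compartments = comp)
}

# internal: exchange-style reactions touching a metabolite (single nonzero
# stoichiometric coefficient, on that metabolite)
boundaryReactionsOf <- function(net, met) {
  S <- net@S
  nz <- Matrix::colSums(S != 0)
  single <- which(nz == 1)
  single <- single[as.vector(S[met, single]) != 0]
  colnames(S)[single]
}

# internal: can the metabolite leave the system through an existing
# exchange-style reaction?
canExportMetabolite <- function(net, met) {
  for (r in boundaryReactionsOf(net, met)) {
    j <- match(r, colnames(net@S))
    coef <- net@S[met, j]
    if ((coef < 0 && net@ub[j] > 0) || (coef > 0 && net@lb[j] < 0))
      return(TRUE)
  }
  FALSE
}
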