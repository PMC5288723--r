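#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' MetabolicNetwork: a constraint-based metabolic model
#'
#' Holds the stoichiometric matrix (rows = metabolites, columns = reactions),
#' flux bounds, gene-protein-reaction (GPR) rules as boolean expression trees,
#' and compartment tags.  A reaction is irreversible when its lower bound is
#' exactly zero and its upper bound positive; the irreversible set is derived,
#' never stored.
#'
#' @slot S sparse stoichiometric matrix (\code{Matrix}), dimnames set to
#'   metabolite and reaction identifiers.
#' @slot lb,ub numeric flux bounds per reaction (arbitrary flux units).
#' @slot gpr named list of GPR expression trees (see \code{\link{parseGpr}});
#'   reactions without a rule are absent from the list.
#' @slot genes character vector of all genes referenced by any GPR.
#' @slot compartments named character, metabolite id -> compartment tag
#'   (convention: \code{"e"} marks extracellular).
#' @export
setClass("MetabolicNetwork",
  representation(S = "Matrix", lb = "numeric", ub = "numeric",
                 gpr = "list", genes = "character",
                 compartments = "character"))

setValidity("MetabolicNetwork", function(object) {
  msg <- character(0)
  S <- object@S
  rxns <- colnames(S); mets <- rownames(S)
  if (is.null(rxns) || is.null(mets))
    msg <- c(msg, "S must carry metabolite and reaction identifiers as dimnames")
  if (anyDuplicated(rxns)) msg <- c(msg, "duplicated reaction identifiers")
  if (anyDuplicated(mets)) msg <- c(msg, "duplicated metabolite identifiers")
  if (length(object@lb) != ncol(S) || length(object@ub) != ncol(S))
    msg <- c(msg, "bounds must have one entry per reaction")
  else if (any(object@lb > object@ub))
    msg <- c(msg, "lower bound exceeds upper bound for some reaction")
  if (length(object@gpr) && !all(names(object@gpr) %in% rxns))
    msg <- c(msg, "GPR rule attached to unknown reaction")
  gpr_genes <- unique(unlist(lapply(object@gpr, gprGenes), use.names = FALSE))
  if (!setequal(gpr_genes, object@genes))
    msg <- c(msg, "gene list must equal the set of genes appearing in GPRs")
  if (length(object@compartments) &&
      !all(names(object@compartments) %in% mets))
    msg <- c(msg, "compartment tag for unknown metabolite")
  if (length(msg)) msg else TRUE
})

#' UniversalSet: candidate reactions for gap filling
#'
#' Columns of \code{U} are candidate reactions over the union of model
#' metabolites and candidate-only metabolites.  Reversible source reactions
#' are split into two irreversible forward columns (suffixes \code{__f} /
#' \code{__r}) so candidate fluxes can be kept nonnegative; \code{sourceId}
#' records the originating identifier so reports can collapse the pair.
#'
#' @slot U sparse candidate stoichiometric matrix, rows named by metabolite,
#'   columns by candidate identifier.
#' @slot sourceId character, per-candidate source reaction id.
#' @slot sourceReversible logical, whether the source reaction was reversible.
#' @slot mode \code{"kegg"} (database reactions) or \code{"exchange"}
#'   (single-metabolite boundary reactions).
#' @export
setClass("UniversalSet",
  representation(U = "Matrix", sourceId = "character",
                 sourceReversible = "logical", mode = "character"))

setValidity("UniversalSet", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("kegg", "exchange"))
    msg <- c(msg, "mode must be 'kegg' or 'exchange'")
  if (anyDuplicated(colnames(object@U)))
    msg <- c(msg, "duplicated candidate identifiers")
  if (length(object@sourceId) != ncol(object@U) ||
      length(object@sourceReversible) != ncol(object@U))
    msg <- c(msg, "per-candidate metadata length mismatch")
  if (object@mode == "exchange" && ncol(object@U) > 0) {
    nz <- Matrix::colSums(object@U != 0)
    if (any(nz != 1))
      msg <- c(msg, "exchange candidates must touch exactly one metabolite")
  }
  if (length(msg)) msg else TRUE
})

#' CouplingTable: pairwise flux coupling classification
#'
#' @slot blocked identifiers of reactions unable to carry flux.
#' @slot pairs data.frame with columns \code{i}, \code{j} (identifiers,
#'   \code{i < j} lexicographically), \code{relation} (one of \code{fully},
#'   \code{directional_i_to_j}, \code{directional_j_to_i}, \code{partial},
#'   \code{uncoupled}) and \code{ratio} (v_i / v_j for fully coupled pairs,
#'   \code{NA} otherwise).  \code{directional_i_to_j} means zero flux through
#'   \code{i} forces zero flux through \code{j}.
#' @export
setClass("CouplingTable",
  representation(blocked = "character", pairs = "data.frame"))

#' GeneCouplingGraph: gene-level coupling through single-gene deletions
#'
#' @slot coupled data.frame (\code{g1}, \code{g2}): deleting \code{g1}
#'   inactivates every unblocked reaction associated with \code{g2}
#'   ("\code{g2} is coupled to \code{g1}").
#' @slot fullyCoupled data.frame of unordered mutually coupled pairs
#'   (\code{g1 < g2}).
#' @export
setClass("GeneCouplingGraph",
  representation(coupled = "data.frame", fullyCoupled = "data.frame"))

#' CorrelationTable: pairwise gene co-expression
#'
#' @slot r data.frame (\code{gene_a}, \code{gene_b}, \code{r}) with Pearson
#'   correlations in [-1, 1]; undefined pairs (zero variance, too few shared
#'   conditions) carry \code{NA}.
#' @export
setClass("CorrelationTable", representation(r = "data.frame"))

#' InconsistencyInstance: the sets L and H fed to the repair program
#'
#' \code{L} holds fully coupled reaction pairs whose linked genes show low
#' absolute co-expression (the inconsistencies to resolve), \code{H} those
#' with high absolute co-expression (couplings to preserve).  \code{ratio}
#' is the full-coupling flux ratio of the pair.  Pairs reachable from gene
#' pairs with conflicting labels are excluded from both and reported in
#' \code{conflicts}.
#'
#' @slot L,H data.frame (\code{i}, \code{j}, \code{ratio}, \code{gene_a},
#'   \code{gene_b}, \code{r}).
#' @slot low,high numeric thresholds on |r|.
#' @slot conflicts data.frame of excluded pairs (possibly empty).
#' @export
setClass("InconsistencyInstance",
  representation(L = "data.frame", H = "data.frame",
                 low = "numeric", high = "numeric",
                 conflicts = "data.frame"))

setValidity("InconsistencyInstance", function(object) {
  msg <- character(0)
  if (length(object@low) != 1 || length(object@high) != 1 ||
      object@low < 0 || object@high > 1 || object@low >= object@high)
    msg <- c(msg, "thresholds must satisfy 0 <= low < high <= 1")
  keyL <- paste(object@L$i, object@L$j)
  keyH <- paste(object@H$i, object@H$j)
  if (length(intersect(keyL, keyH)))
    msg <- c(msg, "L and H must be disjoint")
  if (length(msg)) msg else TRUE
})

#' MilpConfig: parameters of the repair program
#'
#' @slot epsilon strict-inequality margin separating a broken coupling from a
#'   preserved one (dimensionless flux difference; default 1e-6).
#' @slot bigM big-M constant tied to the flux bound magnitude (default 1000).
#' @slot mode \code{"kegg"} or \code{"exchange"}.
#' @slot resolution \code{"all_at_once"} (global optimum over all
#'   inconsistencies) or \code{"one_by_one"} (each pair repaired separately).
#' @slot maxAlternatives cap on integer-cut enumeration.
#' @slot nodeLimit branch-and-bound node budget.
#' @export
setClass("MilpConfig",
  representation(epsilon = "numeric", bigM = "numeric", mode = "character",
                 resolution = "character", maxAlternatives = "numeric",
                 nodeLimit = "numeric"))

setValidity("MilpConfig", function(object) {
  msg <- character(0)
  if (object@epsilon <= 0 || object@epsilon >= object@bigM)
    msg <- c(msg, "epsilon must satisfy 0 < epsilon << bigM")
  if (!object@mode %in% c("kegg", "exchange"))
    msg <- c(msg, "mode must be 'kegg' or 'exchange'")
  if (!object@resolution %in% c("all_at_once", "one_by_one"))
    msg <- c(msg, "resolution must be 'all_at_once' or 'one_by_one'")
  if (object@maxAlternatives < 1)
    msg <- c(msg, "maxAlternatives must be positive")
  if (length(msg)) msg else TRUE
})

#' GapFillSolution: one optimum of the repair program
#'
#' @slot v witness fluxes over model reactions (named).
#' @slot y witness fluxes over candidates (named, nonnegative).
#' @slot d binary per low-correlation pair: 1 = coupling broken in witness.
#' @slot b binary per candidate: 1 = candidate added.
#' @slot h binary per originally irreversible reaction: 1 = runs backward
#'   (made reversible); empty in exchange mode.
#' @slot e,f auxiliary disjunction binaries (internal, kept for inspection).
#' @slot ZStar,NStar step-1 optimum (resolved inconsistencies) and step-2
#'   optimum (modification count).
#' @slot mode universal-set mode the solution was computed under.
#' @export
setClass("GapFillSolution",
  representation(v = "numeric", y = "numeric", d = "numeric", b = "numeric",
                 h = "numeric", e = "numeric", f = "numeric",
                 ZStar = "numeric", NStar = "numeric", mode = "character"))
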