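# Gene-level coupling through GPR-aware single-gene deletions, co-expression
# ingestion, and construction of the inconsistency sets L and H.

#' Reactions inactivated by deleting a single gene
#'
#' The gene is removed, every reaction whose GPR then evaluates to FALSE has
#' both bounds set to zero, and the reactions newly unable to carry
#' steady-state flux are returned (reactions already blocked in the intact
#' network are excluded).
#'
#' @param net a \code{MetabolicNetwork}.
#' @param gene gene identifier.
#' @param baseBlocked blocked set of the intact network; recomputed when
#'   omitted (pass it when calling in a loop).
#' @return character vector of reaction identifiers.
#' @export
deleteGeneBlocked <- function(net, gene, baseBlocked = NULL) {
  if (!gene %in% net@genes) stop("unknown gene: ", gene)
  if (is.null(baseBlocked)) baseBlocked <- findBlocked(net)
  present <- setdiff(net@genes, gene)
  off <- names(net@gpr)[!vapply(net@gpr, gprEval, logical(1),
                                present = present)]
  lb <- net@lb; ub <- net@ub
  idx <- match(off, reactionIds(net))
  lb[idx] <- 0; ub[idx] <- 0
  knet <- metabolicNetwork(net@S, lb = lb, ub = ub, gpr = net@gpr,
                           compartments = net@compartments)
  setdiff(findBlocked(knet), baseBlocked)
}

#' Gene coupling graph from exhaustive single-gene deletions
#'
#' Gene \code{g2} is coupled to \code{g1} when deleting \code{g1} inactivates
#' every unblocked reaction associated with \code{g2} (association is
#' syntactic GPR mention) and \code{g2} has at least one unblocked associated
#' reaction.  Genes coupled in both directions are fully coupled; only those
#' pairs feed the inconsistency construction, since two genes whose functions
#' are mutually dependent are the ones expected to be co-expressed.
#'
#' @param net a \code{MetabolicNetwork} with at least one gene.
#' @return a \code{\linkS4class{GeneCouplingGraph}}.
#' @export
geneCouplingGraph <- function(net) {
  genes <- geneIds(net)
  empty <- data.frame(g1 = character(0), g2 = character(0),
                      stringsAsFactors = FALSE)
  if (length(genes) == 0)
    return(new("GeneCouplingGraph", coupled = empty, fullyCoupled = empty))
  base <- findBlocked(net)
  assoc <- lapply(genes, function(g) setdiff(reactionsOfGene(net, g), base))
  names(assoc) <- genes
  killed <- lapply(genes, function(g) deleteGeneBlocked(net, g, base))
  names(killed) <- genes
  rows <- list()
  for (g1 in genes) for (g2 in genes) {
    if (g1 == g2) next
    if (length(assoc[[g2]]) > 0 && all(assoc[[g2]] %in% killed[[g1]]))
      rows[[length(rows) + 1L]] <- data.frame(g1 = g1, g2 = g2,
                                              stringsAsFactors = FALSE)
  }
  coupled <- if (length(rows)) do.call(rbind, rows) else empty
  key <- paste(coupled$g1, coupled$g2)
  full <- coupled[coupled$g1 < coupled$g2 &
                  paste(coupled$g2, coupled$g1) %in% key, , drop = FALSE]
  rownames(full) <- NULL
  new("GeneCouplingGraph", coupled = coupled, fullyCoupled = full)
}

#' Pairwise Pearson co-expression from an expression matrix
#'
#' @param expr numeric matrix, genes x conditions (rownames = gene ids);
#'   missing values allowed.
#' @param genes genes to tabulate (default: all rows).
#' @return a \code{\linkS4class{CorrelationTable}}; pairs with fewer than 3
#'   shared conditions or zero variance are recorded with \code{NA}
#'   (undefined) and never enter L or H.
#' @export
pearsonTable <- function(expr, genes = rownames(expr)) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  rows <- list()
  if (length(genes) >= 2) {
    for (a in seq_len(length(genes) - 1)) for (b in (a + 1):length(genes)) {
      x <- expr[genes[a], ]; y <- expr[genes[b], ]
      ok <- is.finite(x) & is.finite(y)
      r <- NA_real_
      if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
        r <- stats::cor(x[ok], y[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = min(genes[a], genes[b]), gene_b = max(genes[a], genes[b]),
        r = r, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0), r = numeric(0))
  new("CorrelationTable", r = tab[order(tab$gene_a, tab$gene_b), ,
                                  drop = FALSE])
}

#' Look up a pairwise correlation
#' @param corr a \code{CorrelationTable}.
#' @param a,b gene identifiers (order-free).
#' @return numeric r, or \code{NA} when absent/undefined.
#' @export
correlationOf <- function(corr, a, b) {
  t <- corr@r
  hit <- which((t$gene_a == a & t$gene_b == b) |
               (t$gene_a == b & t$gene_b == a))
  if (length(hit) == 0) NA_real_ else t$r[hit[1]]
}

#' Read / write a correlation table (TSV: gene_a, gene_b, r)
#' @param path TSV path.
#' @return a \code{CorrelationTable}.
#' @export
readCorrelationTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "r")
  if (!all(need %in% names(tab)))
    stop("correlation table must have columns: ",
         paste(need, collapse = ", "))
  swap <- tab$gene_a > tab$gene_b
  tmp <- tab$gene_a[swap]; tab$gene_a[swap] <- tab$gene_b[swap]
  tab$gene_b[swap] <- tmp
  new("CorrelationTable", r = tab[order(tab$gene_a, tab$gene_b),
                                  need, drop = FALSE])
}

#' @rdname readCorrelationTable
#' @param corr a \code{CorrelationTable}.
#' @export
writeCorrelationTable <- function(corr, path) {
  utils::write.table(corr@r, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build the inconsistency sets L and H
#'
#' For each fully coupled gene pair with a defined correlation, every fully
#' coupled reaction pair linking the two genes (one reaction associated with
#' each, association = syntactic GPR mention) is assigned to L when
#' \code{|r| < low}, to H when \code{|r| > high}, and to neither otherwise.
#' A reaction pair reachable from different gene pairs with conflicting
#' labels is excluded from both sets and reported in \code{conflicts}.
#' Output ordering is deterministic (lexicographic by reaction pair).
#'
#' @param net a \code{MetabolicNetwork}.
#' @param coupling \code{CouplingTable} of the same (preprocessed) network.
#' @param genes \code{GeneCouplingGraph} of the same network.
#' @param corr \code{CorrelationTable} for the model genes.
#' @param low,high absolute-correlation thresholds (defaults 0.2 / 0.8).
#' @return an \code{\linkS4class{InconsistencyInstance}}.
#' @export
buildInconsistency <- function(net, coupling, genes, corr,
                               low = 0.2, high = 0.8) {
  if (low < 0 || high > 1 || low >= high)
    stop("thresholds must satisfy 0 <= low < high <= 1")
  fullRxn <- fullyCoupledPairs(coupling)
  cand <- list()
  gp <- genes@fullyCoupled
  for (k in seq_len(nrow(gp))) {
    g1 <- gp$g1[k]; g2 <- gp$g2[k]
    r <- correlationOf(corr, g1, g2)
    if (is.na(r)) next
    a1 <- reactionsOfGene(net, g1); a2 <- reactionsOfGene(net, g2)
    for (r1 in a1) for (r2 in a2) {
      if (r1 == r2) next
      i <- min(r1, r2); j <- max(r1, r2)
      cp <- couplingOf(coupling, i, j)
      if (cp$relation != "fully") next
      label <- if (abs(r) < low) "L" else if (abs(r) > high) "H" else "none"
      if (label == "none") next
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, j = j, ratio = cp$ratio, gene_a = g1, gene_b = g2, r = r,
        label = label, stringsAsFactors = FALSE)
    }
  }
  cols <- c("i", "j", "ratio", "gene_a", "gene_b", "r")
  emptyDf <- data.frame(i = character(0), j = character(0),
                        ratio = numeric(0), gene_a = character(0),
                        gene_b = character(0), r = numeric(0))
  if (length(cand) == 0)
    return(new("InconsistencyInstance", L = emptyDf, H = emptyDf,
               low = low, high = high, conflicts = emptyDf))
  all <- do.call(rbind, cand)
  key <- paste(all$i, all$j)
  conflictKeys <- unique(key[key %in% key[all$label == "L"] &
                             key %in% key[all$label == "H"]])
  pick <- function(lab) {
    d <- all[all$label == lab & !(paste(all$i, all$j) %in% conflictKeys), ,
             drop = FALSE]
    d <- d[!duplicated(paste(d$i, d$j)), cols, drop = FALSE]
    d <- d[order(d$i, d$j), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  confl <- all[paste(all$i, all$j) %in% conflictKeys, cols, drop = FALSE]
  confl <- confl[!duplicated(paste(confl$i, confl$j)), , drop = FALSE]
  rownames(confl) <- NULL
  new("InconsistencyInstance", L = pick("L"), H = pick("H"),
      low = low, high = high, conflicts = confl)
}

#' Read / write an inconsistency instance (JSON)
#' @param path JSON path.
#' @return an \code{InconsistencyInstance}.
#' @export
readInconsistency <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  asDf <- function(x) {
    if (is.null(x) || length(x) == 0)
      return(data.frame(i = character(0), j = character(0),
                        ratio = numeric(0), gene_a = character(0),
                        gene_b = character(0), r = numeric(0)))
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  new("InconsistencyInstance", L = asDf(doc$L), H = asDf(doc$H),
      low = doc$low, high = doc$high, conflicts = asDf(doc$conflicts))
}

#' @rdname readInconsistency
#' @param inc an \code{InconsistencyInstance}.
#' @export
writeInconsistency <- function(inc, path) {
  jsonlite::write_json(list(L = inc@L, H = inc@H, low = inc@low,
                            high = inc@high, conflicts = inc@conflicts),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an expression matrix (TSV, genes x conditions, first column = gene)
#' @param path TSV path.
#' @return numeric matrix with gene rownames.
#' @export
readExpressionMatrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
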