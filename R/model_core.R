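# Model ingestion and preprocessing: SBML / COBRA-JSON readers and writers,
# biomass removal with independent export of biomass precursors, and assembly
# of universal candidate reaction sets.

DEFAULT_BOUND <- 1000

#' Read a metabolic model from SBML or COBRA-style JSON
#'
#' Supports SBML Level 3 with the fbc package (flux bounds as parameters,
#' gene associations as fbc trees) and the conventional COBRA JSON layout.
#' Files omitting bounds get the usual defaults: -1000..1000 for reversible
#' reactions, 0..1000 for irreversible ones.
#'
#' @param path file path.
#' @param dialect \code{"auto"} (by extension), \code{"sbml"} or
#'   \code{"cobra-json"}.
#' @return a \code{\linkS4class{MetabolicNetwork}}.
#' @export
readMetabolicModel <- function(path, dialect = c("auto", "sbml", "cobra-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "cobra-json" else "sbml"
  if (dialect == "cobra-json") readCobraJson(path) else readSbml(path)
}

readCobraJson <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(doc$reactions) || length(doc$reactions) == 0)
    stop("model has no reactions: ", path)
  mets <- vapply(doc$metabolites, function(m) m$id, character(1))
  comp <- vapply(doc$metabolites, function(m)
    if (is.null(m$compartment)) "c" else m$compartment, character(1))
  rxns <- vapply(doc$reactions, function(r) r$id, character(1))
  S <- Matrix::Matrix(0, length(mets), length(rxns), sparse = TRUE,
                      dimnames = list(mets, rxns))
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  gpr <- list()
  for (k in seq_along(doc$reactions)) {
    r <- doc$reactions[[k]]
    st <- r$metabolites
    if (length(st)) {
      unknown <- setdiff(names(st), mets)
      if (length(unknown))
        stop("reaction '", r$id, "' references unknown metabolite '",
             unknown[1], "'")
      S[names(st), k] <- unlist(st)
    }
    rev <- isTRUE(r$reversible) || (!is.null(r$lower_bound) && r$lower_bound < 0)
    lb[k] <- if (is.null(r$lower_bound)) (if (rev) -DEFAULT_BOUND else 0)
             else r$lower_bound
    ub[k] <- if (is.null(r$upper_bound)) DEFAULT_BOUND else r$upper_bound
    if (lb[k] > ub[k])
      stop("reaction '", r$id, "': lower bound exceeds upper bound")
    rule <- r$gene_reaction_rule
    if (!is.null(rule) && nzchar(trimws(rule))) gpr[[r$id]] <- parseGpr(rule)
  }
  metabolicNetwork(S, lb = lb, ub = ub, gpr = gpr,
                   compartments = stats::setNames(comp, mets))
}

readSbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e)))
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (length(sp) == 0) stop("SBML model has no species: ", path)
  mets <- xml2::xml_attr(sp, "id")
  comp <- xml2::xml_attr(sp, "compartment")
  comp[is.na(comp)] <- "c"
  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  glabel <- stats::setNames(xml2::xml_attr(gps, "label"),
                            xml2::xml_attr(gps, "id"))
  glabel[is.na(glabel)] <- names(glabel)[is.na(glabel)]
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (length(rx) == 0) stop("SBML model has no reactions: ", path)
  rxns <- xml2::xml_attr(rx, "id")
  S <- Matrix::Matrix(0, length(mets), length(rxns), sparse = TRUE,
                      dimnames = list(mets, rxns))
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  gpr <- list()
  for (k in seq_along(rx)) {
    node <- rx[[k]]
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, paste0(
        "./*[local-name()='", side, "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        met <- xml2::xml_attr(ref, "species")
        if (!met %in% mets)
          stop("reaction '", rxns[k], "' references unknown species '",
               met, "'")
        coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        if (side == "listOfReactants") coef <- -coef
        S[met, k] <- S[met, k] + coef
      }
    }
    lbid <- xml2::xml_attr(node, "lowerFluxBound")
    ubid <- xml2::xml_attr(node, "upperFluxBound")
    lb[k] <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]]
             else if (rev) -DEFAULT_BOUND else 0
    ub[k] <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]]
             else DEFAULT_BOUND
    if (lb[k] > ub[k])
      stop("reaction '", rxns[k], "': lower bound exceeds upper bound")
    assoc <- xml2::xml_find_first(node,
      "./*[local-name()='geneProductAssociation']/*")
    if (!inherits(assoc, "xml_missing")) {
      tree <- sbmlGprTree(assoc, glabel)
      if (!is.null(tree)) gpr[[rxns[k]]] <- tree
    }
  }
  metabolicNetwork(S, lb = lb, ub = ub, gpr = gpr,
                   compartments = stats::setNames(comp, mets))
}

sbmlGprTree <- function(node, glabel) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    g <- if (gid %in% names(glabel)) glabel[[gid]] else gid
    return(list(op = "gene", gene = g))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), sbmlGprTree, glabel = glabel)
    kids <- Filter(Negate(is.null), kids)
    if (length(kids) == 0) return(NULL)
    if (length(kids) == 1) return(kids[[1]])
    return(list(op = nm, args = kids))
  }
  NULL
}

#' Write a metabolic model to SBML or COBRA-style JSON
#'
#' Writing then re-reading reproduces the stoichiometry, bounds and GPR
#' trees exactly.
#' @param net a \code{MetabolicNetwork}.
#' @param path output path.
#' @param dialect \code{"auto"}, \code{"sbml"} or \code{"cobra-json"}.
#' @export
writeMetabolicModel <- function(net, path,
                                dialect = c("auto", "sbml", "cobra-json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "cobra-json" else "sbml"
  if (dialect == "cobra-json") writeCobraJson(net, path)
  else writeSbml(net, path)
  invisible(path)
}

writeCobraJson <- function(net, path) {
  mets <- metaboliteIds(net); rxns <- reactionIds(net)
  doc <- list(
    metabolites = lapply(mets, function(m)
      list(id = m, compartment = unname(net@compartments[[m]]))),
    reactions = lapply(seq_along(rxns), function(k) {
      col <- net@S[, k]
      nz <- which(col != 0)
      r <- list(id = rxns[k],
                metabolites = as.list(stats::setNames(col[nz], mets[nz])),
                lower_bound = net@lb[k], upper_bound = net@ub[k])
      g <- net@gpr[[rxns[k]]]
      r$gene_reaction_rule <- if (is.null(g)) "" else gprToString(g)
      r
    }),
    genes = lapply(geneIds(net), function(g) list(id = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

writeSbml <- function(net, path) {
  mets <- metaboliteIds(net); rxns <- reactionIds(net)
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>')
  for (cp in unique(net@compartments))
    lines <- c(lines, sprintf('      <compartment id="%s" constant="true"/>', cp))
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (m in mets)
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"/>'), esc(m), net@compartments[[m]]))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (k in seq_along(rxns))
    lines <- c(lines,
      sprintf('      <parameter id="lb_%d" value="%.17g" constant="true"/>',
              k, net@lb[k]),
      sprintf('      <parameter id="ub_%d" value="%.17g" constant="true"/>',
              k, net@ub[k]))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (k in seq_along(rxns)) {
    col <- net@S[, k]
    subs <- which(col < 0); prods <- which(col > 0)
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="lb_%d" fbc:upperFluxBound="ub_%d">'),
      esc(rxns[k]), if (net@lb[k] < 0) "true" else "false", k, k))
    if (length(subs)) {
      lines <- c(lines, '        <listOfReactants>')
      for (i in subs)
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
          esc(mets[i]), -col[i]))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prods)) {
      lines <- c(lines, '        <listOfProducts>')
      for (i in prods)
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
          esc(mets[i]), col[i]))
      lines <- c(lines, '        </listOfProducts>')
    }
    g <- net@gpr[[rxns[k]]]
    if (!is.null(g))
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 sbmlGprXml(g, indent = "          "),
                 '        </fbc:geneProductAssociation>')
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
             '    <fbc:listOfGeneProducts>')
  for (g in geneIds(net))
    lines <- c(lines, sprintf(
      '      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
      esc(g), esc(g)))
  lines <- c(lines, '    </fbc:listOfGeneProducts>', '  </model>', '</sbml>')
  writeLines(lines, path)
}

sbmlGprXml <- function(expr, indent) {
  if (expr$op == "gene")
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                   indent, expr$gene))
  inner <- unlist(lapply(expr$args, sbmlGprXml,
                         indent = paste0(indent, "  ")))
  c(sprintf("%s<fbc:%s>", indent, expr$op), inner,
    sprintf("%s</fbc:%s>", indent, expr$op))
}

#' Remove the biomass reaction and export its precursors independently
#'
#' Pairwise flux coupling through a biomass sink makes large swaths of the
#' network look fully coupled; coupling analysis therefore runs on a network
#' with the biomass reaction removed.  Every metabolite the biomass reaction
#' consumed that cannot already leave the system gets its own irreversible
#' export reaction, so each precursor can drain independently.
#'
#' @param net a \code{MetabolicNetwork}.
#' @param biomass_id identifier of the biomass reaction; when \code{NULL} the
#'   first reaction whose id matches "biomass" case-insensitively is used.
#' @return the preprocessed network; stoichiometry of all surviving original
#'   reactions is untouched.
#' @export
preprocessBiomass <- function(net, biomass_id = NULL) {
  rxns <- reactionIds(net)
  if (is.null(biomass_id)) {
    hit <- grep("biomass", rxns, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) stop("no reaction id matches 'biomass'")
    biomass_id <- hit[1]
  }
  j <- match(biomass_id, rxns)
  if (is.na(j)) stop("biomass reaction not found: ", biomass_id)
  consumed <- metaboliteIds(net)[net@S[, j] < 0]
  keep <- setdiff(seq_along(rxns), j)
  trimmed <- metabolicNetwork(net@S[, keep, drop = FALSE],
                              lb = net@lb[keep], ub = net@ub[keep],
                              gpr = net@gpr[setdiff(names(net@gpr), biomass_id)],
                              compartments = net@compartments)
  need <- consumed[!vapply(consumed, canExportMetabolite, logical(1),
                           net = trimmed)]
  if (length(need) == 0) return(trimmed)
  ids <- paste0("EX_", need, "_bm")
  cols <- lapply(need, function(m) stats::setNames(-1, m))
  appendReactions(trimmed, ids, cols,
                  lb = rep(0, length(ids)), ub = rep(DEFAULT_BOUND, length(ids)))
}

# ---- universal candidate sets ------------------------------------------

# canonical stoichiometry key: case-insensitive metabolite names, combined
# coefficients, sorted; reversible reactions are canonicalized up to sign
canonicalStoichKey <- function(stoich, reversible) {
  nm <- tolower(trimws(names(stoich)))
  agg <- tapply(stoich, nm, sum)
  agg <- agg[abs(agg) > 1e-12]
  if (length(agg) == 0) return("")
  agg <- agg[order(names(agg))]
  key <- function(x) paste(names(x), format(round(x, 9), trim = TRUE,
                                            scientific = FALSE),
                           sep = ":", collapse = ";")
  k1 <- key(agg)
  if (!reversible) return(k1)
  k2 <- key(-agg)
  min(k1, k2)
}

# parse "2 A + B -> C" / "A <=> B" into a signed stoichiometry vector plus a
# flag for metabolites appearing on both sides
parseReactionEquation <- function(eq) {
  arrows <- c("<=>", "<->", "<==>", "=>", "->", "=")
  arrow <- NULL
  for (a in arrows) if (grepl(a, eq, fixed = TRUE)) { arrow <- a; break }
  if (is.null(arrow)) stop("no reaction arrow in equation: ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("malformed equation: ", eq)
  parseSide <- function(txt) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      if (!nzchar(t)) stop("empty term in equation: ", eq)
      m <- regmatches(t, regexec("^([0-9]*\\.?[0-9]+)?\\s*(\\S.*)$", t))[[1]]
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      met <- trimws(m[3])
      out[met] <- if (met %in% names(out)) out[[met]] + coef else coef
    }
    out
  }
  sub <- parseSide(sides[1]); prod <- parseSide(sides[2])
  both <- intersect(names(sub), names(prod))
  st <- stats::setNames(numeric(0), character(0))
  for (m in union(names(sub), names(prod)))
    st[m] <- (if (m %in% names(prod)) prod[[m]] else 0) -
             (if (m %in% names(sub)) sub[[m]] else 0)
  st <- st[abs(st) > 1e-12]
  list(stoich = st, sameBothSides = length(both) > 0,
       reversibleArrow = arrow %in% c("<=>", "<->", "<==>", "="))
}

#' Load a universal candidate reaction set from a tabular file
#'
#' Expects a TSV with columns \code{id}, \code{equation} and
#' \code{reversibility}.  Candidates are filtered in order: (a) reactions
#' with the same metabolite on both substrate and product side are dropped;
#' (b) canonical duplicates (identical stoichiometry after case-insensitive
#' metabolite-name normalization, up to direction for reversible reactions)
#' are collapsed to the first occurrence; (c) candidates identical to a
#' reaction already present in the model are dropped.  Reversible survivors
#' are split into two irreversible forward columns (\code{__f}, \code{__r})
#' so candidate fluxes stay nonnegative in the repair program.  Candidate
#' metabolites absent from the model are admitted and receive their own
#' steady-state mass-balance rows.
#'
#' @param path TSV path.
#' @param net the target \code{MetabolicNetwork}.
#' @return a \code{\linkS4class{UniversalSet}} with \code{mode = "kegg"}.
#' @export
loadUniversal <- function(path, net) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("universal reaction table is empty: ", path)
  need <- c("id", "equation", "reversibility")
  if (!all(need %in% names(tab)))
    stop("universal table must have columns: ", paste(need, collapse = ", "))
  parsed <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    parsed[[k]] <- tryCatch(parseReactionEquation(tab$equation[k]),
      error = function(e) stop("row ", k, " ('", tab$id[k], "'): ",
                               conditionMessage(e)))
    rv <- tolower(as.character(tab$reversibility[k]))
    parsed[[k]]$reversible <- rv %in% c("true", "reversible", "1", "yes") ||
      (rv %in% c("", "na") && parsed[[k]]$reversibleArrow)
  }
  universalFromParsed(tab$id, parsed, net)
}

universalFromParsed <- function(ids, parsed, net) {
  # (a) same-metabolite-both-sides
  keep <- !vapply(parsed, `[[`, logical(1), "sameBothSides")
  # (b) canonical duplicates, (c) identical to a model reaction
  modelKeys <- vapply(seq_len(ncol(net@S)), function(j) {
    col <- net@S[, j]
    nz <- which(col != 0)
    canonicalStoichKey(stats::setNames(col[nz], metaboliteIds(net)[nz]),
                       reversible = net@lb[j] < 0)
  }, character(1))
  seen <- character(0)
  for (k in which(keep)) {
    key <- canonicalStoichKey(parsed[[k]]$stoich, parsed[[k]]$reversible)
    if (key %in% seen || key %in% modelKeys) keep[k] <- FALSE
    else seen <- c(seen, key)
  }
  ids <- ids[keep]; parsed <- parsed[keep]
  colIds <- character(0); srcIds <- character(0); srcRev <- logical(0)
  cols <- list()
  for (k in seq_along(parsed)) {
    st <- parsed[[k]]$stoich
    if (parsed[[k]]$reversible) {
      colIds <- c(colIds, paste0(ids[k], "__f"), paste0(ids[k], "__r"))
      srcIds <- c(srcIds, ids[k], ids[k])
      srcRev <- c(srcRev, TRUE, TRUE)
      cols <- c(cols, list(st, -st))
    } else {
      colIds <- c(colIds, ids[k])
      srcIds <- c(srcIds, ids[k])
      srcRev <- c(srcRev, FALSE)
      cols <- c(cols, list(st))
    }
  }
  allMets <- union(metaboliteIds(net),
                   unique(unlist(lapply(cols, names), use.names = FALSE)))
  U <- Matrix::Matrix(0, length(allMets), length(colIds), sparse = TRUE,
                      dimnames = list(allMets, colIds))
  for (k in seq_along(cols)) U[names(cols[[k]]), k] <- cols[[k]]
  new("UniversalSet", U = U, sourceId = srcIds, sourceReversible = srcRev,
      mode = "kegg")
}

#' Build the universal set of exchange reactions
#'
#' One candidate per model metabolite that lacks an existing exchange-style
#' reaction (single nonzero stoichiometric coefficient).  Each candidate is
#' conceptually reversible (the metabolite may enter or leave the system) and
#' is represented as an export/import column pair with nonnegative fluxes.
#'
#' @param net a \code{MetabolicNetwork}.
#' @return a \code{\linkS4class{UniversalSet}} with \code{mode = "exchange"}.
#' @export
buildExchangeUniversal <- function(net) {
  mets <- metaboliteIds(net)
  lack <- mets[vapply(mets, function(m)
    length(boundaryReactionsOf(net, m)) == 0, logical(1))]
  colIds <- as.vector(rbind(paste0("EX_", lack, "__f"),
                            paste0("EX_", lack, "__r")))
  U <- Matrix::Matrix(0, length(mets), length(colIds), sparse = TRUE,
                      dimnames = list(mets, colIds))
  for (k in seq_along(lack)) {
    U[lack[k], 2 * k - 1] <- -1   # export
    U[lack[k], 2 * k]     <-  1   # import
  }
  new("UniversalSet", U = U,
      sourceId = rep(paste0("EX_", lack), each = 2),
      sourceReversible = rep(TRUE, length(colIds)), mode = "exchange")
}

#' An empty universal set over a network's metabolites
#'
#' Useful as the degenerate "no candidates available" input.
#' @param net a \code{MetabolicNetwork}.
#' @param mode \code{"kegg"} or \code{"exchange"}.
#' @return a \code{UniversalSet} with zero candidates.
#' @export
emptyUniversal <- function(net, mode = "kegg") {
  mets <- metaboliteIds(net)
  U <- Matrix::Matrix(0, length(mets), 0, sparse = TRUE,
                      dimnames = list(mets, character(0)))
  new("UniversalSet", U = U, sourceId = character(0),
      sourceReversible = logical(0), mode = mode)
}

#' Number of distinct candidate reactions in a universal set
#'
#' Split direction columns of one source reaction count once.
#' @param us a \code{UniversalSet}.
#' @return integer.
#' @export
nCandidates <- function(us) length(unique(us@sourceId))

#' Serialize a universal set to TSV (id, equation, reversibility)
#' @param us a \code{UniversalSet}.
#' @param path output path.
#' @export
writeUniversal <- function(us, path) {
  src <- unique(us@sourceId)
  rows <- lapply(src, function(id) {
    j <- which(us@sourceId == id)[1]
    col <- us@U[, j]
    nz <- which(col != 0)
    st <- stats::setNames(as.numeric(col[nz]), rownames(us@U)[nz])
    term <- function(x) {
      cf <- abs(x)
      paste(ifelse(cf == 1, names(x), paste(cf, names(x))), collapse = " + ")
    }
    lhs <- term(st[st < 0]); rhs <- term(st[st > 0])
    rev <- us@sourceReversible[j]
    data.frame(id = id,
               equation = paste(lhs, if (rev) "<=>" else "->", rhs),
               reversibility = rev)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
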