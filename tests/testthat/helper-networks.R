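# Builders for the small fixture networks used across the suite.

# linear chain:  -> A -> B -> ... -> (export); reactions Rin, R1..R(k-1), Rout
chainNetwork <- function(mets = c("A", "B", "C"), prefix = "R",
                         gpr = list()) {
  n <- length(mets)
  rxns <- c(paste0(prefix, "in"),
            paste0(prefix, seq_len(n - 1)),
            paste0(prefix, "out"))
  S <- matrix(0, n, n + 1, dimnames = list(mets, rxns))
  S[1, 1] <- 1
  for (k in seq_len(n - 1)) {
    S[k, k + 1] <- -1
    S[k + 1, k + 1] <- 1
  }
  S[n, n + 1] <- -1
  metabolicNetwork(S, lb = rep(0, n + 1), ub = rep(1000, n + 1), gpr = gpr)
}

# universal set made of explicit single columns (kegg mode)
handUniversal <- function(net, cols, extraMets = character(0),
                          mode = "kegg") {
  mets <- union(metaboliteIds(net), extraMets)
  U <- Matrix::Matrix(0, length(mets), length(cols), sparse = TRUE,
                      dimnames = list(mets, names(cols)))
  for (k in seq_along(cols)) U[names(cols[[k]]), k] <- cols[[k]]
  new("UniversalSet", U = U, sourceId = names(cols),
      sourceReversible = rep(FALSE, length(cols)), mode = mode)
}

# inconsistency instance from bare reaction pairs (full-coupling ratio 1
# unless stated); gene columns are irrelevant for the repair program
handInstance <- function(L, H = NULL, low = 0.2, high = 0.8) {
  mk <- function(p) {
    if (is.null(p) || length(p) == 0)
      return(data.frame(i = character(0), j = character(0),
                        ratio = numeric(0), gene_a = character(0),
                        gene_b = character(0), r = numeric(0)))
    do.call(rbind, lapply(p, function(x)
      data.frame(i = x[[1]], j = x[[2]],
                 ratio = if (length(x) > 2) as.numeric(x[[3]]) else 1,
                 gene_a = NA_character_, gene_b = NA_character_,
                 r = NA_real_, stringsAsFactors = FALSE)))
  }
  new("InconsistencyInstance", L = mk(L), H = mk(H), low = low, high = high,
      conflicts = mk(NULL))
}

# four independent chains: pairs 1 and 2 repairable from the database
# candidates, pair 3 only by a new exchange, pair 4 protected by an H pair
# so that nothing can repair it
fallbackFixture <- function() {
  mets <- as.vector(outer(c("A", "B", "C"), 1:4, paste0))
  rxn <- function(k, what) paste0("c", k, "_", what)
  rxns <- as.vector(vapply(1:4, function(k)
    c(rxn(k, "in"), rxn(k, "a"), rxn(k, "b"), rxn(k, "out")),
    character(4)))
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (k in 1:4) {
    A <- paste0("A", k); B <- paste0("B", k); C <- paste0("C", k)
    S[A, rxn(k, "in")] <- 1
    S[A, rxn(k, "a")] <- -1; S[B, rxn(k, "a")] <- 1
    S[B, rxn(k, "b")] <- -1; S[C, rxn(k, "b")] <- 1
    S[C, rxn(k, "out")] <- -1
  }
  net <- metabolicNetwork(S, lb = rep(0, ncol(S)), ub = rep(1000, ncol(S)))
  kegg <- handUniversal(net, list(u1 = c(B1 = -1), u2 = c(B2 = -1)))
  inc <- handInstance(
    L = list(c("c1_a", "c1_b"), c("c2_a", "c2_b"),
             c("c3_a", "c3_b"), c("c4_a", "c4_b")),
    H = list(c("c4_a", "c4_out")))
  list(net = net, kegg = kegg, exch = buildExchangeUniversal(net),
       inc = inc)
}

# chain whose coupled pair can only be repaired by relaxing the
# irreversibility of the dead branch Rb (E -> B with E only exportable)
reversibilityFixture <- function() {
  mets <- c("A", "B", "C", "E")
  rxns <- c("Rin", "R1", "R2", "Rout", "Rb", "RoutE")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["A", "Rin"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "R2"] <- -1; S["C", "R2"] <- 1
  S["C", "Rout"] <- -1
  S["E", "Rb"] <- -1; S["B", "Rb"] <- 1
  S["E", "RoutE"] <- -1
  metabolicNetwork(S, lb = rep(0, length(rxns)), ub = rep(1000, length(rxns)))
}
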