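Package: fluxgap
Title: Gap Finding and Gap Filling of Metabolic Networks from Gene
    Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects candidate gaps in genome-scale metabolic network
    reconstructions by confronting predicted flux coupling relations with
    experimental gene co-expression, and proposes a minimal set of network
    modifications (reactions added from a universal candidate database,
    irreversibility relaxations, or exchange reactions) that resolves the
    maximum number of coupling/co-expression inconsistencies while
    preserving couplings supported by high co-expression. The repair step
    is a two-stage mixed-integer linear program with integer-cut
    enumeration of alternate optima; flux coupling analysis, gene-level
    coupling through gene-protein-reaction rules, and self-certifying
    synthetic fixtures are included, together with brute-force oracles
    (steady-state polytope vertex enumeration, candidate subset search)
    used for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, jsonlite, xml2
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
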