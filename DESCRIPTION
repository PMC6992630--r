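Package: tcrep
Title: T Cell Receptor Beta-Chain Repertoire Analysis Across Tissue Compartments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing bulk TCR-beta CDR3 repertoires across
    paired tissue compartments (peripheral blood, tumor, adjacent uninvolved
    lung, healthy and COPD lung). Reads immunoSEQ- and AIRR-style
    rearrangement tables, computes per-sample repertoire attributes (T cell
    density, clonality as one minus Pielou's evenness, species richness with
    Good-Toulmin extrapolation to a fixed template depth), quantifies
    cross-compartment homology (Jaccard and Morisita-Horn indices, top-N
    prevalent-clone sharing, public clones), calls tissue-enriched clones by
    paired exact tests with FDR control, groups CDR3s into antigen-specificity
    clusters via enriched local motifs and global similarity with viral
    classification against a tetramer-defined reference, and runs cohort-level
    association and survival analyses. Includes a multi-compartment synthetic
    cohort simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tools,
    optparse,
    vegan
Config/testthat/edition: 3
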