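Package: conformgen
Title: Conformational Ensemble Exposure Analysis and Summary-Statistic
    Causal Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for linking a missense variant to protein
    conformational behaviour and to causal genetic evidence.  One half of
    the package analyses conformational ensembles: multi-model PDB
    trajectories are combined, aligned by two-pass Kabsch superposition,
    reduced by coordinate principal component analysis, partitioned by
    average-linkage clustering, and characterised cluster-by-cluster through
    RMSD, radius of gyration, Shrake-Rupley solvent-accessible surface area,
    and motif-level exposure and surrogate-antigenicity deltas.  The other
    half implements a summary-statistic causal-genetics chain: Wald-ratio
    Mendelian randomization with instrument F-statistics, Wakefield
    approximate-Bayes-factor colocalization posteriors, credible-set
    construction from posterior inclusion probabilities, LD r-squared, and
    criteria-based variant prioritization.  Synthetic generators for
    bead-model conformer trajectories with planted burial/exposure changes
    and for two-trait GWAS summary statistics under AR(1)-style LD make
    every step testable without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
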