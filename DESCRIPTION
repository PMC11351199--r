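Package: synviab
Title: Synthetic-Viability Candidate Discovery from Copy Number, Expression and CRISPR Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative discovery of candidate synthetic-viability genes in
    homologous-recombination-deficient (bi-allelic BRCA1/BRCA2) tumors.
    Assigns ploidy-relative copy-number status to cytobands, tests per-band
    deletion/amplification enrichment in cases versus HR-proficient controls
    (Fisher's exact test with Benjamini-Hochberg FDR control) with a
    fixed row/column-margin permutation null for the count of enriched bands,
    scores copy-number-coupled transcriptional downregulation with a
    transcriptional consistency score (TCS), scores differential gene
    essentiality between wild-type and BRCA-knockout CRISPR screens with a
    relative proliferation score (RPS), and intersects the three evidence
    streams into candidate lists. Ships a synthetic-cohort generator with
    planted ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vegan,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
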