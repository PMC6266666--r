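Package: venomics
Title: Venom Peptide Mass Reconciliation, Identification Filtering and Bioassay Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating venom-gland transcriptomes with intact-mass and
    shotgun proteomics of crude venom. Computes modification-aware monoisotopic
    peptide masses (disulfide bonds, N-terminal pyroglutamate, reduction and
    hydroxyethyl alkylation of cysteines), enumerates candidate mature peptides
    from annotated precursors and reconciles them with deconvoluted mass lists,
    counts cysteines per peptide by pairing native against reduced/alkylated mass
    lists, applies signal-peptide-conditional protein identification thresholds to
    peptide-spectrum-match tables, assigns rational toxin names with
    identity-based subtype clustering, and estimates paralytic dose-response
    (PD50), venom composition fractions and expression-intensity correlations.
    Includes a seeded synthetic-data generator emulating a multi-family venom
    repertoire so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
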