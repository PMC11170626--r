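Package: epichem
Title: Diversity and Structure-Activity Landscape Analysis of Epigenetically
    Annotated Food-Chemical Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemoinformatic analysis of compound libraries annotated with
    binary multi-target epigenetic activity profiles. Reads and validates
    the curated database CSV dialect, computes four structural fingerprints
    (MACCS keys, extended-connectivity radius 2 and 3, path-based) and
    all-pairs Jaccard-Tanimoto similarities, extracts Bemis-Murcko
    scaffolds and summarizes scaffold diversity with cyclic-system-recovery
    curves and their AUC, computes activity-profile statistics
    (target frequencies, single- and multi-target compounds), builds
    structure-activity-similarity (SAS) maps with consensus region
    classification and pseudo-activity-cliff detection, and embeds the
    library into a 2-D chemical space with a seeded t-SNE over
    physicochemical descriptors. Includes a deterministic synthetic-library
    generator with controlled scaffold-frequency distributions and
    scaffold-coupled activity profiles so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
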