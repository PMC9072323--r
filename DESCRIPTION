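Package: protaxa
Title: Species Inference from Shotgun Proteomics of Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns a mammalian species (or a set of indistinguishable
    species) to each mass-spectrometry raw file from tables of identified
    peptide precursors, using a gene-wise aligned multi-species protein
    database. Peptide identifications are mapped to global alignment
    coordinates, aggregated into site-level metrics, combined into a
    normalized joint score, and used to decide every pairwise
    species-to-species comparison over sites where the two species differ.
    False assignments are controlled by chimeric decoy species (coverage-
    ranked q-values) and by a protease-intensity threshold calibrated on
    laboratory blanks. A seeded simulator generates aligned databases and
    precursor evidence so the whole pipeline can be exercised without
    mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
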