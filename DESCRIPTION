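Package: neoms
Title: Neoepitope Discovery and Validation from MHC Class I Immunopeptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for mass-spectrometry-driven discovery and validation
    of tumor neoepitopes. Builds mutation-centered long-peptide search
    databases from somatic amino-acid variants applied to a reference
    proteome, scores candidate 8-11-mers against H-2 Kd/Dd/Ld binding motifs
    and computes the Differential Agretopic Index (DAI), filters
    peptide-spectrum-match lists by target-decoy FDR and peptide length with
    asymmetric quartile intensity normalization, validates candidates by
    heavy/light parallel-reaction-monitoring co-elution logic, scores tumor
    growth curves with the Tumor Control Index (rejection + inhibition +
    stability, maximum 30), and computes structural post-metrics
    (superposition-based peptide RMSD, Shrake-Rupley solvent-accessible
    surface area, exposed hydrophobic surface, salt bridges) on peptide-MHC
    models. A synthetic-data module generates every input class so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    multcomp,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
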