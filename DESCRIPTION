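Package: ficms
Title: Fragment-Ion-Coverage Based Identification of Histone Modification Marks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tailored database-search strategy for identifying histone
    post-translational modification marks from small MS/MS datasets. Instead of
    target-decoy false-discovery-rate filtration, peptide-spectrum matches are
    accepted when at least half of the theoretical b/y fragment ions are
    observed (fragment ion coverage, FIC). The search includes common
    co-occurring modifications (lysine acetylation, lysine and arginine
    monomethylation) as background variable modifications, and dissects
    chimeric spectra produced by co-eluting positional isomers using
    site-determining ions. Ships in-silico tryptic digestion, combinatorial
    modified-peptide enumeration, MGF/mzML spectrum I/O, a deterministic
    synthetic-spectrum simulator, target-decoy FDR and ROC comparison
    machinery, automated confidence classification, and site-level reporting
    in mature histone numbering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
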