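Package: tumorclock
Title: Timing Tumor Progression from Somatic Allele Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the progression history of a tumor from bulk
    whole-genome sequencing summaries: somatic SNV mutant allele fractions,
    germline heterozygous SNP B-allele fractions, and tumor/normal copy-ratio
    segments. Provides closed-form expectations linking tumor purity and
    allele-specific copy states to allele-fraction peaks, enumeration of
    small-copy-number evolutionary histories, grid-based purity/ploidy
    fitting validated against somatic allele fractions, mutational-clock
    timing of copy gains, CN-LOH and clonal expansions with bootstrap
    confidence intervals, whole-genome-duplication calling, a corrected
    1/f power-law test for neutral subclonal evolution, kataegis detection
    from inter-mutation distances, and a fully seeded synthetic tumor
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
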