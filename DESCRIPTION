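Package: hapresample
Title: Reversible Recombination-Based Resampling of Haplotype Reference Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic haplotype reference panels by simulating a
    user-chosen number of generations of meiotic recombination over a phased
    reference panel. Recombination breakpoints are drawn from a homogeneous
    Poisson process in genetic-map coordinates and applied as a streaming
    permutation of haplotypes, so the synthetic panel preserves per-site
    allele frequencies exactly and linkage-disequilibrium structure
    approximately, while breaking the link between haplotypes and sample
    identities. The transform is exactly reversible given the genetic map,
    the generation count and the random seed. Includes HapMap-style genetic
    map interpolation, LD-score evaluation metrics (per-variant LD scores,
    cross-panel Pearson correlation and regression slope), a founder-mosaic
    fixture simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
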