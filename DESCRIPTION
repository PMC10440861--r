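Package: CNSVMatrix
Title: Channel Matrices for Copy-Number and Structural Variant Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies allele-specific copy-number segments into a 48-channel
    schema (heterozygosity state x total copy number x segment size) and
    structural variants into a 32-channel schema (clustered/non-clustered x
    event type x size), producing channel-by-sample count matrices suitable
    for mutational-signature decomposition. Reads segmentation tables from
    six common copy-number callers plus a generic format, and structural
    variants from BEDPE with strand-convention class inference. Clustered
    rearrangements are detected by exact piecewise-constant fitting (Potts
    filter) of inter-mutational distances of breakpoints. Includes per-sample
    profile bar charts, rainfall plots, a seeded synthetic-data generator
    with ground-truth channel assignments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
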