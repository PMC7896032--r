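Package: padcyto
Title: Cytometry of Pericentromere-Associated Domains in Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image cytometry of pericentromere-associated heterochromatin domains
    (PADs, chromocenters) during early differentiation commitment. Segments nuclei
    and H3K9me3-positive chromocenters in multi-channel fluorescence images, gates
    cells by integrated DAPI fluorescence intensity, counts CENPA-positive
    centromere foci nested in chromocenters, computes the acridine-orange red/green
    DNA-conformation index and a euchromatin heterogeneity statistic, fits
    scale-free size-number relationships (reciprocal-count versus square-root area,
    power-law, exponential), performs qPCR relative quantification (delta-delta-CT,
    two-reference geometric-mean normalization, geNorm stability M), and provides
    Welch tests from summary statistics with Benjamini-Hochberg adjustment. Includes
    a seeded synthetic microscopy-image and qPCR-plate generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
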