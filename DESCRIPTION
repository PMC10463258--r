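Package: splicefrac
Title: Splice-Variant Fractions from Mixed Sanger Traces and Gel Densitometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the relative abundance of mRNA splice variants that
    differ by short insertions at exon-exon junctions, from two routine
    RT-PCR readouts: mixed Sanger sequencing chromatograms of co-amplified
    products (decomposed by informative-site peak-amplitude ratios or by
    constrained least squares) and agarose-gel lane densitometry of
    length-resolved fragments. Combines both measurements into a four-isoform
    profile with technical-replicate aggregation, and provides the comparison
    statistics used in splice-ratio studies (unpaired t test, two-tailed
    variance-ratio F test, two-way ANOVA). Includes a forward simulator for
    four-channel electropherograms and gel lane profiles with known ground
    truth, and readers for ABIF/AB1 trace files, FASTA references, and plain
    text lane profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
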