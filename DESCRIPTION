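Package: triplexhub
Title: Statistical Discovery of Universal RNA-DNA Triplex Target Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA-DNA triple helices under Hoogsteen base-pairing
    rules and scores the number of predicted triplexes for each RNA-DNA
    pair against a length-calibrated Poisson null model. Triplex windows
    are enumerated exhaustively (overlaps allowed) for the pyrimidine
    (TC), purine (GA) and mixed (GT) motif families in both parallel and
    antiparallel orientations on both DNA strands, with a configurable
    minimum length and error rate. The expected count is modelled as a
    linear function of RNA and DNA lengths calibrated by simulation on
    random sequences, observed counts are converted to Poisson tail
    p-values with Bonferroni adjustment, and genomic regions significant
    for more than 90 percent of a transcript panel are classified as
    universal triplex target sites. Includes strand-aware purine and
    poly-purine composition profiling, exact dinucleotide-preserving
    shuffling for control RNAs, and a synthetic-data generator that
    plants purine-rich low-complexity tracts in a random genome for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
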