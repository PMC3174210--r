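Package: greyDBP
Title: DNA-Binding Protein Prediction from a Grey-Model Pseudo Amino Acid
    Composition
Version: 1.0.0
Authors@R:
    person("greyDBP", "Developers", email = "greydbp@example.org",
           role = c("aut", "cre"))
Description: Represents a protein sequence as a 23-component pseudo amino
    acid composition: the 20 amino acid occurrence frequencies plus the
    absolute values of the three GM(2,1) grey-model coefficients fitted by
    least squares to a physicochemical (molecular-volume) encoding of the
    sequence. A built-in random forest classifies sequences as DNA-binding
    or non-DNA-binding, with jackknife (leave-one-out) and independent-set
    evaluation, FASTA dataset screening filters, a synthetic labeled-dataset
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
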