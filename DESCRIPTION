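Package: ssdesign
Title: Secondary-Structure-Conditioned Protein Sequence Design with
    Reduced Amino Acid Alphabets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative design of amino acid sequences that adopt a target
    secondary structure, using a bidirectional LSTM encoder with multi-head
    self-attention trained on DSSP state strings and per-residue
    physicochemical properties (van der Waals volume, logD at pH 7, formal
    charge). Supports reduced amino acid alphabets via hard logit masking at
    inference, alphabet-library curation with stratified sampling, DSSP
    sequence complexity metrics (Shannon, transition, Simpson), percent
    identity evaluation, and a seeded synthetic-data generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
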