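Package: triplexr
Title: Prediction of DNA-RNA Triple Helices from Canonical Hoogsteen Pairing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Finds triplex target sites (TTS) and triplex-forming
    oligonucleotides (TFO) between a DNA duplex and an RNA under the four
    canonical Hoogsteen pairing frames. Candidate alignments are scanned over
    purine tracts of both DNA strands with a configurable minimum consecutive
    pair requirement and mismatch-rate budget, then reduced to non-redundant
    hits by end-trimming, core-run, region-domination and sliding-tie rules.
    Optionally annotates predicted target sites with CpG islands detected by a
    running-sum scoring scan. Includes a deterministic synthetic fixture
    generator with planted triplexes and islands, a brute-force reference
    search for verification, and a command-line interface writing TSV and BED
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
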