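Package: circbact
Title: Discovery and Mass-Spectrometric Verification of Head-to-Tail
    Circular Bacteriocins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mining bacterial genomes for circular (head-to-tail
    cyclized) bacteriocin gene clusters, modelling precursor maturation
    (leader cleavage and amide-bond cyclization with loss of one water),
    performing in-silico tryptic digestion of circular peptides including
    junction-spanning fragments, matching theoretical fragment and intact
    masses against LC-MS/MS and MALDI-TOF peak lists to render a
    circularity verdict, and designing split-intein-mediated-ligation
    (SIML) expression constructs and linear T7 PCR templates for in vitro
    or in vivo production of circular peptides. Includes a deterministic
    synthetic-data generator for end-to-end validation with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
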