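Package: polxscan
Title: Classification and Genomic Context Analysis of Prokaryotic X-Family
    DNA Polymerases
Version: 0.1.0
Authors@R:
    person("polxscan", "developers", email = "polxscan@example.org",
           role = c("aut", "cre"))
Description: Tools for alignment-anchored analysis of prokaryotic X-family
    DNA polymerases (PolXs). Maps reference residue numbering (human Pol
    beta) onto multiple sequence alignment columns, classifies each PolX by
    its palm-domain catalytic triad (canonical acidic vs altered), measures
    palm and fingers domain lengths with truncation calls, and profiles
    dNTP-binding-site and PHP nuclease motifs. Also classifies bacterial
    genomes by non-homologous end joining (NHEJ) gene content (Ku, LigD
    domain architecture), tests PolX-NHEJ co-occurrence with Pearson's
    chi-square plus a permutation oracle, extracts co-directional operon
    neighborhoods of PolX genes, and generates synthetic alignments and
    genome tables with planted ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
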