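Package: nucleosig
Title: Nucleosome-Positioning Signatures, Cis-Motif Clusters and miRNA
    Homology Regions in DNA Sequence Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-landscape analysis of regulatory DNA: dinucleotide-usage
    scoring of nucleosome positioning sequences, W/S rotational anisotropy
    tracks, DNA curvature and SymCurv dyad prediction with superhelical
    coordinates, structural alignment of periodic anisotropy tracks by
    normalized cross-correlation, position-weight-matrix cis-motif profiling
    with optimal histogram bin width, ungapped miRNA homology-region scanning
    with nearest-neighbor duplex free energies, GC isochore segmentation, and
    transcript-noise upper-limit statistics.  Ships seeded synthetic-sequence
    and bursty-expression generators so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    grDevices,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
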