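Package: voxconn
Title: Voxel-Wise Degree Centrality and Local Functional Connectivity
    Density for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Graph-theoretic voxel-wise connectivity metrics for 4D
    functional neuroimaging data. Computes binary and weighted degree
    centrality under either a fixed correlation threshold or a sparsity
    target, the latter with a memory-bounded two-level adaptive-histogram
    top-k algorithm that never materialises the full voxel-by-voxel
    correlation matrix. Also computes binary and weighted local functional
    connectivity density (lFCD) by 26-connected region growing, the
    concordance correlation coefficient for validating spatial maps, and
    synthetic 4D fixtures with known block-correlation structure. Reads
    and writes NIfTI-1 volumes and ships a command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), yaml, igraph, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
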