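Package: fedlsh
Title: Privacy-Preserving Federated Similarity Search via Locality-Sensitive Hashing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Federated similarity search for genomic fragments and other
    high-dimensional feature vectors. Clients blind their data with a secret
    scalar and products of random Givens rotations, outsource the
    locality-sensitive hashing (LSH) projection to an untrusted cloud server,
    verify the returned encrypted hash tables with a Freivalds-style random
    contraction, and recover the plaintext projections locally. A data server
    aggregates integer-quantized hash tables from all clients and answers
    k-candidate similarity queries under Euclidean, cosine or L1 ranking.
    Includes a FASTA front-end that numericizes nucleotide sequences and
    slices them into fixed-length overlapping windows with content-addressed
    deduplication, synthetic benchmark generators, and an instrumented
    scalar-multiplication cost account.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    digest,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
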