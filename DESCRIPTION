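Package: dltrace
Title: Linear-Space Damerau-Levenshtein Distance and Optimal Edit Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the unrestricted Damerau-Levenshtein distance between
    two character sequences (protein, DNA/RNA, or arbitrary text) in linear
    space, together with an optimal edit trace listing the substitutions,
    insertions, deletions, and adjacent transpositions that realise it.
    Distance computation uses a refined dynamic-programming recurrence that
    restricts the transposition case, valid for weighted operation costs
    satisfying 2S <= I+D <= 2T; a cache-blocked strip variant processes the
    matrix in vertical blocks.  Trace reconstruction uses Hirschberg-style
    divide and conquer over the final boundary arrays of the linear-space
    pass.  A full-matrix Lowrance-Wagner implementation and a cost-ordered
    search over edit sequences are included as independent references, and a
    small command-line interface accepts inline strings or FASTA records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
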