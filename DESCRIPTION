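Package: phraseminer
Title: Statistical Mining of Coherent Multi-Word Phrases from Title/Abstract Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts coherent multi-word phrases from a corpus of document
    titles and abstracts. Candidate strings bounded by punctuation or stopwords
    are harvested, segmented left-to-right by a chained hypergeometric test on
    contiguous sentence co-occurrence counts (with Benjamini-Hochberg
    correction), and then filtered by whether treating the phrase as a single
    retrieval unit improves BM25 average precision under a title-based
    pseudo-relevance standard. Includes a synthetic-corpus generator with
    planted phrases for end-to-end validation, writers for the released
    phrase-set file formats, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
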