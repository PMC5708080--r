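Package: ndops
Title: Headless N-Dimensional Image Processing Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An extensible application container for headless scientific image
    processing. Provides prioritized plugin registries with per-context
    singleton services, an N-dimensional image data model with array, planar,
    disk-cached cell and function-backed storage layouts, bit-packed pixel
    sample types (including sub-byte and 12-bit integers), a prioritized
    type-converter framework, a typed operation-matching engine with special
    (pre-matched) ops, op chaining (difference of Gaussians, mean as
    sum/size), an expression evaluator, parameterized modules with input
    harvesting and persisted defaults, pluggable Netpbm (PGM/PPM) image
    formats with chunked input/output, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
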