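Package: ngffbench
Title: Chunked Next-Generation Bioimage Formats and a Latency Benchmark
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for chunked, cloud-addressable bioimage storage and for
    measuring what chunking buys. Implements a native reader/writer/validator
    for the next-generation file format layout (Zarr v2 dialect with '/'
    dimension separator, multiscale pyramids, label images, and high-content
    screening plates) over an abstract key-value store; a deterministic
    synthetic dataset generator emulating whole-slide cyclic
    immunofluorescence and light-sheet time-lapse volumes; conversion to and
    from chunked HDF5 and tiled pyramidal BigTIFF; a seeded chunk-access
    latency benchmark with request-count instrumentation and a
    latency-injection backend; and raincloud/trade-off reporting of the
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
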