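Package: ecgcompress
Title: Low-Complexity Lossy ECG Compression with QRS-Detection Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Lossy compression of single-lead electrocardiogram (ECG)
    signals by anti-aliased decimation, together with two benchmark
    compressors (rational-rate B/K resampling and adaptive linear
    prediction), a two-event-related moving-averages (TERMA) QRS detector
    for validating compression quality, beat-detection evaluation metrics
    (sensitivity, positive predictivity, F-score, bit compression ratio,
    percentage root-mean-square difference), and an F-score-driven grid
    search for the decimation factor. Includes WFDB (format 212) and CSV
    record/annotation I/O and a synthetic annotated-ECG generator so the
    full pipeline is testable without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
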