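Package: cropheight
Title: Automatic Crop Height Measurement from Field Camera Images with a
    Striped Reference Marker
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates crop canopy height from daily RGB frames taken by a
    fixed field camera pointed at a striped reference marker bar of known
    length. The visible part of the bar is segmented by computing an
    excess-color index (excess green by default), filtering it with a
    square matched kernel whose negative central column block has the
    marker's pixel width, thresholding the response, and taking the longest
    vertical run of mask pixels as the marker. Visible marker length is
    converted to crop height against an initial calibration frame. Daily
    series can be flagged from rain-gauge and pyranometer logs, corrected
    by interpolation over unreliable frames, and summarised with relative
    error statistics and a Welch t comparison between feature pipelines. A
    seeded synthetic scene generator renders striped-marker field frames
    with known ground truth under five weather conditions for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jpeg,
    yaml,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
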