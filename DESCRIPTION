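Package: socketmap
Title: Rectification Mapping and Design Analysis for Transtibial Prosthetic Sockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns 3D residual-limb scans to CAD/CAM socket designs
    (principal-axis and landmark coarse alignment followed by iterative
    closest point restricted to the anterior sub-patellar region), extracts
    signed rectification maps and eight quantitative design variables per
    socket (seven local rectification sizes and a cross-sectional volume
    reduction), and analyses cohorts of such design profiles with rank
    statistics and a kernel-density-estimate plus Gaussian naive Bayes
    conditional design model that can emit most-probable template
    rectification patterns. Includes a synthetic limb and socket generator
    with known ground truth so the whole pipeline is testable without
    access to patient scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    jsonlite,
    tibble,
    dplyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
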