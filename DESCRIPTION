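Package: motordist
Title: Procrustes-Based Motor Distance Between Movement Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how similarly two individuals move by computing a
    normalized Procrustes distance between their movement repertoires.
    Per-trial wrist kinematics (speed, acceleration, jerk) are time-normalized
    into 10x3 trial matrices, Procrustes-aligned within subject into a single
    representative (FPT) trial, and compared across subjects to yield a
    labelled motor-distance matrix. Includes the surrounding statistical
    machinery: a swap permutation test contrasting within- and between-person
    distances, metric multidimensional scaling with Kruskal stress, intraclass
    correlation robustness under trial subsampling, an RMSE-based individual
    motor signature baseline with a cell-substitution comparison test, and the
    Mantel test for cross-condition agreement. A minimum-jerk reach-to-grasp
    simulator generates synthetic datasets with controllable subject styles
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
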