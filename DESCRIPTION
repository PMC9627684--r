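Package: upvs
Title: Morphometry of the Utero-Placental Vascular Skeleton from 3D Power Doppler
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies first-trimester utero-placental vascular morphology from
    3D power-Doppler ultrasound volumes. Thresholds 8-bit Doppler magnitude data
    inside a manually segmented vascular region to obtain the utero-placental
    vascular volume (uPVV), thins it to a one-voxel-wide centerline skeleton by
    topology-preserving 3D thinning, classifies skeleton voxels by their number
    of 26-connected neighbours (endpoint, vessel, bifurcation, crossing point),
    and derives seven morphologic characteristics plus vascular-branching
    density ratios per placental and vascular volume. Includes synthetic
    vascular phantoms with graph-level ground truth, a longitudinal cohort
    simulator, and the cohort statistics of a first-trimester study design:
    Spearman correlation, principal component analysis, Mann-Whitney U
    comparisons and quadratic-in-gestational-age linear mixed models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    lme4,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
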