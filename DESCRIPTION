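Package: melanoscan
Title: Melanoma Detection from Dermoscopy Images via Reinforcement-Learning
    Segmentation and a Fish-Migration-Optimized SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for melanoma screening on dermoscopy
    images. Lesions are segmented by a Q-learning agent that learns
    threshold and morphology actions against manually segmented training
    masks, with competing agents selecting the sub-image tiling and an
    argmin-dissimilarity rule selecting the post-processing radius.
    Seventeen geometric, texture (gray-level co-occurrence) and statistical
    features plus three Hu invariant moments are extracted from each
    segmented lesion. A binary feature mask is selected by the Enhanced
    Fish Migration Optimizer (EFMO) - a population metaheuristic with age
    stages, energy dynamics, fecundity and motion rules, enhanced by
    opposition-based initialization and a chaotic sine map - over a
    weighted accuracy/Fisher-score cost, and the same optimizer tunes the
    gamma and C parameters of a radial-basis-function support vector
    machine in two stages. Shifted/rotated benchmark functions and a
    seeded comparison harness validate the optimizer itself, and a
    seeded synthetic-lesion generator makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    e1071,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    kernlab
Config/testthat/edition: 3
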