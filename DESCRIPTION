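Package: longlesion
Title: Longitudinal Detection of New Multiple Sclerosis Lesions on FLAIR MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting new multiple sclerosis lesions between two
    co-registered longitudinal FLAIR MRI time-points. Provides brain-like
    phantom generation with lesions, tissue maps and a lesion-probability
    atlas; MRI acquisition-artifact data augmentation (blur, edge
    enhancement, axial subsampling distortion, anisotropic downsampling,
    noise, bias field, and k-space motion, spike and ghosting artifacts);
    synthesis of realistic two-time-point samples with known new-lesion
    masks from single time-point scans via lesion inpainting and lesion
    generation; a siamese-encoder 3D U-Net trained in three stages
    (single-time-point pretraining, synthetic-pair pretraining with a
    frozen encoder, fine-tuning); and voxel-wise and lesion-wise
    evaluation metrics with paired significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
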