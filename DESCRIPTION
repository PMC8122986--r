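Package: mrisr
Title: Two-Stage Tri-Planar GAN Super-Resolution of 3D Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs high-resolution 3D brain MRI volumes from
    half-resolution acquisitions using two successive 2D super-resolution
    passes instead of a 3D convolutional network. Slices of the low-resolution
    volume are taken on the three anatomical planes, upscaled x2 per slice by
    an RFB-ESRGAN generator, and reassembled into a volume whose remaining
    missing voxels (one eighth of the grid) are restored by a second,
    noise-injected same-size generator (nESRGAN) applied slice-wise on all
    three planes. Includes a compact CNN engine with analytic backpropagation,
    relativistic-average GAN losses, PSNR/SSIM evaluation, a synthetic brain
    phantom generator, NIfTI I/O, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
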