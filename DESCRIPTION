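Package: steerable3d
Title: SO(3)-Steerable Voxel Convolutions and Rotation-Equivariant 3D U-Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds rotation-equivariant convolutional networks for 3D
    volumetric (e.g. MRI) segmentation. Features are direct sums of SO(3)
    irreducible representations (scalars, vectors, rank-2 tensors);
    convolution kernels are steerable bases of radial profiles times real
    spherical harmonics reduced by Clebsch-Gordan coefficients, so every
    layer - convolution with self connection, gated nonlinearity, norm
    max-pooling, norm instance normalization, trilinear upsampling - commutes
    exactly with the 24 grid rotations of the cube and approximately with
    arbitrary rotations. Includes a reference (non-equivariant) 3D U-Net,
    a CPU training loop with Adam and early stopping, patch-wise
    Gaussian-weighted inference, Dice evaluation, an equivariance testing
    harness, and a synthetic 3D phantom generator whose structures are
    distinguishable only by spatial cues, for pose-robustness benchmarks
    that need no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
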