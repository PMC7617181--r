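# Synthetic 3D phantoms for pose-robustness benchmarks.
#
# The canonical phantom contains five structures whose joint layout gives
# orientation cues, including one *cue pair*: two spheres with identical
# intensity distributions that can only be told apart by where they sit
# relative to a directional landmark (a capsule with a shell marker at one
# end) - a stand-in for brain structures that are distinguishable only by
# spatial cues. Each generated phantom is the canonical scene in a random
# pose, plus voxel noise.

#' Specification of the synthetic phantom generator
#'
#' Structures (labels 1..5, background 0), at canonical pose, in a volume
#' of side `size` (geometry scales linearly with size):
#' \enumerate{
#'   \item ellipsoid elongated along z (semi-axes 5,5,12 at size 48),
#'   \item capsule along x (half-length 8, radius 4),
#'   \item spherical shell marking the +x end of the capsule,
#'   \item cue sphere near the marked end,
#'   \item cue sphere of identical size and intensity near the unmarked
#'     end.
#' }
#' Structures 4 and 5 share their intensity mean and noise, so their
#' marginal intensity distributions are identical by construction and a
#' voxel-intensity classifier cannot separate them: only their position
#' relative to the shell marker does. The ellipsoid and capsule are also
#' intensity-identical by default, forming a second, shape-keyed cue pair:
#' they differ only in geometry and orientation. Intensity levels of the
#' remaining groups are separated by several noise standard deviations, so
#' the *groups* are easy to segment and structure identity is the
#' spatial-cue part of the task.
#'
#' @param size cubic volume side in voxels (default 48).
#' @param n_channels image channels (default 1, up to 4).
#' @param noise_sd additive Gaussian noise, as a fraction of the
#'   foreground contrast range (default 0.1).
#' @param pose_range poses are drawn as a rotation through a uniform angle
#'   in (-pose_range, pose_range) degrees in a random anatomical plane
#'   (default 15, the "moderate patient placement" regime).
#' @param intensities optional (n_structures+1) x n_channels matrix of
#'   mean intensities (row 1 = background); rows 5 and 6 (the cue pair)
#'   must be identical.
#' @param voxel_range optional 2-column matrix of per-structure (min, max)
#'   admissible voxel counts; defaults to (0.3, 3) times the nominal
#'   count.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(size = 48L, n_channels = 1L, noise_sd = 0.1,
                         pose_range = 15, intensities = NULL,
                         voxel_range = NULL) {
  stopifnot(size >= 24, n_channels >= 1, n_channels <= 4, noise_sd >= 0)
  base_int <- cbind(c(0, 0.8, 0.8, 1.2, 0.45, 0.45),
                    c(0, 0.5, 0.5, 0.9, 1.00, 1.00),
                    c(0, 1.0, 1.0, 0.4, 0.70, 0.70),
                    c(0, 0.6, 0.6, 1.1, 0.30, 0.30))
  if (is.null(intensities)) intensities <- base_int[, seq_len(n_channels),
                                                    drop = FALSE]
  if (any(intensities[5, ] != intensities[6, ]))
    stop("cue-pair structures must have identical intensities")
  s <- size / 48
  structures <- list(
    list(name = "ellipsoid", type = "ellipsoid",
         center = c(0, -9, 0) * s, semi = c(5, 5, 12) * s),
    list(name = "capsule", type = "capsule",
         center = c(0, 9, 0) * s, half_len = 8 * s, radius = 4 * s),
    list(name = "shell", type = "shell",
         center = c(14, 9, 0) * s, r_out = 4.5 * s, r_in = 2.5 * s),
    list(name = "cue_marked", type = "sphere",
         center = c(10, 16, 0) * s, radius = 4 * s),
    list(name = "cue_unmarked", type = "sphere",
         center = c(-10, 16, 0) * s, radius = 4 * s)
  )
  # farthest structure point must stay inside under any rotation
  reach <- max(vapply(structures, function(st) {
    sqrt(sum(st$center^2)) + switch(st$type, ellipsoid = max(st$semi),
                                    capsule = st$half_len + st$radius,
                                    shell = st$r_out, sphere = st$radius)
  }, 0))
  if (reach > size / 2 - 0.5) stop("structures cannot fit the volume")
  if (is.null(voxel_range)) {
    nominal <- c(4 / 3 * pi * prod(c(5, 5, 12) * s),
                 pi * (4 * s)^2 * 16 * s + 4 / 3 * pi * (4 * s)^3,
                 4 / 3 * pi * ((4.5 * s)^3 - (2.5 * s)^3),
                 4 / 3 * pi * (4 * s)^3,
                 4 / 3 * pi * (4 * s)^3)
    voxel_range <- cbind(floor(0.3 * nominal), ceiling(3 * nominal))
  }
  structure(list(size = as.integer(size), n_channels = as.integer(n_channels),
                 noise_sd = noise_sd, pose_range = pose_range,
                 intensities = intensities, structures = structures,
                 voxel_range = voxel_range, cue_pair = c(4L, 5L)),
            class = "phantom_spec")
}

# canonical (unrotated, noise-free) label map of a spec
phantom_canonical_labels <- function(spec) {
  n <- spec$size
  g <- seq_len(n) - (n + 1) / 2
  X <- array(rep(g, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(g, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(g, each = n * n), dim = c(n, n, n))
  lab <- array(0L, dim = c(n, n, n))
  for (k in seq_along(spec$structures)) {
    st <- spec$structures[[k]]
    xc <- X - st$center[1]; yc <- Y - st$center[2]; zc <- Z - st$center[3]
    inside <- switch(st$type,
      ellipsoid = (xc / st$semi[1])^2 + (yc / st$semi[2])^2 +
        (zc / st$semi[3])^2 <= 1,
      sphere = xc^2 + yc^2 + zc^2 <= st$radius^2,
      shell = {
        r2 <- xc^2 + yc^2 + zc^2
        r2 <= st$r_out^2 & r2 >= st$r_in^2
      },
      capsule = {
        ax <- pmin(pmax(xc, -st$half_len), st$half_len)
        (xc - ax)^2 + yc^2 + zc^2 <= st$radius^2
      })
    lab[inside] <- k
  }
  lab
}

#' Generate one labeled phantom volume
#'
#' Deterministic given (spec, seed). The canonical scene is posed by a
#' random in-plane rotation (cubic resampling for intensities, nearest
#' neighbor for labels), then channel intensities and additive Gaussian
#' noise are applied.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return list with `image` (n_channels, D, H, W), `labels` (D, H, W)
#'   integer array with values 0..5, and `pose` (plane, angle in degrees).
#' @export
generate_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  lab0 <- phantom_canonical_labels(spec)
  plane <- sample(c("axial", "coronal", "sagittal"), 1)
  angle <- stats::runif(1, -spec$pose_range, spec$pose_range)
  R <- plane_rotation(angle, plane)
  lab <- if (spec$pose_range == 0) lab0 else
    array(as.integer(rotate_volume(lab0, R, "nearest")), dim = dim(lab0))
  n <- spec$size
  img <- array(0, dim = c(spec$n_channels, n, n, n))
  for (c in seq_len(spec$n_channels)) {
    base <- array(spec$intensities[lab0 + 1L, c], dim = dim(lab0))
    ch <- if (spec$pose_range == 0) base else rotate_volume(base, R, "cubic")
    img[c, , , ] <- ch + stats::rnorm(length(ch), sd = spec$noise_sd)
  }
  counts <- tabulate(lab, nbins = length(spec$structures))
  for (k in seq_along(counts)) {
    if (counts[k] < spec$voxel_range[k, 1] || counts[k] > spec$voxel_range[k, 2])
      stop("structure ", k, " voxel count ", counts[k],
           " outside configured range")
  }
  list(image = img, labels = lab, pose = list(plane = plane, angle = angle),
       seed = seed)
}

#' Generate reproducible train/validation/test phantom splits
#'
#' Splits get disjoint per-volume seeds derived from the master seed.
#' Training and validation poses are drawn from the spec's (narrow) pose
#' range; test poses from `test_pose_range` (same narrow range by
#' default - pose robustness is probed afterwards by rotating the test
#' volumes with the harness).
#'
#' @param spec a [phantom_spec()].
#' @param n_train,n_val,n_test split sizes.
#' @param seed master seed.
#' @param test_pose_range pose range for the test split (default: the
#'   spec's).
#' @return list with elements `train`, `val`, `test` (lists of phantoms)
#'   and `seeds`.
#' @export
generate_dataset <- function(spec, n_train, n_val, n_test, seed,
                             test_pose_range = spec$pose_range) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_train + n_val + n_test)
  spec_test <- spec; spec_test$pose_range <- test_pose_range
  gen <- function(sds, sp) lapply(sds, function(s) generate_phantom(sp, s))
  list(train = gen(seeds[seq_len(n_train)], spec),
       val = gen(seeds[n_train + seq_len(n_val)], spec),
       test = gen(seeds[n_train + n_val + seq_len(n_test)], spec_test),
       seeds = seeds)
}

#' Save a phantom as a NIfTI pair with a JSON sidecar
#'
#' Writes `<prefix>_image.nii.gz` (channels along the 4th dimension),
#' `<prefix>_labels.nii.gz` and `<prefix>.json` (pose and seed).
#'
#' @param phantom result of [generate_phantom()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
save_phantom <- function(phantom, prefix) {
  img <- aperm(phantom$image, c(2, 3, 4, 1))
  if (dim(img)[4] == 1) img <- array(img, dim = dim(img)[1:3])
  RNifti::writeNifti(img, paste0(prefix, "_image.nii.gz"))
  RNifti::writeNifti(phantom$labels, paste0(prefix, "_labels.nii.gz"))
  jsonlite::write_json(list(pose = phantom$pose, seed = phantom$seed),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Load a phantom saved by [save_phantom()]
#' @param prefix the path prefix used when saving.
#' @return list with `image`, `labels`, and sidecar metadata if present.
#' @export
load_phantom <- function(prefix) {
  img <- as.array(RNifti::readNifti(paste0(prefix, "_image.nii.gz")))
  if (length(dim(img)) == 3) img <- array(img, dim = c(dim(img), 1))
  img <- aperm(img, c(4, 1, 2, 3))
  lab <- as.array(RNifti::readNifti(paste0(prefix, "_labels.nii.gz")))
  out <- list(image = img, labels = array(as.integer(lab), dim = dim(lab)))
  side <- paste0(prefix, ".json")
  if (file.exists(side))
    out <- c(out, jsonlite::read_json(side, simplifyVector = TRUE))
  out
}
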