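# Rotating volumes and irrep fields, and measuring equivariance.

#' Match a rotation against the 24 octahedral grid rotations
#' @param R 3x3 rotation matrix.
#' @param tol matching tolerance.
#' @return the exact signed permutation matrix, or NULL if R is not a
#'   grid rotation.
#' @export
as_octahedral_rotation <- function(R, tol = 1e-9) {
  for (Q in octahedral_rotations())
    if (max(abs(R - Q)) < tol) return(Q)
  NULL
}

# exact grid rotation of a channels-first array: out[., v] = in[., R^T v]
# about the volume center. Requires a cubic grid unless R is the identity.
grid_rotate <- function(x, R) {
  Q <- as_octahedral_rotation(R)
  if (is.null(Q)) stop("exact-grid rotation requires an octahedral rotation")
  if (all(Q == diag(3))) return(x)
  d <- dim(x); sp <- d[-1]
  if (length(unique(sp)) != 1) stop("exact-grid rotation requires a cubic grid")
  n <- sp[1]; cen <- (n + 1) / 2
  g <- seq_len(n) - cen
  # source coordinate u = Q^T v for every output voxel v (axes x, y, z)
  V <- cbind(rep(g, times = n * n), rep(rep(g, each = n), times = n),
             rep(g, each = n * n))
  U <- V %*% Q                          # = t(Q^T %*% t(V))
  src <- (U[, 1] + cen) + n * (U[, 2] + cen - 1) + n * n * (U[, 3] + cen - 1)
  xm <- matrix(x, d[1])
  array(xm[, as.integer(round(src)), drop = FALSE], dim = d)
}

# block-diagonal Wigner action on the feature axis of a values array
wigner_field_transform <- function(values, ir, R) {
  ent <- irreps(ir)$entries
  sl <- irreps_slices(ir)
  out <- values
  for (e in seq_len(nrow(ent))) {
    l <- ent$l[e]
    if (l == 0) next
    d <- 2L * l + 1L; m <- ent$mul[e]
    D <- wigner_block(l, R)
    N <- prod(dim(values)[-1])
    blk <- array(values[sl[[e]], , , , drop = FALSE], dim = c(d, m * N))
    out[sl[[e]], , , ] <- array(D %*% blk, dim = c(d * m, dim(values)[-1]))
  }
  out
}

# Catmull-Rom cubic interpolation weights for fractional offset t in [0,1)
catmull_rom_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  list(wm1 = 0.5 * (-t + 2 * t2 - t3),
       w0 = 0.5 * (2 - 5 * t2 + 3 * t3),
       w1 = 0.5 * (t + 4 * t2 - 3 * t3),
       w2 = 0.5 * (-t2 + t3))
}

# resample one 3D volume at rotated coordinates: out(v) = in(R^T (v - c) + c)
resample_rotated <- function(vol, R, interpolation = "cubic", fill = 0) {
  d <- dim(vol)
  cen <- (d + 1) / 2
  gx <- seq_len(d[1]) - cen[1]; gy <- seq_len(d[2]) - cen[2]
  gz <- seq_len(d[3]) - cen[3]
  N <- prod(d)
  V <- cbind(rep(gx, times = d[2] * d[3]),
             rep(rep(gy, each = d[1]), times = d[3]),
             rep(gz, each = d[1] * d[2]))
  U <- V %*% R                           # row-wise R^T v
  cx <- U[, 1] + cen[1]; cy <- U[, 2] + cen[2]; cz <- U[, 3] + cen[3]
  outside <- cx < 1 | cx > d[1] | cy < 1 | cy > d[2] | cz < 1 | cz > d[3]
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  flat <- function(ix, iy, iz)
    clamp(ix, d[1]) + d[1] * (clamp(iy, d[2]) - 1L) +
      d[1] * d[2] * (clamp(iz, d[3]) - 1L)
  if (interpolation == "nearest") {
    out <- vol[flat(as.integer(round(cx)), as.integer(round(cy)),
                    as.integer(round(cz)))]
  } else if (interpolation == "linear") {
    ix <- floor(cx); iy <- floor(cy); iz <- floor(cz)
    tx <- cx - ix; ty <- cy - iy; tz <- cz - iz
    out <- numeric(N)
    for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
      w <- (if (ox == 0) 1 - tx else tx) * (if (oy == 0) 1 - ty else ty) *
        (if (oz == 0) 1 - tz else tz)
      out <- out + w * vol[flat(ix + ox, iy + oy, iz + oz)]
    }
  } else if (interpolation == "cubic") {
    ix <- floor(cx); iy <- floor(cy); iz <- floor(cz)
    wx <- catmull_rom_weights(cx - ix)
    wy <- catmull_rom_weights(cy - iy)
    wz <- catmull_rom_weights(cz - iz)
    wl <- function(w, o) switch(as.character(o), "-1" = w$wm1, "0" = w$w0,
                                "1" = w$w1, "2" = w$w2)
    out <- numeric(N)
    for (ox in -1:2) for (oy in -1:2) for (oz in -1:2) {
      w <- wl(wx, ox) * wl(wy, oy) * wl(wz, oz)
      out <- out + w * vol[flat(ix + ox, iy + oy, iz + oz)]
    }
  } else stop("unknown interpolation ", interpolation)
  out[outside] <- fill
  array(out, dim = d)
}

#' Rotate a 3D volume (or multi-channel volume) about its center
#'
#' Octahedral rotations (all multiples of 90 degrees about the axes) are
#' applied as exact grid permutations regardless of the interpolation
#' setting; other rotations are resampled with Catmull-Rom cubic splines
#' (`"cubic"`, for images), trilinear (`"linear"`) or nearest-neighbor
#' (`"nearest"`, for integer label maps). Out-of-field voxels get `fill`.
#'
#' @param vol (D, H, W) or (C, D, H, W) array.
#' @param rotation 3x3 rotation matrix.
#' @param interpolation "cubic", "linear" or "nearest".
#' @param fill background value.
#' @return the rotated array, same shape.
#' @export
rotate_volume <- function(vol, rotation, interpolation = "cubic", fill = 0) {
  check_rotation(rotation)
  three_d <- length(dim(vol)) == 3
  if (three_d) vol <- array(vol, dim = c(1, dim(vol)))
  Q <- as_octahedral_rotation(rotation)
  out <- if (!is.null(Q) &&
             (all(Q == diag(3)) || length(unique(dim(vol)[-1])) == 1)) {
    grid_rotate(vol, Q)
  } else {
    y <- vol
    for (c in seq_len(dim(vol)[1]))
      y[c, , , ] <- resample_rotated(array(vol[c, , , ], dim(vol)[-1]),
                                     rotation, interpolation, fill)
    y
  }
  if (three_d) array(out, dim = dim(out)[-1]) else out
}

#' Rotate an irrep field: move the grid and rotate the features
#'
#' Implements the transformation law f'(x) = rho(r) f(r^-1 x): the grid is
#' resampled (an exact permutation for octahedral rotations in
#' `"exact-grid"` mode, spline interpolation otherwise) and each order-l
#' channel is multiplied by the Wigner block D^l(r).
#'
#' @param field an [irrep_field()].
#' @param rotation 3x3 rotation matrix.
#' @param mode `"exact-grid"` (requires an octahedral rotation and a cubic
#'   grid) or `"interpolated"` (cubic spline resampling).
#' @return the rotated `irrep_field`.
#' @export
rotate_irrep_field <- function(field, rotation,
                               mode = c("exact-grid", "interpolated")) {
  mode <- match.arg(mode)
  check_rotation(rotation)
  vals <- if (mode == "exact-grid") {
    if (is.null(as_octahedral_rotation(rotation)))
      stop("exact-grid mode requires one of the 24 octahedral rotations")
    grid_rotate(field$values, rotation)
  } else {
    rotate_volume(field$values, rotation, interpolation = "cubic")
  }
  irrep_field(field$irreps, wigner_field_transform(vals, field$irreps,
                                                   rotation))
}

#' Relative equivariance error of a layer or model
#'
#' Computes `||L(rho f) - rho(L f)|| / max(||L(rho f)||, ||rho(L f)||,
#' tiny)` with the field-wide Euclidean norm, where rho rotates grid and
#' features. A per-irrep-entry breakdown is attached as attribute
#' `"per_entry"`.
#'
#' @param fn a function mapping an `irrep_field` to an `irrep_field`.
#' @param field the input `irrep_field`.
#' @param rotation 3x3 rotation matrix.
#' @param mode rotation mode, see [rotate_irrep_field()].
#' @return non-negative scalar.
#' @export
equivariance_error <- function(fn, field, rotation, mode = "exact-grid") {
  a <- fn(rotate_irrep_field(field, rotation, mode))
  b <- rotate_irrep_field(fn(field), rotation, mode)
  num <- sqrt(sum((a$values - b$values)^2))
  den <- max(sqrt(sum(a$values^2)), sqrt(sum(b$values^2)), 1e-30)
  err <- num / den
  ent <- a$irreps$entries; sl <- irreps_slices(a$irreps)
  per <- vapply(seq_len(nrow(ent)), function(e) {
    da <- a$values[sl[[e]], , , , drop = FALSE]
    db <- b$values[sl[[e]], , , , drop = FALSE]
    sqrt(sum((da - db)^2)) / max(sqrt(sum(da^2)), sqrt(sum(db^2)), 1e-30)
  }, 0)
  names(per) <- sprintf("%dx%d", ent$mul, ent$l)
  attr(err, "per_entry") <- per
  err
}

#' In-plane rotation matrix for a named anatomical plane
#' @param angle_deg rotation angle in degrees.
#' @param plane "axial" (about z), "coronal" (about y) or "sagittal"
#'   (about x).
#' @return 3x3 rotation matrix.
#' @export
plane_rotation <- function(angle_deg, plane = c("axial", "coronal",
                                                "sagittal")) {
  plane <- match.arg(plane)
  axis <- switch(plane, axial = c(0, 0, 1), coronal = c(0, 1, 0),
                 sagittal = c(1, 0, 0))
  rotation_axis_angle(axis, angle_deg * pi / 180)
}

#' Dice-vs-rotation-angle robustness curve
#'
#' Rotates every test volume (cubic spline) and its labels (nearest
#' neighbor) through each angle in the given plane, predicts with the
#' model, and tabulates the per-structure Dice; multiples of 90 degrees
#' are applied as exact grid permutations, so there the reference labels
#' are interpolation-free.
#'
#' @param model a trained `unet_model`.
#' @param dataset list of `list(image, labels)` volumes.
#' @param angles rotation angles in degrees.
#' @param plane rotation plane, see [plane_rotation()].
#' @param structures label values to score (default: all nonzero labels of
#'   the first volume).
#' @param ... passed to [predict_patchwise()].
#' @return data.frame with columns `angle`, `structure`, `dice` (mean over
#'   volumes).
#' @export
robustness_curve <- function(model, dataset, angles, plane = "axial",
                             structures = NULL, ...) {
  if (length(dataset) == 0) stop("empty dataset")
  if (is.null(structures))
    structures <- sort(setdiff(unique(as.vector(dataset[[1]]$labels)), 0))
  rows <- list()
  for (ang in angles) {
    R <- plane_rotation(ang, plane)
    acc <- matrix(0, length(dataset), length(structures))
    for (v in seq_along(dataset)) {
      img <- rotate_volume(dataset[[v]]$image, R, "cubic")
      lab <- rotate_volume(dataset[[v]]$labels, R, "nearest")
      pred <- predict_patchwise(model, img, ...)
      acc[v, ] <- vapply(structures, function(s)
        dice_score(pred$labels, lab, s), 0)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      angle = ang, structure = structures, dice = colMeans(acc))
  }
  do.call(rbind, rows)
}
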