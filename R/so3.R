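# package-level cache for Wigner fit factors and Clebsch-Gordan blocks
.so3_cache <- new.env(parent = emptyenv())

#' Selection rule for tensor-product paths
#'
#' Returns the harmonic orders l through which an order `l_in` feature can
#' feed an order `l_out` feature: all integers with
#' |l_in - l_out| <= l <= min(l_in + l_out, l_max), ascending.
#'
#' @param l_in,l_out,l_max non-negative integer orders.
#' @return integer vector (possibly empty).
#' @export
allowed_paths <- function(l_in, l_out, l_max) {
  stopifnot(l_in >= 0, l_out >= 0, l_max >= 0)
  lo <- abs(l_in - l_out)
  hi <- min(l_in + l_out, l_max)
  if (hi < lo) return(integer(0))
  seq.int(lo, hi)
}

#' Real spherical harmonics
#'
#' Evaluates the orthonormal real spherical harmonics of order l
#' (component ordering m = -l..l, Condon-Shortley phase omitted) at a set
#' of directions. Non-unit directions are normalized; a zero vector is an
#' error. Normalization: integral of Y_lm^2 over the unit sphere is 1.
#'
#' @param l order, 0 <= l <= 4.
#' @param directions 3 x N matrix (columns are directions) or a length-3
#'   vector.
#' @return (2l+1) x N matrix.
#' @export
real_spherical_harmonics <- function(l, directions) {
  if (is.vector(directions)) directions <- matrix(directions, nrow = 3)
  stopifnot(nrow(directions) == 3, l >= 0, l <= 4)
  nrm <- sqrt(colSums(directions^2))
  if (any(nrm < 1e-12)) stop("degenerate direction: zero-length vector")
  u <- sweep(directions, 2, nrm, "/")
  x <- u[1, ]; y <- u[2, ]; z <- u[3, ]
  sp <- sqrt(pi)
  out <- switch(as.character(l),
    "0" = rbind(rep(1 / (2 * sp), length(x))),
    "1" = sqrt(3) / (2 * sp) * rbind(y, z, x),
    "2" = rbind(
      sqrt(15) / (2 * sp) * x * y,
      sqrt(15) / (2 * sp) * y * z,
      sqrt(5) / (4 * sp) * (3 * z^2 - 1),
      sqrt(15) / (2 * sp) * x * z,
      sqrt(15) / (4 * sp) * (x^2 - y^2)
    ),
    "3" = rbind(
      sqrt(35 / 2) / (4 * sp) * y * (3 * x^2 - y^2),
      sqrt(105) / (2 * sp) * x * y * z,
      sqrt(21 / 2) / (4 * sp) * y * (5 * z^2 - 1),
      sqrt(7) / (4 * sp) * z * (5 * z^2 - 3),
      sqrt(21 / 2) / (4 * sp) * x * (5 * z^2 - 1),
      sqrt(105) / (4 * sp) * z * (x^2 - y^2),
      sqrt(35 / 2) / (4 * sp) * x * (x^2 - 3 * y^2)
    ),
    "4" = rbind(
      3 * sqrt(35) / (4 * sp) * x * y * (x^2 - y^2),
      3 * sqrt(35 / 2) / (4 * sp) * y * z * (3 * x^2 - y^2),
      3 * sqrt(5) / (4 * sp) * x * y * (7 * z^2 - 1),
      3 * sqrt(5 / 2) / (4 * sp) * y * z * (7 * z^2 - 3),
      (3 / (16 * sp)) * (35 * z^4 - 30 * z^2 + 3),
      3 * sqrt(5 / 2) / (4 * sp) * x * z * (7 * z^2 - 3),
      3 * sqrt(5) / (8 * sp) * (x^2 - y^2) * (7 * z^2 - 1),
      3 * sqrt(35 / 2) / (4 * sp) * x * z * (x^2 - 3 * y^2),
      3 * sqrt(35) / (16 * sp) * (x^4 - 6 * x^2 * y^2 + y^4)
    ),
    stop("spherical harmonics implemented for l <= 4")
  )
  unname(out)
}

#' Validate a rotation matrix
#' @param R 3x3 matrix.
#' @param tol orthogonality tolerance.
#' @return R, invisibly; errors if not a proper rotation.
#' @keywords internal
#' @export
check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)))
    stop("rotation must be a 3x3 matrix")
  if (max(abs(R %*% t(R) - diag(3))) > tol)
    stop("invalid rotation: matrix is not orthogonal")
  if (det(R) < 0) stop("invalid rotation: determinant is negative (reflection)")
  invisible(R)
}

#' Rotation matrix from axis and angle
#' @param axis length-3 vector (normalized internally).
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# deterministic well-spread unit vectors (Fibonacci sphere)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  rbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

wigner_fit_factor <- function(l) {
  key <- paste0("wfit_", l)
  if (!is.null(.so3_cache[[key]])) return(.so3_cache[[key]])
  U <- fibonacci_sphere(3L * (2L * l + 1L) + 6L)
  A <- real_spherical_harmonics(l, U)
  # right pseudo-inverse of A: D = Y(RU) %*% pinv reproduces D exactly
  pinv <- t(A) %*% solve(A %*% t(A))
  val <- list(U = U, pinv = pinv)
  .so3_cache[[key]] <- val
  val
}

#' Wigner rotation block for real irreps
#'
#' The (2l+1) x (2l+1) orthogonal matrix D^l(R) by which an order-l real
#' feature transforms, in the package's real m = -l..l basis: it satisfies
#' Y^l(R u) = D^l(R) Y^l(u). Computed by expressing the rotated harmonics
#' in the unrotated harmonic basis over a fixed point set (the degree-l
#' harmonics span a rotation-invariant space, so the fit is exact up to
#' round-off).
#'
#' @param l order (0..4).
#' @param rotation 3x3 proper rotation matrix.
#' @return (2l+1) x (2l+1) orthogonal matrix.
#' @export
wigner_block <- function(l, rotation) {
  check_rotation(rotation)
  if (l == 0) return(matrix(1, 1, 1))
  f <- wigner_fit_factor(l)
  real_spherical_harmonics(l, rotation %*% f$U) %*% f$pinv
}

#' Real Clebsch-Gordan coefficient block
#'
#' The 3-index block C of shape (2l1+1, 2l2+1, 2l3+1) reducing the tensor
#' product of real irreps l1 and l2 into l3. It is the (unique for SO(3))
#' solution of the intertwiner constraint
#' `(D^l1(R) x D^l2(R)) C = C D^l3(R)` for all rotations R, computed as
#' the null space of that constraint stacked over fixed generic rotations,
#' normalized to unit Frobenius norm with the largest-magnitude entry
#' positive. If the selection rule |l1-l2| <= l3 <= l1+l2 fails the block
#' is all zero. In this convention the (1,1,0) block is the Euclidean dot
#' product scaled by 1/sqrt(3) and the (1,1,1) block is proportional to
#' the fully antisymmetric cross-product form (entries of magnitude
#' 1/sqrt(6)).
#'
#' @param l1,l2,l3 orders (each <= 4).
#' @return numeric array of dim (2l1+1, 2l2+1, 2l3+1).
#' @export
clebsch_gordan <- function(l1, l2, l3) {
  d1 <- 2L * l1 + 1L; d2 <- 2L * l2 + 1L; d3 <- 2L * l3 + 1L
  if (l3 < abs(l1 - l2) || l3 > l1 + l2)
    return(array(0, dim = c(d1, d2, d3)))
  key <- paste("cg", l1, l2, l3, sep = "_")
  if (!is.null(.so3_cache[[key]])) return(.so3_cache[[key]])
  rots <- list(
    rotation_axis_angle(c(1, 2, 3), 0.7123),
    rotation_axis_angle(c(-2, 1, 0.5), 1.3931),
    rotation_axis_angle(c(0.3, -1.1, 2.2), 2.0177)
  )
  blocks <- lapply(rots, function(R) {
    D1 <- wigner_block(l1, R); D2 <- wigner_block(l2, R)
    D3 <- wigner_block(l3, R)
    D12 <- kronecker(D2, D1)          # row index (a,b), a fastest
    kronecker(diag(d3), D12) - kronecker(t(D3), diag(d1 * d2))
  })
  M <- do.call(rbind, blocks)
  sv <- svd(M)
  vals <- sv$d
  n <- length(vals)
  if (vals[n] > 1e-8) stop("no Clebsch-Gordan intertwiner found")
  if (n > 1 && vals[n - 1] < 1e-4) stop("Clebsch-Gordan null space not unique")
  v <- sv$v[, n]
  imax <- which.max(abs(v))
  v <- v * sign(v[imax])
  C <- array(v, dim = c(d1, d2, d3))
  .so3_cache[[key]] <- C
  C
}

#' The 24 orientation-preserving symmetries of the cube
#'
#' All 3x3 signed permutation matrices with determinant +1: the rotations
#' that map a cubic voxel grid onto itself, used for exact (interpolation
#' free) equivariance tests.
#'
#' @return list of 24 rotation matrices, the first being the identity.
#' @export
octahedral_rotations <- function() {
  if (!is.null(.so3_cache[["octa"]])) return(.so3_cache[["octa"]])
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    P <- diag(3)[p, , drop = FALSE]
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      R <- diag(c(s1, s2, s3)) %*% P
      if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1L]] <- R
    }
  }
  # identity first, deterministic order otherwise
  is_id <- vapply(out, function(R) all(R == diag(3)), TRUE)
  out <- c(out[is_id], out[!is_id])
  .so3_cache[["octa"]] <- out
  out
}
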