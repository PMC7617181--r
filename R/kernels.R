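#' Enumerate tensor-product paths between two irreps
#'
#' A path `{i x l -> j}` connects input channel i (order l_i) to output
#' channel j (order l_j) through harmonic order l, for every l allowed by
#' the selection rule |l_i - l_j| <= l <= min(l_i + l_j, l_max). The
#' table is complete and duplicate-free, ordered by (i, j, l).
#'
#' @param irreps_in,irreps_out input/output feature types.
#' @param l_max maximum harmonic order (default 4).
#' @return data.frame with columns `i`, `l_i`, `l`, `j`, `l_j`.
#' @export
enumerate_paths <- function(irreps_in, irreps_out, l_max = 4L) {
  ci <- irreps_channels(irreps(irreps_in))
  co <- irreps_channels(irreps(irreps_out))
  rows <- list()
  for (i in seq_len(nrow(ci))) for (j in seq_len(nrow(co))) {
    for (l in allowed_paths(ci$l[i], co$l[j], l_max)) {
      rows[[length(rows) + 1L]] <-
        data.frame(i = i, l_i = ci$l[i], l = l, j = j, l_j = co$l[j])
    }
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(0), l_i = integer(0), l = integer(0),
                      j = integer(0), l_j = integer(0)))
  do.call(rbind, rows)
}

# centered integer grid offsets of an S^3 kernel, x fastest (column-major)
kernel_offsets <- function(S) {
  p <- (S - 1L) / 2L
  g <- seq.int(-p, p)
  cbind(x = rep(g, times = S * S),
        y = rep(rep(g, each = S), times = S),
        z = rep(g, each = S * S))
}

#' Sample the steerable kernel basis on a voxel grid
#'
#' For each group of paths sharing orders (l_i, l, l_j) and each radial
#' index k, samples the continuous steerable basis function
#' `b_k(|a|) * [CG(l_i, l, l_j) contracted with Y^l(a/|a|)]`
#' at the integer offsets a of a centered S^3 grid. The center sample is
#' exactly zero (the radial basis vanishes at the origin). Input and
#' output irreps must be in canonical grouped form (ascending order, one
#' entry per order) so that channels of equal order occupy contiguous
#' feature rows.
#'
#' @param irreps_in,irreps_out feature types (canonical form).
#' @param S odd kernel size.
#' @param profile a [radial_profile()]; default `radial_profile(5,
#'   kernel_r_max(S))`. Its cutoff must not exceed the grid circumradius.
#' @param l_max maximum harmonic order (default 4).
#' @return object of class `kernel_basis` with per-(l_i,l,l_j) basis
#'   blocks of shape (2l_j+1, 2l_i+1, S^3, K) and the channel-level path
#'   table.
#' @export
sample_kernel_basis <- function(irreps_in, irreps_out, S, profile = NULL,
                                l_max = 4L) {
  if (S %% 2 == 0) stop("unsupported kernel size: S must be odd")
  irreps_in <- irreps(irreps_in); irreps_out <- irreps(irreps_out)
  ein <- irreps_in$entries; eout <- irreps_out$entries
  if (any(duplicated(ein$l)) || is.unsorted(ein$l) ||
      any(duplicated(eout$l)) || is.unsorted(eout$l))
    stop("kernel basis requires canonical grouped irreps")
  if (is.null(profile)) profile <- radial_profile(5L, kernel_r_max(S))
  if (profile$r_max > kernel_r_max(S) + 1e-9)
    stop("radial cutoff exceeds the kernel grid circumradius")
  offs <- kernel_offsets(S)
  r <- sqrt(rowSums(offs^2))
  B_rad <- radial_profile_values(profile, r)          # K x S^3
  nonzero <- r > 0
  dirs <- t(offs[nonzero, , drop = FALSE]) / rep(r[nonzero], each = 3)
  sl_in <- irreps_slices(irreps_in); sl_out <- irreps_slices(irreps_out)
  K <- profile$K; S3 <- nrow(offs)
  groups <- list()
  for (ei in seq_len(nrow(ein))) for (eo in seq_len(nrow(eout))) {
    li <- ein$l[ei]; lj <- eout$l[eo]
    di <- 2L * li + 1L; dj <- 2L * lj + 1L
    for (l in allowed_paths(li, lj, l_max)) {
      C <- clebsch_gordan(li, l, lj)                  # (di, dl, dj)
      Y <- matrix(0, 2L * l + 1L, S3)
      Y[, nonzero] <- real_spherical_harmonics(l, dirs)
      # ang[pj, pi, s] = sum_m C[pi, m, pj] Y[m, s]
      Cm <- matrix(aperm(C, c(3, 1, 2)), dj * di, 2L * l + 1L)
      ang <- array(Cm %*% Y, dim = c(dj, di, S3))
      B <- array(0, dim = c(dj, di, S3, K))
      for (k in seq_len(K))
        B[, , , k] <- ang * rep(B_rad[k, ], each = dj * di)
      key <- paste(li, l, lj, sep = "_")
      groups[[key]] <- list(
        li = li, l = l, lj = lj, di = di, dj = dj,
        ni = ein$mul[ei], nj = eout$mul[eo],
        in_rows = sl_in[[ei]], out_rows = sl_out[[eo]],
        B = B
      )
    }
  }
  structure(list(
    irreps_in = irreps_in, irreps_out = irreps_out, S = S,
    profile = profile, l_max = as.integer(l_max), groups = groups,
    paths = enumerate_paths(irreps_in, irreps_out, l_max)
  ), class = "kernel_basis")
}

#' Blank weight set for a kernel basis
#'
#' One real weight per (radial index k, path); stored grouped as arrays
#' of shape (K, n_in_channels, n_out_channels) per (l_i, l, l_j) group.
#'
#' @param basis a [sample_kernel_basis()] result.
#' @param fill initial value.
#' @return named list of weight arrays (class `kernel_weights`).
#' @export
new_kernel_weights <- function(basis, fill = 0) {
  stopifnot(inherits(basis, "kernel_basis"))
  w <- lapply(basis$groups, function(g)
    array(fill, dim = c(basis$profile$K, g$ni, g$nj)))
  structure(w, class = "kernel_weights")
}

#' Total number of kernel weights of a basis
#' @keywords internal
#' @export
kernel_weights_length <- function(basis) {
  sum(vapply(basis$groups, function(g) basis$profile$K * g$ni * g$nj, 0))
}

# coerce a flat numeric vector into grouped kernel weights (k fastest,
# then input channel, then output channel, groups in basis order)
kernel_weights_from_vector <- function(basis, v) {
  if (length(v) != kernel_weights_length(basis))
    stop("weight length mismatch: expected ", kernel_weights_length(basis))
  out <- new_kernel_weights(basis)
  at <- 0L
  for (key in names(basis$groups)) {
    n <- length(out[[key]])
    out[[key]][] <- v[at + seq_len(n)]
    at <- at + n
  }
  out
}

#' Assemble a dense convolution kernel from basis and weights
#'
#' The linear combination `sum_k w(k, path) * basis_block(path, k)` placed
#' at the channel slices of each path, giving an ordinary CNN kernel that
#' evaluates the equivariant convolution exactly (the "precomputed"
#' network).
#'
#' @param basis a `kernel_basis`.
#' @param weights a `kernel_weights` list or flat numeric vector.
#' @return array of dim (dim_out, dim_in, S, S, S).
#' @export
assemble_kernel <- function(basis, weights) {
  if (is.numeric(weights)) weights <- kernel_weights_from_vector(basis, weights)
  S <- basis$S; S3 <- S^3
  dout <- irreps_dim(basis$irreps_out); din <- irreps_dim(basis$irreps_in)
  kern <- array(0, dim = c(dout, din, S3))
  K <- basis$profile$K
  for (key in names(basis$groups)) {
    g <- basis$groups[[key]]
    w <- weights[[key]]
    if (is.null(w)) stop("weights missing group ", key)
    if (!all(dim(w) == c(K, g$ni, g$nj))) stop("weight shape mismatch in ", key)
    Bm <- matrix(g$B, ncol = K)                        # (dj*di*S3) x K
    Rm <- Bm %*% matrix(w, nrow = K)                   # ... x (ni*nj)
    Ra <- array(Rm, dim = c(g$dj, g$di, S3, g$ni, g$nj))
    blk <- aperm(Ra, c(1, 5, 2, 4, 3))                 # (dj, nj, di, ni, S3)
    kern[g$out_rows, g$in_rows, ] <-
      kern[g$out_rows, g$in_rows, , drop = FALSE] +
      array(blk, dim = c(g$dj * g$nj, g$di * g$ni, S3))
  }
  array(kern, dim = c(dout, din, S, S, S))
}

# gradient of a scalar loss wrt kernel weights, given the gradient wrt the
# assembled dense kernel (the adjoint of assemble_kernel)
kernel_weights_grad <- function(basis, dkern) {
  S3 <- basis$S^3
  K <- basis$profile$K
  dk <- array(dkern, dim = c(dim(dkern)[1], dim(dkern)[2], S3))
  out <- list()
  for (key in names(basis$groups)) {
    g <- basis$groups[[key]]
    blk <- array(dk[g$out_rows, g$in_rows, , drop = FALSE],
                 dim = c(g$dj, g$nj, g$di, g$ni, S3))
    Ra <- aperm(blk, c(1, 3, 5, 4, 2))                 # (dj, di, S3, ni, nj)
    Bm <- matrix(g$B, ncol = K)
    out[[key]] <- array(crossprod(Bm, matrix(Ra, nrow = g$dj * g$di * S3)),
                        dim = c(K, g$ni, g$nj))
  }
  structure(out, class = "kernel_weights")
}

#' Count trainable weights of one steerable convolution
#'
#' `K x number_of_paths` convolution weights, plus one self-connection
#' weight per equal-order channel pair when `with_self_connection`.
#' Biases (scalar output channels) are not included.
#'
#' @param irreps_in,irreps_out feature types.
#' @param K number of radial basis functions.
#' @param l_max maximum harmonic order.
#' @param with_self_connection include the pointwise tensor-product
#'   weights.
#' @return non-negative integer.
#' @export
count_parameters <- function(irreps_in, irreps_out, K = 5L, l_max = 4L,
                             with_self_connection = FALSE) {
  paths <- enumerate_paths(irreps_in, irreps_out, l_max)
  n <- K * nrow(paths)
  if (with_self_connection) {
    ci <- irreps_channels(irreps(irreps_in))
    co <- irreps_channels(irreps(irreps_out))
    n <- n + sum(outer(ci$l, co$l, "==") * 1L)
  }
  as.integer(n)
}

#' Export a sampled kernel basis as a binary archive with JSON descriptor
#'
#' Writes `<path>/basis.json` (irreps, kernel size, radial count, l_max
#' and convention tags) and `<path>/basis.bin` (the sampled blocks as
#' doubles, group order as in `basis$groups`), so precomputed bases can be
#' reused across runs; [load_kernel_basis()] restores them bit-exactly.
#'
#' @param basis a `kernel_basis`; `path` a directory (created).
#' @return `path`, invisibly.
#' @export
save_kernel_basis <- function(basis, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  desc <- list(
    format = "steerable3d-basis-v1",
    irreps_in = format(basis$irreps_in), irreps_out = format(basis$irreps_out),
    S = basis$S, K = basis$profile$K, r_max = basis$profile$r_max,
    l_max = basis$l_max,
    conventions = list(component_order = "real m = -l..l",
                       harmonics = "orthonormal real, no Condon-Shortley",
                       radial = "raised-cosine bumps, centers k*r_max/K"),
    groups = lapply(basis$groups, function(g)
      list(li = g$li, l = g$l, lj = g$lj, n = length(g$B)))
  )
  jsonlite::write_json(desc, file.path(path, "basis.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "basis.bin"), "wb")
  for (g in basis$groups) writeBin(as.vector(g$B), con, size = 8)
  close(con)
  invisible(path)
}

#' Load a kernel basis saved by [save_kernel_basis()]
#' @param path the saved directory.
#' @return a `kernel_basis`.
#' @export
load_kernel_basis <- function(path) {
  desc <- jsonlite::read_json(file.path(path, "basis.json"),
                              simplifyVector = FALSE)
  prof <- radial_profile(desc$K, desc$r_max)
  basis <- sample_kernel_basis(irreps(desc$irreps_in),
                               irreps(desc$irreps_out),
                               desc$S, prof, desc$l_max)
  con <- file(file.path(path, "basis.bin"), "rb")
  for (key in names(basis$groups)) {
    n <- length(basis$groups[[key]]$B)
    basis$groups[[key]]$B[] <- readBin(con, "double", n = n, size = 8)
  }
  close(con)
  basis
}
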