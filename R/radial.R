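#' Radial basis profile for steerable kernels
#'
#' A compactly supported family of K overlapping raised-cosine bumps
#' b_k(r), k = 1..K, centered at equally spaced radii c_k = k * r_max / K
#' in (0, r_max] with half-width r_max / K. Every b_k vanishes at r = 0
#' and for r > r_max, is continuous on [0, r_max], and adjacent bumps
#' overlap by half their support, so the family is well conditioned on a
#' voxel grid; the last bump peaks at r_max itself so corner samples of a
#' kernel whose cutoff is the grid circumradius stay live.
#'
#' @param K number of basis functions (default 5).
#' @param r_max support cutoff in voxel units. For a kernel of odd size S
#'   the natural choice is the grid circumradius `sqrt(3) * (S - 1) / 2`,
#'   which keeps corner samples live (see [kernel_r_max()]).
#' @return an object of class `radial_profile`.
#' @export
radial_profile <- function(K = 5L, r_max) {
  stopifnot(K >= 1, r_max > 0)
  structure(list(K = as.integer(K), r_max = r_max,
                 centers = seq_len(K) * r_max / K,
                 width = r_max / K),
            class = "radial_profile")
}

#' Default kernel cutoff radius: the circumradius of a centered S^3 grid
#' @param S odd kernel size.
#' @return `sqrt(3) * (S - 1) / 2`.
#' @export
kernel_r_max <- function(S) sqrt(3) * (S - 1) / 2

#' Evaluate the radial basis at a set of distances
#'
#' @param profile a [radial_profile()].
#' @param distances non-negative numeric vector.
#' @return K x N matrix, row k holding b_k at each distance.
#' @export
radial_profile_values <- function(profile, distances) {
  stopifnot(inherits(profile, "radial_profile"))
  if (any(distances < 0)) stop("negative distance outside radial domain")
  out <- matrix(0, profile$K, length(distances))
  w <- profile$width
  for (k in seq_len(profile$K)) {
    t <- (distances - profile$centers[k]) / w
    inside <- abs(t) < 1 & distances <= profile$r_max
    out[k, inside] <- 0.5 * (1 + cos(pi * t[inside]))
  }
  # exact zeros at the origin regardless of floating-point cos
  out[, distances == 0] <- 0
  out
}
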