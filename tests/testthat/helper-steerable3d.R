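# shared helpers for the test suite

# block-diagonal Wigner matrix acting on the full feature axis of an irreps
block_diag_wigner <- function(ir, R) {
  ir <- irreps(ir)
  d <- irreps_dim(ir)
  M <- matrix(0, d, d)
  ch <- irreps_channels(ir)
  for (c in seq_len(nrow(ch))) {
    idx <- ch$start[c] + seq_len(ch$d[c]) - 1L
    M[idx, idx] <- wigner_block(ch$l[c], R)
  }
  M
}

# a deterministic set of random (non-octahedral) rotations
random_rotations <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    rotation_axis_angle(stats::rnorm(3), stats::runif(1, 0.1, pi)))
}

# direct evaluation of the equivariant convolution as the path sum:
# for each path {i x l -> j} and tap a, accumulate
#   CG(l_i,l,l_j) x Y^l(a/|a|) b_k(|a|) w(k,path) applied to F_i(x + a).
# Shift-and-add over taps; independent of assemble_kernel + GEMM route.
direct_path_sum_conv <- function(field, basis, weights) {
  x <- field$values
  sp <- dim(x)[-1]
  S <- basis$S
  p <- (S - 1L) / 2L
  offs <- steerable3d:::kernel_offsets(S)
  r <- sqrt(rowSums(offs^2))
  Brad <- radial_profile_values(basis$profile, r)
  out <- array(0, dim = c(irreps_dim(basis$irreps_out), sp))
  ch_in <- irreps_channels(basis$irreps_in)
  ch_out <- irreps_channels(basis$irreps_out)
  paths <- basis$paths
  # shifted copy of the input: F(x + a), zero outside
  shift <- function(v, a) {
    y <- array(0, dim = dim(v))
    sx <- intersect(seq_len(sp[1]), seq_len(sp[1]) + a[1]) # dest indices
    sy <- intersect(seq_len(sp[2]), seq_len(sp[2]) + a[2])
    sz <- intersect(seq_len(sp[3]), seq_len(sp[3]) + a[3])
    y[, sx - a[1], sy - a[2], sz - a[3]] <-
      v[, sx, sy, sz, drop = FALSE]
    y
  }
  for (pidx in seq_len(nrow(paths))) {
    pa <- paths[pidx, ]
    C <- clebsch_gordan(pa$l_i, pa$l, pa$l_j)
    di <- 2 * pa$l_i + 1; dj <- 2 * pa$l_j + 1
    rows_i <- ch_in$start[pa$i] + seq_len(di) - 1L
    rows_j <- ch_out$start[pa$j] + seq_len(dj) - 1L
    key <- paste(pa$l_i, pa$l, pa$l_j, sep = "_")
    g <- basis$groups[[key]]
    ci <- pa$i - min(which(ch_in$l == pa$l_i)) + 1L
    cj <- pa$j - min(which(ch_out$l == pa$l_j)) + 1L
    w <- weights[[key]][, ci, cj]
    for (o in seq_len(nrow(offs))) {
      a <- offs[o, ]
      if (all(a == 0)) next                      # b_k(0) = 0
      Y <- real_spherical_harmonics(pa$l, a / r[o])
      kap <- matrix(0, dj, di)
      for (m in seq_len(2 * pa$l + 1))
        kap <- kap + Y[m] * t(array(C[, m, ], dim = c(di, dj)))
      kap <- kap * sum(w * Brad[, o])
      xs <- shift(x[rows_i, , , , drop = FALSE], a)
      out[rows_j, , , ] <- out[rows_j, , , , drop = FALSE] +
        array(kap %*% matrix(xs, di), dim = c(dj, sp))
    }
  }
  irrep_field(basis$irreps_out, out)
}

# random kernel weights for a basis
random_kernel_weights <- function(basis, seed = 1) {
  set.seed(seed)
  w <- new_kernel_weights(basis)
  for (k in names(w)) w[[k]][] <- stats::rnorm(length(w[[k]]))
  w
}
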