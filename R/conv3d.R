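# Dense 3D convolution, evaluated as one BLAS multiply per kernel tap on a
# zero-padded channel matrix (cheaper in R than an explicit im2col matrix).
# Convention (cross-correlation, as in CNNs): for a kernel array of dim
# (Cout, Cin, S, S, S) with spatial index a = offset + (S+1)/2,
#   out[j, x] = sum_{i, a} kern[j, i, a] * in[i, x + a],  a in [-p, p]^3,
# with zero same-padding, so spatial size is preserved.

.conv_cache <- new.env(parent = emptyenv())

# flat indices into the padded (D+2p, H+2p, W+2p) grid of the N = D*H*W
# sample positions for each of the S^3 taps, cached per shape
conv3d_tap_indices <- function(D, H, W, S) {
  key <- paste(D, H, W, S, sep = "x")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  p <- (S - 1L) / 2L
  Dp <- D + 2L * p; Hp <- H + 2L * p
  base_x <- seq_len(D)
  base_y <- (seq_len(H) - 1L) * Dp
  base_z <- (seq_len(W) - 1L) * Dp * Hp
  grid <- outer(outer(base_x, base_y, "+"), base_z, "+")  # (D,H,W) flat
  idx <- vector("list", S^3)
  o <- 0L
  for (az in seq_len(S)) for (ay in seq_len(S)) for (ax in seq_len(S)) {
    o <- o + 1L
    idx[[o]] <- as.integer(grid + (ax - 1L) + (ay - 1L) * Dp +
                             (az - 1L) * Dp * Hp)
  }
  .conv_cache[[key]] <- idx
  idx
}

conv3d_pad <- function(x, p) {
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4] + 2 * p))
  xp[, p + seq_len(d[2]), p + seq_len(d[3]), p + seq_len(d[4])] <- x
  matrix(xp, d[1])
}

# forward: x (Cin, D, H, W), kern (Cout, Cin, S, S, S) -> (Cout, D, H, W).
# Returns the padded channel matrix too so a backward pass can reuse it.
conv3d_forward_full <- function(x, kern) {
  d <- dim(x); S <- dim(kern)[3]; p <- (S - 1L) / 2L
  Cout <- dim(kern)[1]
  N <- prod(d[-1])
  idx <- conv3d_tap_indices(d[2], d[3], d[4], S)
  xpm <- conv3d_pad(x, p)
  kf <- array(kern, dim = c(Cout, d[1], S^3))
  out <- matrix(0, Cout, N)
  for (o in seq_len(S^3))
    out <- out + matrix(kf[, , o], Cout, d[1]) %*% xpm[, idx[[o]], drop = FALSE]
  list(out = array(out, dim = c(Cout, d[-1])), xpm = xpm, dims = d)
}

conv3d_forward <- function(x, kern) conv3d_forward_full(x, kern)$out

# backward from the cached padded input matrix; gy (Cout, D, H, W).
# The input gradient is itself a convolution of gy with the spatially
# flipped, channel-transposed kernel, so both directions run as per-tap
# gathers + GEMM (gathers are much cheaper than scatter-adds in R).
conv3d_backward <- function(cache, kern, gy) {
  d <- cache$dims; S <- dim(kern)[3]; p <- (S - 1L) / 2L
  Cin <- d[1]; Cout <- dim(kern)[1]
  N <- prod(d[-1])
  S3 <- S^3
  idx <- conv3d_tap_indices(d[2], d[3], d[4], S)
  G <- matrix(gy, Cout, N)
  kf <- array(kern, dim = c(Cout, Cin, S3))
  dkern <- array(0, dim = dim(kf))
  for (o in seq_len(S3))
    dkern[, , o] <- tcrossprod(G, cache$xpm[, idx[[o]], drop = FALSE])
  gpm <- conv3d_pad(array(G, dim = c(Cout, d[-1])), p)
  dxm <- matrix(0, Cin, N)
  for (o in seq_len(S3)) {
    flip <- S3 + 1L - o                  # tap -a
    dxm <- dxm + crossprod(matrix(kf[, , o], Cout, Cin),
                           gpm[, idx[[flip]], drop = FALSE])
  }
  list(dx = array(dxm, dim = d), dkern = array(dkern, dim = dim(kern)))
}
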