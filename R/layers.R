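# Network layer primitives, each with a forward and a backward pass.
# Layers are plain lists with a `type` field; parameters live in
# `layer$params` and backward passes return gradients of the same shape.
# All equivariant layers map valid irrep fields to valid irrep fields and
# commute exactly (up to round-off) with the 24 octahedral grid rotations.

sigmoid <- function(x) 1 / (1 + exp(-x))
silu <- function(x) x * sigmoid(x)
silu_grad <- function(x) { s <- sigmoid(x); s * (1 + x * (1 - s)) }

scalar_rows <- function(ir) {
  ir <- irreps(ir)
  e <- which(ir$entries$l == 0L)
  if (length(e) == 0) return(integer(0))
  irreps_slices(ir)[[e]]
}

## ---- self connection (pointwise weighted tensor product) ----------------

#' Blank self-connection weight table
#'
#' One matrix of shape (n_in_channels, n_out_channels) per order present
#' in both the input and output irreps, named `"l<order>"`.
#'
#' @param irreps_in,irreps_out feature types.
#' @param fill initial value.
#' @return named list of matrices.
#' @export
new_sc_weights <- function(irreps_in, irreps_out, fill = 0) {
  ein <- irreps(irreps_in)$entries; eout <- irreps(irreps_out)$entries
  common <- intersect(ein$l, eout$l)
  out <- list()
  for (l in sort(common))
    out[[paste0("l", l)]] <- matrix(fill, ein$mul[ein$l == l],
                                    eout$mul[eout$l == l])
  out
}

sc_forward <- function(x, irreps_in, irreps_out, sc) {
  sp <- dim(x)[-1]; N <- prod(sp)
  y <- array(0, dim = c(irreps_dim(irreps_out), sp))
  ein <- irreps(irreps_in)$entries; eout <- irreps(irreps_out)$entries
  sin <- irreps_slices(irreps_in); sout <- irreps_slices(irreps_out)
  for (nm in names(sc)) {
    l <- as.integer(sub("l", "", nm)); d <- 2L * l + 1L
    ei <- which(ein$l == l); eo <- which(eout$l == l)
    ni <- ein$mul[ei]; nj <- eout$mul[eo]
    X <- array(x[sin[[ei]], , , , drop = FALSE], dim = c(d, ni, N))
    Xm <- matrix(aperm(X, c(1, 3, 2)), d * N, ni)
    Ym <- Xm %*% sc[[nm]]
    y[sout[[eo]], , , ] <- aperm(array(Ym, dim = c(d, N, nj)), c(1, 3, 2))
  }
  y
}

sc_backward <- function(x, irreps_in, irreps_out, sc, gy) {
  sp <- dim(x)[-1]; N <- prod(sp)
  dx <- array(0, dim = dim(x))
  dsc <- lapply(sc, function(m) m * 0)
  ein <- irreps(irreps_in)$entries; eout <- irreps(irreps_out)$entries
  sin <- irreps_slices(irreps_in); sout <- irreps_slices(irreps_out)
  for (nm in names(sc)) {
    l <- as.integer(sub("l", "", nm)); d <- 2L * l + 1L
    ei <- which(ein$l == l); eo <- which(eout$l == l)
    ni <- ein$mul[ei]; nj <- eout$mul[eo]
    X <- array(x[sin[[ei]], , , , drop = FALSE], dim = c(d, ni, N))
    Xm <- matrix(aperm(X, c(1, 3, 2)), d * N, ni)
    G <- array(gy[sout[[eo]], , , , drop = FALSE], dim = c(d, nj, N))
    Gm <- matrix(aperm(G, c(1, 3, 2)), d * N, nj)
    dsc[[nm]] <- crossprod(Xm, Gm)
    dXm <- Gm %*% t(sc[[nm]])
    dx[sin[[ei]], , , ] <- dx[sin[[ei]], , , , drop = FALSE] +
      array(aperm(array(dXm, dim = c(d, N, ni)), c(1, 3, 2)),
            dim = c(d * ni, sp))
  }
  list(dx = dx, dsc = dsc)
}

## ---- steerable convolution layer -----------------------------------------

# per-group initialization scale: variance-preserving for unit-variance
# input, counting the summed basis energy and the self connection as fan-in
steerable_conv_init_sd <- function(basis, has_sc) {
  eout <- basis$irreps_out$entries
  # mean squared basis magnitude per group, per output component
  b2 <- vapply(basis$groups, function(g)
    sum(g$B^2) / (g$dj * basis$profile$K), 0)
  fan <- setNames(numeric(nrow(eout)), paste0("l", eout$l))
  for (key in names(basis$groups)) {
    g <- basis$groups[[key]]
    fan[paste0("l", g$lj)] <- fan[paste0("l", g$lj)] +
      basis$profile$K * g$ni * b2[key]
  }
  if (has_sc) {
    ein <- basis$irreps_in$entries
    for (l in intersect(ein$l, eout$l))
      fan[paste0("l", l)] <- fan[paste0("l", l)] + ein$mul[ein$l == l]
  }
  list(conv = vapply(basis$groups, function(g)
    1 / sqrt(max(fan[paste0("l", g$lj)], 1e-12)), 0),
    sc = 1 / sqrt(pmax(fan, 1e-12)))
}

#' Create a steerable convolution layer
#'
#' Sum of the basis-parameterized convolution, a pointwise self
#' connection (the kernels vanish at the origin, so a 1x1x1 tensor
#' product restores center taps), and a bias on scalar output channels
#' only (a bias on l>0 channels would break equivariance). Weights are
#' drawn with per-path variance scaling so output variance is
#' approximately 1 for unit-variance input.
#'
#' @param basis a [sample_kernel_basis()].
#' @param with_sc include the self connection (default TRUE).
#' @param with_bias include scalar biases (default TRUE).
#' @return a layer object.
#' @export
layer_steerable_conv <- function(basis, with_sc = TRUE, with_bias = TRUE) {
  sdv <- steerable_conv_init_sd(basis, with_sc)
  w <- new_kernel_weights(basis)
  for (key in names(w))
    w[[key]][] <- stats::rnorm(length(w[[key]]), sd = sdv$conv[key])
  sc <- NULL
  if (with_sc) {
    sc <- new_sc_weights(basis$irreps_in, basis$irreps_out)
    for (nm in names(sc))
      sc[[nm]][] <- stats::rnorm(length(sc[[nm]]), sd = sdv$sc[nm])
  }
  bias <- if (with_bias) numeric(length(scalar_rows(basis$irreps_out))) else NULL
  list(type = "steerable_conv", basis = basis,
       irreps_in = basis$irreps_in, irreps_out = basis$irreps_out,
       params = list(w = w, sc = sc, bias = bias))
}

steerable_conv_forward <- function(layer, x) {
  kern <- assemble_kernel(layer$basis, layer$params$w)
  cf <- conv3d_forward_full(x, kern)
  y <- cf$out
  if (!is.null(layer$params$sc))
    y <- y + sc_forward(x, layer$irreps_in, layer$irreps_out, layer$params$sc)
  if (!is.null(layer$params$bias)) {
    rows <- scalar_rows(layer$irreps_out)
    if (length(rows)) y[rows, , , ] <- y[rows, , , , drop = FALSE] +
        layer$params$bias
  }
  list(out = y, cache = list(x = x, kern = kern,
                             conv = list(xpm = cf$xpm, dims = cf$dims)))
}

steerable_conv_backward <- function(layer, cache, gy) {
  bk <- conv3d_backward(cache$conv, cache$kern, gy)
  grads <- list(w = kernel_weights_grad(layer$basis, bk$dkern))
  dx <- bk$dx
  if (!is.null(layer$params$sc)) {
    sb <- sc_backward(cache$x, layer$irreps_in, layer$irreps_out,
                      layer$params$sc, gy)
    dx <- dx + sb$dx
    grads$sc <- sb$dsc
  }
  if (!is.null(layer$params$bias)) {
    rows <- scalar_rows(layer$irreps_out)
    grads$bias <- if (length(rows))
      rowSums(matrix(gy[rows, , , , drop = FALSE], length(rows))) else numeric(0)
  }
  list(dx = dx, grads = grads)
}

## ---- plain (reference) convolution layer ---------------------------------

layer_conv <- function(c_in, c_out, S) {
  sd <- 1 / sqrt(c_in * S^3)
  list(type = "conv",
       params = list(kern = array(stats::rnorm(c_out * c_in * S^3, sd = sd),
                                  dim = c(c_out, c_in, S, S, S)),
                     bias = numeric(c_out)))
}

conv_forward <- function(layer, x) {
  cf <- conv3d_forward_full(x, layer$params$kern)
  list(out = cf$out + layer$params$bias,
       cache = list(xpm = cf$xpm, dims = cf$dims))
}

conv_backward <- function(layer, cache, gy) {
  bk <- conv3d_backward(cache, layer$params$kern, gy)
  list(dx = bk$dx,
       grads = list(kern = bk$dkern,
                    bias = rowSums(matrix(gy, dim(gy)[1]))))
}

## ---- gated nonlinearity ---------------------------------------------------

#' Gate specification for a conv block output
#'
#' The convolution preceding a gate emits, in addition to the block's
#' nominal irreps, one auxiliary scalar per non-scalar output channel;
#' these gate scalars sit at the end of the l = 0 block. The gate layer
#' squashes each gate through a sigmoid, multiplies its non-scalar
#' channel by it, applies a smooth pointwise activation (SiLU,
#' x * sigmoid(x)) to the ordinary scalars, and drops the gate channels.
#'
#' @param irreps_out the block's nominal output irreps (canonical form).
#' @return list with `irreps_in` (conv output incl. gates), `irreps_out`,
#'   `n_scalars`, `n_gates`.
#' @export
gate_spec <- function(irreps_out) {
  irreps_out <- irreps(irreps_out)
  e <- irreps_out$entries
  if (is.unsorted(e$l) || any(duplicated(e$l)))
    stop("gate_spec requires canonical grouped irreps")
  n_scalars <- irreps_mul_of(irreps_out, 0L)
  n_gates <- sum(e$mul[e$l > 0])
  mul0 <- n_scalars + n_gates
  ein <- rbind(data.frame(mul = mul0, l = 0L),
               e[e$l > 0, c("mul", "l"), drop = FALSE])
  list(irreps_in = irreps(ein), irreps_out = irreps_out,
       n_scalars = n_scalars, n_gates = n_gates)
}

layer_gate <- function(spec) list(type = "gate", spec = spec, params = list())

gate_forward <- function(layer, x) {
  sp <- layer$spec
  din <- dim(x); N3 <- din[-1]
  ns <- sp$n_scalars; ng <- sp$n_gates
  if (din[1] != irreps_dim(sp$irreps_in)) stop("gate: missing gate channels")
  y <- array(0, dim = c(irreps_dim(sp$irreps_out), N3))
  if (ns > 0) y[seq_len(ns), , , ] <- silu(x[seq_len(ns), , , , drop = FALSE])
  sg <- NULL
  if (ng > 0) {
    gates <- x[ns + seq_len(ng), , , , drop = FALSE]
    sg <- sigmoid(gates)
    eout <- sp$irreps_out$entries
    sl_out <- irreps_slices(sp$irreps_out)
    gi <- 0L
    off_in <- ns + ng    # non-scalar rows start here in the input
    for (e in seq_len(nrow(eout))) {
      if (eout$l[e] == 0) next
      d <- 2L * eout$l[e] + 1L
      for (c in seq_len(eout$mul[e])) {
        gi <- gi + 1L
        rows_in <- off_in + seq_len(d); off_in <- off_in + d
        rows_out <- sl_out[[e]][(c - 1L) * d + seq_len(d)]
        y[rows_out, , , ] <- x[rows_in, , , , drop = FALSE] *
          rep(sg[gi, , , ], each = d)
      }
    }
  }
  list(out = y, cache = list(x = x, sg = sg))
}

gate_backward <- function(layer, cache, gy) {
  sp <- layer$spec; x <- cache$x
  ns <- sp$n_scalars; ng <- sp$n_gates
  dx <- array(0, dim = dim(x))
  if (ns > 0)
    dx[seq_len(ns), , , ] <- gy[seq_len(ns), , , , drop = FALSE] *
      silu_grad(x[seq_len(ns), , , , drop = FALSE])
  if (ng > 0) {
    sg <- cache$sg
    eout <- sp$irreps_out$entries
    sl_out <- irreps_slices(sp$irreps_out)
    gi <- 0L; off_in <- ns + ng
    for (e in seq_len(nrow(eout))) {
      if (eout$l[e] == 0) next
      d <- 2L * eout$l[e] + 1L
      for (c in seq_len(eout$mul[e])) {
        gi <- gi + 1L
        rows_in <- off_in + seq_len(d); off_in <- off_in + d
        rows_out <- sl_out[[e]][(c - 1L) * d + seq_len(d)]
        g_blk <- gy[rows_out, , , , drop = FALSE]
        s <- sg[gi, , , ]
        dx[rows_in, , , ] <- g_blk * rep(s, each = d)
        dot <- colSums(matrix(g_blk * x[rows_in, , , , drop = FALSE], d))
        dx[ns + gi, , , ] <- array(dot * s * (1 - s), dim = dim(s))
      }
    }
  }
  list(dx = dx, grads = list())
}

## ---- norm instance normalization -----------------------------------------

layer_norm_inorm <- function(ir, eps = 1e-5)
  list(type = "norm_inorm", irreps = irreps(ir), eps = eps, params = list())

norm_inorm_forward <- function(layer, x) {
  ir <- layer$irreps; eps <- layer$eps
  y <- array(0, dim = dim(x))
  N <- prod(dim(x)[-1])
  ch <- irreps_channels(ir)
  cache <- list(x = x, stats = vector("list", nrow(ch)))
  for (c in seq_len(nrow(ch))) {
    rows <- ch$start[c] + seq_len(ch$d[c]) - 1L
    if (ch$l[c] == 0) {
      v <- x[rows, , , ]
      mu <- mean(v); s2 <- mean((v - mu)^2)
      inv <- 1 / sqrt(s2 + eps)
      y[rows, , , ] <- (v - mu) * inv
      cache$stats[[c]] <- list(mu = mu, inv = inv)
    } else {
      V <- matrix(x[rows, , , , drop = FALSE], ch$d[c], N)
      nrm <- sqrt(colSums(V^2))
      s <- 1 / (mean(nrm) + eps)
      y[rows, , , ] <- array(V * s, dim = c(ch$d[c], dim(x)[-1]))
      cache$stats[[c]] <- list(nrm = nrm, s = s)
    }
  }
  list(out = y, cache = cache)
}

norm_inorm_backward <- function(layer, cache, gy) {
  ir <- layer$irreps
  x <- cache$x
  dx <- array(0, dim = dim(x))
  N <- prod(dim(x)[-1])
  ch <- irreps_channels(ir)
  for (c in seq_len(nrow(ch))) {
    rows <- ch$start[c] + seq_len(ch$d[c]) - 1L
    st <- cache$stats[[c]]
    if (ch$l[c] == 0) {
      v <- x[rows, , , ]; g <- gy[rows, , , ]
      yv <- (v - st$mu) * st$inv
      dx[rows, , , ] <- st$inv * (g - mean(g) - yv * mean(g * yv))
    } else {
      d <- ch$d[c]
      V <- matrix(x[rows, , , , drop = FALSE], d, N)
      G <- matrix(gy[rows, , , , drop = FALSE], d, N)
      tot <- sum(G * V)
      unit <- sweep(V, 2, pmax(st$nrm, 1e-30), "/")
      dV <- G * st$s - unit * (tot * st$s^2 / N)
      dx[rows, , , ] <- array(dV, dim = c(d, dim(x)[-1]))
    }
  }
  list(dx = dx, grads = list())
}

## ---- standard instance norm (reference net, all channels scalar) ---------

layer_inorm <- function(n_chan, eps = 1e-5)
  list(type = "inorm",
       irreps = irreps(data.frame(mul = n_chan, l = 0L)),
       eps = eps, params = list())

## ---- leaky ReLU (reference net) ------------------------------------------

layer_lrelu <- function(alpha = 0.01)
  list(type = "lrelu", alpha = alpha, params = list())

lrelu_forward <- function(layer, x) {
  pos <- x > 0
  list(out = x * (pos + layer$alpha * (1 - pos)), cache = list(pos = pos))
}

lrelu_backward <- function(layer, cache, gy)
  list(dx = gy * (cache$pos + layer$alpha * (1 - cache$pos)), grads = list())

## ---- norm max pooling ------------------------------------------------------

layer_norm_maxpool <- function(ir, window = 2L) {
  if (window < 1) stop("pooling window must be >= 1")
  list(type = "norm_maxpool", irreps = irreps(ir), window = as.integer(window),
       params = list())
}

norm_maxpool_forward <- function(layer, x) {
  w <- layer$window; ir <- layer$irreps
  d4 <- dim(x); sp <- d4[-1]
  if (any(sp %% w != 0))
    stop("spatial dims ", paste(sp, collapse = "x"),
         " not divisible by pooling window ", w)
  sp2 <- sp %/% w; Nw <- prod(sp2); w3 <- w^3
  y <- array(0, dim = c(d4[1], sp2))
  ent <- ir$entries; sl <- irreps_slices(ir)
  amax_all <- vector("list", nrow(ent))
  for (e in seq_len(nrow(ent))) {
    d <- 2L * ent$l[e] + 1L; m <- ent$mul[e]
    blk <- array(x[sl[[e]], , , , drop = FALSE],
                 dim = c(d, m, w, sp2[1], w, sp2[2], w, sp2[3]))
    X3 <- aperm(blk, c(1, 2, 4, 6, 8, 3, 5, 7))     # d, m, D2,H2,W2, w,w,w
    X3 <- array(X3, dim = c(d, m * Nw, w3))
    key <- if (ent$l[e] == 0) array(X3, dim = c(m * Nw, w3))
           else colSums(array(X3^2, dim = c(d, m * Nw, w3)))
    amax <- max.col(key, ties.method = "first")
    flat <- rep(seq_len(m * Nw), each = d)
    idx <- seq_len(d) + d * (flat - 1L) + d * m * Nw * (rep(amax, each = d) - 1L)
    y[sl[[e]], , , ] <- array(X3[idx], dim = c(d * m, sp2))
    amax_all[[e]] <- amax
  }
  list(out = y, cache = list(amax = amax_all, sp = sp))
}

norm_maxpool_backward <- function(layer, cache, gy) {
  w <- layer$window; ir <- layer$irreps
  sp <- cache$sp; sp2 <- sp %/% w; Nw <- prod(sp2); w3 <- w^3
  ent <- ir$entries; sl <- irreps_slices(ir)
  dx <- array(0, dim = c(irreps_dim(ir), sp))
  for (e in seq_len(nrow(ent))) {
    d <- 2L * ent$l[e] + 1L; m <- ent$mul[e]
    amax <- cache$amax[[e]]
    G <- array(gy[sl[[e]], , , , drop = FALSE], dim = c(d, m * Nw))
    dX3 <- array(0, dim = c(d, m * Nw, w3))
    flat <- rep(seq_len(m * Nw), each = d)
    idx <- seq_len(d) + d * (flat - 1L) + d * m * Nw * (rep(amax, each = d) - 1L)
    dX3[idx] <- G
    dblk <- array(dX3, dim = c(d, m, sp2[1], sp2[2], sp2[3], w, w, w))
    dblk <- aperm(dblk, c(1, 2, 6, 3, 7, 4, 8, 5))
    dx[sl[[e]], , , ] <- array(dblk, dim = c(d * m, sp))
  }
  list(dx = dx, grads = list())
}

## ---- trilinear upsampling --------------------------------------------------

# interpolation matrix mapping n samples to f*n samples; sample positions
# follow the half-voxel convention (output center (o+0.5)/f - 0.5 in input
# coordinates), which commutes with grid reversals, hence with the
# octahedral rotations
upsample_matrix <- function(n, f) {
  M <- matrix(0, f * n, n)
  for (o in seq_len(f * n)) {
    pos <- (o - 0.5) / f - 0.5          # 0-based input coordinate
    i0 <- floor(pos); t <- pos - i0
    a <- min(max(i0, 0), n - 1) + 1L
    b <- min(max(i0 + 1, 0), n - 1) + 1L
    M[o, a] <- M[o, a] + (1 - t)
    M[o, b] <- M[o, b] + t
  }
  M
}

# multiply matrix M along spatial axis `axis` (2..4) of (C, D, H, W)
apply_axis_matrix <- function(x, M, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  y <- M %*% matrix(xp, d[axis])
  dy <- c(nrow(M), d[-axis])
  aperm(array(y, dim = dy), order(perm))
}

layer_upsample <- function(factor = 2L)
  list(type = "upsample", factor = as.integer(factor), params = list())

upsample_forward <- function(layer, x) {
  f <- layer$factor
  if (f == 1) return(list(out = x, cache = list(sp = dim(x)[-1])))
  sp <- dim(x)[-1]
  for (ax in 2:4) x <- apply_axis_matrix(x, upsample_matrix(dim(x)[ax], f), ax)
  list(out = x, cache = list(sp = sp))
}

upsample_backward <- function(layer, cache, gy) {
  f <- layer$factor
  if (f == 1) return(list(dx = gy, grads = list()))
  for (ax in 2:4)
    gy <- apply_axis_matrix(gy, t(upsample_matrix(dim(gy)[ax] / f, f)), ax)
  list(dx = gy, grads = list())
}

## ---- dispatch --------------------------------------------------------------

layer_forward <- function(layer, x) {
  switch(layer$type,
    steerable_conv = steerable_conv_forward(layer, x),
    conv = conv_forward(layer, x),
    gate = gate_forward(layer, x),
    norm_inorm = norm_inorm_forward(layer, x),
    inorm = norm_inorm_forward(layer, x),
    lrelu = lrelu_forward(layer, x),
    norm_maxpool = norm_maxpool_forward(layer, x),
    upsample = upsample_forward(layer, x),
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, cache, gy) {
  switch(layer$type,
    steerable_conv = steerable_conv_backward(layer, cache, gy),
    conv = conv_backward(layer, cache, gy),
    gate = gate_backward(layer, cache, gy),
    norm_inorm = norm_inorm_backward(layer, cache, gy),
    inorm = norm_inorm_backward(layer, cache, gy),
    lrelu = lrelu_backward(layer, cache, gy),
    norm_maxpool = norm_maxpool_backward(layer, cache, gy),
    upsample = upsample_backward(layer, cache, gy),
    stop("unknown layer type ", layer$type))
}

## ---- user-facing functional wrappers on irrep fields ----------------------

#' Equivariant convolution of an irrep field
#'
#' Convolution with the assembled steerable kernel plus the pointwise self
#' connection and scalar bias (Eq. of the steerable-kernel model:
#' radial profiles times spherical harmonics reduced by Clebsch-Gordan
#' blocks). Same-padding preserves spatial size.
#'
#' @param field an [irrep_field()] whose irreps equal the basis input.
#' @param basis a [sample_kernel_basis()].
#' @param weights `kernel_weights` (or flat vector).
#' @param sc_weights optional self-connection weights
#'   ([new_sc_weights()] layout).
#' @param bias optional numeric bias, one per scalar output channel.
#' @return the output `irrep_field`.
#' @export
steerable_conv <- function(field, basis, weights, sc_weights = NULL,
                           bias = NULL) {
  if (format(field$irreps) != format(basis$irreps_in))
    stop("field irreps do not match kernel basis input irreps")
  if (is.numeric(weights)) weights <- kernel_weights_from_vector(basis, weights)
  layer <- list(type = "steerable_conv", basis = basis,
                irreps_in = basis$irreps_in, irreps_out = basis$irreps_out,
                params = list(w = weights, sc = sc_weights, bias = bias))
  irrep_field(basis$irreps_out, steerable_conv_forward(layer, field$values)$out)
}

#' Pointwise self connection (1x1x1 weighted tensor product)
#'
#' Voxel-wise channel mixing within equal-order blocks; the output at a
#' voxel depends only on the input at that voxel, and the map commutes
#' exactly with feature rotations.
#'
#' @param field an [irrep_field()].
#' @param irreps_out output feature type.
#' @param sc_weights weights as from [new_sc_weights()].
#' @return an `irrep_field`.
#' @export
self_connection <- function(field, irreps_out, sc_weights) {
  irreps_out <- irreps(irreps_out)
  irrep_field(irreps_out,
              sc_forward(field$values, field$irreps, irreps_out, sc_weights))
}

#' Gated nonlinearity
#' @param field conv output including gate scalars.
#' @param spec a [gate_spec()].
#' @return an `irrep_field` with the gate channels consumed.
#' @export
gated_nonlinearity <- function(field, spec) {
  if (format(field$irreps) != format(spec$irreps_in))
    stop("field does not carry the gate channels demanded by the spec")
  irrep_field(spec$irreps_out,
              gate_forward(list(type = "gate", spec = spec), field$values)$out)
}

#' Norm max-pooling
#'
#' Scalar channels are max-pooled ordinarily; for each non-scalar channel
#' the entire (2l+1)-vector with the greatest Euclidean norm in the window
#' is kept (ties: lowest flat index). Spatial dims must be divisible by
#' the window.
#'
#' @param field an [irrep_field()].
#' @param window pooling window (default 2).
#' @return an `irrep_field` at reduced resolution.
#' @export
norm_max_pool <- function(field, window = 2L) {
  layer <- layer_norm_maxpool(field$irreps, window)
  irrep_field(field$irreps, norm_maxpool_forward(layer, field$values)$out)
}

#' Norm instance normalization
#'
#' Scalar channels: standard instance normalization (zero mean, unit
#' variance per channel). Non-scalar channels v: v / (mean voxel norm +
#' eps); norms are rotation invariant, so the map commutes with feature
#' rotations exactly.
#'
#' @param field an [irrep_field()].
#' @param eps stabilizer (default 1e-5).
#' @return an `irrep_field`.
#' @export
norm_instance_norm <- function(field, eps = 1e-5) {
  layer <- layer_norm_inorm(field$irreps, eps)
  irrep_field(field$irreps, norm_inorm_forward(layer, field$values)$out)
}

#' Trilinear upsampling
#' @param field an [irrep_field()].
#' @param factor integer upscaling factor (default 2).
#' @return an `irrep_field` at factor-times resolution.
#' @export
trilinear_upsample <- function(field, factor = 2L) {
  if (factor < 1) stop("factor must be >= 1")
  layer <- layer_upsample(factor)
  irrep_field(field$irreps, upsample_forward(layer, field$values)$out)
}
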