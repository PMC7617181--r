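# layer semantics, gradients, and exact equivariance

rot_field <- function(f, R) rotate_irrep_field(f, R, "exact-grid")

test_that("steerable conv: bias broadcast, shape contract, irreps check", {
  set.seed(1)
  basis <- sample_kernel_basis("1x0+1x1", "2x0+1x1", 3)
  w <- random_kernel_weights(basis)
  sc <- new_sc_weights(basis$irreps_in, basis$irreps_out, fill = 0.3)
  bias <- c(0.7, -0.2)
  zero <- irrep_field(basis$irreps_in, array(0, dim = c(4, 6, 6, 6)))
  out <- steerable_conv(zero, basis, w, sc, bias)
  expect_equal(dim(out$values), c(5, 6, 6, 6))
  expect_true(all(out$values[1, , , ] == 0.7))
  expect_true(all(out$values[2, , , ] == -0.2))
  expect_true(all(out$values[3:5, , , ] == 0))   # no bias on l=1
  bad <- random_irrep_field("2x0", c(6, 6, 6))
  expect_error(steerable_conv(bad, basis, w), "match")
})

test_that("scalar-only steerable conv is an ordinary isotropic convolution", {
  set.seed(2)
  basis <- sample_kernel_basis("2x0", "2x0", 5)
  w <- random_kernel_weights(basis)
  kern <- assemble_kernel(basis, w)
  # isotropy: invariant under all 24 grid rotations of the taps
  offs <- steerable3d:::kernel_offsets(5)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  kf <- array(kern, dim = c(2, 2, 125))
  for (R in octahedral_rotations()) {
    idx <- match(key(offs %*% t(R)), key(offs))
    expect_lt(max(abs(kf[, , idx] - kf)), 1e-12)
  }
  f <- random_irrep_field("2x0", c(8, 8, 8))
  out <- steerable_conv(f, basis, w)
  expect_equal(out$values, steerable3d:::conv3d_forward(f$values, kern))
})

test_that("self connection is a local, feature-rotation-equivariant map", {
  set.seed(3)
  ir_in <- irreps("2x0+2x1"); ir_out <- irreps("1x0+1x1")
  sc <- new_sc_weights(ir_in, ir_out)
  for (nm in names(sc)) sc[[nm]][] <- rnorm(length(sc[[nm]]))
  # scalar-only: per-voxel matrix multiply
  scs <- new_sc_weights("2x0", "3x0")
  scs$l0[] <- rnorm(6)
  fs <- random_irrep_field("2x0", c(4, 4, 4))
  out <- self_connection(fs, "3x0", scs)
  expect_equal(out$values[, 2, 3, 4], t(scs$l0) %*% fs$values[, 2, 3, 4],
               ignore_attr = TRUE)
  # locality: delta input -> delta output
  fd <- irrep_field(ir_in, array(0, dim = c(8, 5, 5, 5)))
  fd$values[, 3, 2, 4] <- rnorm(8)
  outd <- self_connection(fd, ir_out, sc)$values
  expect_true(all(outd[, -3, , ] == 0) && all(outd[, , -2, ] == 0))
  expect_gt(max(abs(outd[, 3, 2, 4])), 0)
  # feature-only Wigner rotation commutes exactly
  f <- random_irrep_field(ir_in, c(4, 4, 4))
  for (R in random_rotations(3, seed = 4)) {
    Din <- block_diag_wigner(ir_in, R); Dout <- block_diag_wigner(ir_out, R)
    fr <- irrep_field(ir_in, array(Din %*% matrix(f$values, 8),
                                   dim = dim(f$values)))
    a <- self_connection(fr, ir_out, sc)$values
    b <- array(Dout %*% matrix(self_connection(f, ir_out, sc)$values, 4),
               dim = dim(a))
    expect_lt(max(abs(a - b)), 1e-10)
  }
})

test_that("gated nonlinearity squashes non-scalars and drops the gates", {
  spec <- gate_spec("2x0+1x1+1x2")
  expect_identical(format(spec$irreps_in), "4x0+1x1+1x2")
  f <- random_irrep_field(spec$irreps_in, c(3, 3, 3))
  # gate pre-activation -> -Inf drives the gated channel to zero
  f$values[3, , , ] <- -1e4
  # gate value 0 scales its channel by exactly 0.5
  f$values[4, , , ] <- 0
  out <- gated_nonlinearity(f, spec)
  expect_identical(format(out$irreps), "2x0+1x1+1x2")
  expect_lt(max(abs(out$values[3:5, , , ])), 1e-12)
  expect_equal(out$values[6:10, , , ], 0.5 * f$values[8:12, , , ])
  # scalars pass through SiLU
  expect_equal(out$values[1, , , ],
               f$values[1, , , ] / (1 + exp(-f$values[1, , , ])))
  expect_error(gated_nonlinearity(random_irrep_field("2x0+1x1", c(3, 3, 3)),
                                  spec), "gate")
  # rotating features before or after gating is identical
  g <- random_irrep_field(spec$irreps_in, c(4, 4, 4))
  for (R in random_rotations(3, seed = 6)) {
    Din <- block_diag_wigner(spec$irreps_in, R)
    Dout <- block_diag_wigner(spec$irreps_out, R)
    gr <- irrep_field(spec$irreps_in,
                      array(Din %*% matrix(g$values, nrow(Din)),
                            dim = dim(g$values)))
    a <- gated_nonlinearity(gr, spec)$values
    b <- array(Dout %*% matrix(gated_nonlinearity(g, spec)$values,
                               nrow(Dout)), dim = dim(a))
    expect_lt(max(abs(a - b)), 1e-10)
  }
})

test_that("norm max-pooling keeps the full vector of largest norm", {
  # scalar channels reduce to standard max pooling
  set.seed(7)
  fs <- random_irrep_field("2x0", c(4, 4, 4))
  ps <- norm_max_pool(fs, 2)
  blk <- fs$values[1, 1:2, 1:2, 1:2]
  expect_equal(ps$values[1, 1, 1, 1], max(blk))
  # the worked vector window: largest norm wins as a whole vector
  f <- irrep_field("1x1", array(0, dim = c(3, 2, 2, 2)))
  f$values[, 1, 1, 1] <- c(1, 0, 0)
  f$values[, 2, 1, 1] <- c(0, -3, 0)
  f$values[, 1, 2, 1] <- c(0, 0, 2)
  f$values[, 2, 2, 1] <- c(1, 1, 1)
  out <- norm_max_pool(f, 2)
  expect_equal(as.vector(out$values), c(0, -3, 0))
  # spatially constant field: identical values at halved resolution
  fc <- irrep_field("1x0+1x1", array(rep(c(2, 0.3, -1, 4), 64),
                                     dim = c(4, 4, 4, 4)))
  pc <- norm_max_pool(fc, 2)
  expect_true(all(pc$values == c(2, 0.3, -1, 4)))
  expect_equal(dim(pc$values), c(4, 2, 2, 2))
  expect_error(norm_max_pool(random_irrep_field("1x0", c(5, 5, 5)), 2),
               "divisible")
  expect_error(layer_norm_maxpool("1x0", 0), "window")
})

test_that("norm instance normalization fixes norms and scalar moments", {
  # constant-norm vector field maps to norm ~ c/(c+eps)
  v <- array(0, dim = c(3, 4, 4, 4))
  v[1, , , ] <- 3; v[2, , , ] <- 4                 # norm 5 everywhere
  out <- norm_instance_norm(irrep_field("1x1", v), eps = 1e-5)
  nrm <- sqrt(colSums(matrix(out$values, 3)^2))
  expect_equal(max(abs(nrm - 5 / (5 + 1e-5))), 0, tolerance = 1e-12)
  # scalar channels: mean 0, variance 1
  set.seed(8)
  f <- random_irrep_field("3x0+2x1", c(6, 6, 6))
  o <- norm_instance_norm(f)
  for (c in 1:3) {
    expect_lt(abs(mean(o$values[c, , , ])), 1e-10)
    expect_equal(mean(o$values[c, , , ]^2), 1, tolerance = 1e-3)
  }
  # commutes with feature rotation (norms invariant)
  for (R in random_rotations(2, seed = 9)) {
    D <- block_diag_wigner(f$irreps, R)
    fr <- irrep_field(f$irreps, array(D %*% matrix(f$values, nrow(D)),
                                      dim = dim(f$values)))
    a <- norm_instance_norm(fr)$values
    b <- array(D %*% matrix(norm_instance_norm(f)$values, nrow(D)),
               dim = dim(a))
    expect_lt(max(abs(a - b)), 1e-10)
  }
})

test_that("trilinear upsampling is linear, identity at factor 1", {
  f <- irrep_field("1x0+1x1", array(rep(c(2, 0.3, -1, 4), 27),
                                    dim = c(4, 3, 3, 3)))
  up <- trilinear_upsample(f, 2)
  expect_equal(dim(up$values), c(4, 6, 6, 6))
  expect_true(all(abs(up$values - c(2, 0.3, -1, 4)) < 1e-12))  # constant
  expect_equal(trilinear_upsample(f, 1)$values, f$values)
  set.seed(10)
  a <- random_irrep_field("2x0", c(4, 4, 4))
  b <- random_irrep_field("2x0", c(4, 4, 4))
  ab <- irrep_field("2x0", a$values + b$values)
  expect_equal(trilinear_upsample(ab)$values,
               trilinear_upsample(a)$values + trilinear_upsample(b)$values)
})

test_that("every equivariant layer commutes with the 24 grid rotations", {
  set.seed(11)
  ir <- irreps("2x0+2x1+1x2")
  basis <- sample_kernel_basis(ir, ir, 3)
  conv <- layer_steerable_conv(basis)
  spec <- gate_spec("1x0+1x1")
  maps <- list(
    conv = function(f) irrep_field(ir, steerable3d:::steerable_conv_forward(
      conv, f$values)$out),
    inorm = function(f) norm_instance_norm(f),
    pool = function(f) norm_max_pool(f, 2),
    up = function(f) trilinear_upsample(f, 2)
  )
  f <- random_irrep_field(ir, c(8, 8, 8))
  for (nm in names(maps)) {
    errs <- vapply(octahedral_rotations(), function(R)
      as.numeric(equivariance_error(maps[[nm]], f, R)), 0)
    expect_lt(max(errs), 1e-5, label = paste("layer", nm))
  }
})

test_that("analytic backward passes match finite differences", {
  set.seed(12)
  ir_in <- irreps("2x0+1x1"); ir_out <- irreps("2x0+1x1+1x2")
  basis <- sample_kernel_basis(ir_in, ir_out, 3)
  lay <- layer_steerable_conv(basis)
  spec <- gate_spec(ir_out)
  cases <- list(
    sconv = list(layer = lay, ir = ir_in),
    gate = list(layer = layer_gate(spec), ir = spec$irreps_in),
    inorm = list(layer = layer_norm_inorm(ir_out), ir = ir_out),
    pool = list(layer = layer_norm_maxpool(ir_out, 2), ir = ir_out),
    up = list(layer = layer_upsample(2), ir = ir_out),
    lrelu = list(layer = layer_lrelu(), ir = ir_out)
  )
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    x <- random_irrep_field(cs$ir, c(4, 4, 4))$values
    fw <- steerable3d:::layer_forward(cs$layer, x)
    gy <- array(rnorm(length(fw$out)), dim = dim(fw$out))
    bk <- steerable3d:::layer_backward(cs$layer, fw$cache, gy)
    idx <- sample(length(x), 5)
    for (i in idx) {
      eps <- 1e-6
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      fd <- (sum(steerable3d:::layer_forward(cs$layer, xp)$out * gy) -
               sum(steerable3d:::layer_forward(cs$layer, xm)$out * gy)) /
        (2 * eps)
      expect_equal(bk$dx[i], fd, tolerance = 1e-4,
                   label = paste(nm, "input grad", i))
    }
  }
})
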