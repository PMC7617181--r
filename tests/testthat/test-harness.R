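test_that("exact-grid rotation: identity, composition, scalars unmixed", {
  set.seed(30)
  f <- random_irrep_field("2x0+1x1+1x2", c(6, 6, 6))
  expect_equal(rotate_irrep_field(f, diag(3))$values, f$values)
  R90 <- plane_rotation(90, "axial")
  twice <- rotate_irrep_field(rotate_irrep_field(f, R90), R90)
  once <- rotate_irrep_field(f, plane_rotation(180, "axial"))
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  # scalar-only fields: channels never mix, only the grid moves
  fs <- random_irrep_field("3x0", c(6, 6, 6))
  r <- rotate_irrep_field(fs, R90)
  expect_identical(sort(as.vector(r$values[2, , , ])),
                   sort(as.vector(fs$values[2, , , ])))
  expect_error(rotate_irrep_field(f, rotation_axis_angle(c(1, 1, 0), 0.3),
                                  "exact-grid"), "octahedral")
})

test_that("exact-grid rotation preserves norm and inverts exactly", {
  set.seed(31)
  f <- random_irrep_field("1x0+2x1", c(8, 8, 8))
  for (R in octahedral_rotations()[c(3, 12, 19)]) {
    fr <- rotate_irrep_field(f, R)
    expect_equal(sum(fr$values^2), sum(f$values^2), tolerance = 1e-12)
    back <- rotate_irrep_field(fr, t(R))
    expect_lt(max(abs(back$values - f$values)), 1e-6)
  }
})

test_that("interpolated rotation matches the exact path at 90 degrees", {
  set.seed(32)
  v <- array(rnorm(12^3), dim = c(12, 12, 12))
  R <- plane_rotation(90, "coronal")
  expect_equal(rotate_volume(v, R, "cubic"), rotate_volume(v, R, "nearest"))
  f <- random_irrep_field("1x1", c(12, 12, 12))
  a <- rotate_irrep_field(f, R, "exact-grid")
  b <- rotate_irrep_field(f, R, "interpolated")
  expect_lt(max(abs(a$values - b$values)), 1e-10)
})

test_that("equivariance_error separates equivariant from ordinary maps", {
  set.seed(33)
  ir <- irreps("2x0+1x1")
  f <- random_irrep_field(ir, c(8, 8, 8))
  idf <- function(g) g
  for (R in octahedral_rotations()[c(5, 20)])
    expect_equal(as.numeric(equivariance_error(idf, f, R)), 0)
  # pointwise scalar op: exactly zero error in exact-grid mode
  pw <- function(g) irrep_field(g$irreps, g$values) # identity on values
  expect_equal(as.numeric(equivariance_error(pw, f,
                                             octahedral_rotations()[[7]])), 0)
  # negative control: ordinary random-kernel convolution
  kern <- array(rnorm(5 * 5 * 27), dim = c(5, 5, 3, 3, 3))
  ordinary <- function(g)
    irrep_field(g$irreps, steerable3d:::conv3d_forward(g$values, kern))
  err <- as.numeric(equivariance_error(ordinary, f, plane_rotation(90, "axial")))
  expect_gt(err, 1e-2)
  # steerable conv passes where the ordinary conv fails
  basis <- sample_kernel_basis(ir, ir, 3)
  w <- random_kernel_weights(basis)
  st <- function(g) steerable_conv(g, basis, w)
  expect_lt(as.numeric(equivariance_error(st, f, plane_rotation(90, "axial"))),
            1e-5)
})

test_that("robustness_curve reproduces unrotated Dice at angle zero", {
  set.seed(34)
  spec <- phantom_spec(size = 24)
  ds <- lapply(c(51, 52), function(s) generate_phantom(spec, s))
  cfg <- unet_config(base_irreps = "2x0+1x1", levels = 2, kernel_size = 3,
                     in_channels = 1, n_classes = 6, ref_depth = 8,
                     l_max = 2)
  m <- build_equivariant_unet(cfg)
  rc <- robustness_curve(m, ds, angles = c(0), plane = "axial")
  direct <- evaluate_model(m, ds)
  agg <- stats::aggregate(dice ~ structure, direct, mean)
  expect_equal(rc$dice, agg$dice, tolerance = 1e-12)
  expect_identical(rc$structure, 1:5)
  expect_error(robustness_curve(m, list(), 0), "empty")
})
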