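test_that("path enumeration is complete and duplicate-free", {
  # scalars only: one l=0 path per channel pair
  p <- enumerate_paths("3x0", "2x0", 2)
  expect_equal(nrow(p), 6)
  expect_true(all(p$l == 0))
  # the 1x0+1x1 -> 1x0+1x1 example: six paths
  p <- enumerate_paths("1x0+1x1", "1x0+1x1", 2)
  expect_equal(nrow(p), 6)
  expect_equal(p$l[p$i == 2 & p$j == 2], 0:2)
  expect_equal(p$l[p$i == 1 & p$j == 2], 1)
  # oracle: independent brute-force count for the default 8:4:2 irreps
  ir <- irreps("8x0+4x1+2x2")
  ch <- irreps_channels(ir)
  brute <- 0L
  for (i in seq_len(nrow(ch))) for (j in seq_len(nrow(ch)))
    for (l in 0:4) if (abs(ch$l[i] - ch$l[j]) <= l && l <= ch$l[i] + ch$l[j])
      brute <- brute + 1L
  expect_identical(nrow(enumerate_paths(ir, ir, 4)), brute)
  expect_identical(anyDuplicated(enumerate_paths(ir, ir, 4)[, c("i", "j", "l")]),
                   0L)
})

test_that("sampled kernel basis is zero at the center voxel", {
  basis <- sample_kernel_basis("2x0+1x1", "1x0+1x1+1x2", 5)
  cen <- (5^3 + 1) / 2
  for (g in basis$groups) expect_true(all(g$B[, , cen, ] == 0))
  # and therefore any assembled kernel is exactly zero at the origin
  kern <- assemble_kernel(basis, random_kernel_weights(basis))
  expect_identical(max(abs(kern[, , 3, 3, 3])), 0)
  expect_error(sample_kernel_basis("1x0", "1x0", 4), "odd")
})

test_that("scalar-to-scalar basis blocks are isotropic on the grid", {
  basis <- sample_kernel_basis("1x0", "1x0", 5)
  offs <- steerable3d:::kernel_offsets(5)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  for (R in octahedral_rotations()) {
    idx <- match(key(offs %*% t(R)), key(offs))
    for (g in basis$groups) for (k in seq_len(dim(g$B)[4]))
      expect_lt(max(abs(g$B[1, 1, idx, k] - g$B[1, 1, , k])), 1e-12)
  }
})

test_that("sampled basis blocks steer exactly under grid rotations", {
  basis <- sample_kernel_basis("1x0+1x1+1x2", "1x0+1x1+1x2", 5)
  offs <- steerable3d:::kernel_offsets(5)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  set.seed(2)
  for (R in octahedral_rotations()[c(2, 8, 14, 21)]) {
    idx <- match(key(offs %*% t(R)), key(offs))
    for (g in basis$groups[c("1_1_1", "1_2_2", "2_2_0")]) {
      Di <- wigner_block(g$li, R); Dj <- wigner_block(g$lj, R)
      for (k in c(1, 4)) {
        Bk <- array(g$B[, , , k], dim = c(g$dj, g$di, length(idx)))
        rot <- Bk[, , idx, drop = FALSE]          # block at rotated taps
        conj <- array(0, dim = dim(rot))
        for (o in seq_len(dim(rot)[3]))
          conj[, , o] <- Dj %*% Bk[, , o] %*% t(Di)
        expect_lt(max(abs(rot - conj)), 1e-5)
      }
    }
  }
})

test_that("kernel assembly is linear in the weights", {
  basis <- sample_kernel_basis("1x0+1x1", "1x0+1x1", 3)
  expect_true(all(assemble_kernel(basis, new_kernel_weights(basis)) == 0))
  w1 <- random_kernel_weights(basis, 1)
  w2 <- random_kernel_weights(basis, 2)
  ws <- w1
  for (k in names(ws)) ws[[k]] <- w1[[k]] + w2[[k]]
  expect_equal(assemble_kernel(basis, ws),
               assemble_kernel(basis, w1) + assemble_kernel(basis, w2))
  bad <- w1; bad[[1]] <- array(0, dim = dim(bad[[1]]) + c(1L, 0L, 0L))
  expect_error(assemble_kernel(basis, bad), "shape")
  expect_error(kernel_weights_from_vector(basis, numeric(3)), "mismatch")
})

test_that("assembled-kernel convolution matches the direct path sum", {
  set.seed(10)
  basis <- sample_kernel_basis("2x0+1x1+1x2", "1x0+2x1+1x2", 3)
  w <- random_kernel_weights(basis)
  f <- random_irrep_field(basis$irreps_in, c(8, 8, 8))
  fast <- steerable_conv(f, basis, w)
  slow <- direct_path_sum_conv(f, basis, w)
  expect_lt(max(abs(fast$values - slow$values)) / max(abs(slow$values)), 1e-5)
})

test_that("parameter counting matches enumeration and grows with l_max", {
  expect_identical(count_parameters("1x0", "1x0", K = 5), 5L)
  ir_in <- "2x0+1x1"; ir_out <- "1x0+2x1+1x2"
  brute <- 5L * nrow(enumerate_paths(ir_in, ir_out, 4))
  expect_identical(count_parameters(ir_in, ir_out, K = 5, l_max = 4), brute)
  # self connection adds one weight per equal-order channel pair
  expect_identical(count_parameters(ir_in, ir_out, K = 5, l_max = 4,
                                    with_self_connection = TRUE),
                   brute + 2L * 1L + 1L * 2L)
  counts <- vapply(0:4, function(lm)
    count_parameters(ir_in, ir_out, K = 5, l_max = lm), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("kernel basis archives round-trip through disk", {
  basis <- sample_kernel_basis("1x0+1x1", "1x0+1x1", 3)
  path <- withr::local_tempdir()
  save_kernel_basis(basis, path)
  b2 <- load_kernel_basis(path)
  for (k in names(basis$groups))
    expect_identical(b2$groups[[k]]$B, basis$groups[[k]]$B)
})
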