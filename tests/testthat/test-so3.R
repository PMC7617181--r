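test_that("selection rule enumerates exactly the allowed orders", {
  expect_identical(allowed_paths(0, 0, 2), 0L)
  expect_identical(allowed_paths(1, 1, 2), 0:2)
  expect_identical(allowed_paths(2, 2, 4), 0:4)
  expect_identical(allowed_paths(0, 2, 4), 2L)
  expect_length(allowed_paths(0, 2, 1), 0)
  # brute force: l allowed iff a triangle of orders exists
  for (li in 0:3) for (lj in 0:3) {
    brute <- Filter(function(l) abs(li - lj) <= l && l <= li + lj, 0:4)
    expect_identical(allowed_paths(li, lj, 4), as.integer(brute))
  }
})

test_that("real spherical harmonics: parity, invariance, steerability", {
  u <- matrix(rnorm(30), 3)
  y0 <- real_spherical_harmonics(0, u)
  expect_lt(diff(range(y0)), 1e-14)           # l = 0 rotation-invariant
  y1 <- real_spherical_harmonics(1, u)
  expect_equal(real_spherical_harmonics(1, -u), -y1)  # odd parity
  expect_error(real_spherical_harmonics(1, c(0, 0, 0)), "degenerate")
  for (l in 0:4) for (R in random_rotations(5, seed = l + 1)) {
    lhs <- real_spherical_harmonics(l, R %*% u)
    rhs <- wigner_block(l, R) %*% real_spherical_harmonics(l, u)
    expect_lt(max(abs(lhs - rhs)), 1e-6)
  }
})

test_that("Wigner blocks are orthogonal homomorphisms, similar to R at l=1", {
  expect_equal(wigner_block(0, diag(3)), matrix(1, 1, 1))
  rots <- random_rotations(20, seed = 3)
  for (l in 1:3) {
    for (i in seq(1, 19, by = 2)) {
      R1 <- rots[[i]]; R2 <- rots[[i + 1]]
      D1 <- wigner_block(l, R1)
      expect_lt(max(abs(D1 %*% t(D1) - diag(2 * l + 1))), 1e-6)
      expect_lt(max(abs(wigner_block(l, R1 %*% R2) -
                          D1 %*% wigner_block(l, R2))), 1e-6)
    }
  }
  R <- rots[[1]]
  D1 <- wigner_block(1, R)
  expect_equal(sum(diag(D1)), sum(diag(R)), tolerance = 1e-10)
  expect_equal(det(D1), det(R), tolerance = 1e-10)
  expect_error(wigner_block(1, matrix(1, 3, 3)), "orthogonal")
})

test_that("Clebsch-Gordan blocks realize the classical tensor products", {
  expect_equal(as.vector(clebsch_gordan(0, 0, 0)), 1)
  C110 <- matrix(clebsch_gordan(1, 1, 0), 3, 3)
  expect_equal(C110, diag(3) / sqrt(3))       # dot product up to 1/sqrt(3)
  C111 <- clebsch_gordan(1, 1, 1)
  expect_lt(max(abs(C111 + aperm(C111, c(2, 1, 3)))), 1e-10)  # antisymmetric
  expect_equal(abs(C111[1, 2, 3]), 1 / sqrt(6), tolerance = 1e-10)
  expect_true(all(clebsch_gordan(0, 1, 2) == 0))  # selection rule violated
})

test_that("Clebsch-Gordan equivariance identity holds for l <= 3", {
  rots <- random_rotations(20, seed = 9)
  for (l1 in 0:3) for (l2 in 0:3) for (l3 in allowed_paths(l1, l2, 3)) {
    C <- clebsch_gordan(l1, l2, l3)
    Cm <- matrix(C, (2 * l1 + 1) * (2 * l2 + 1), 2 * l3 + 1)
    for (R in rots[c(1, 8, 20)]) {
      lhs <- kronecker(wigner_block(l2, R), wigner_block(l1, R)) %*% Cm
      rhs <- Cm %*% wigner_block(l3, R)
      expect_lt(max(abs(lhs - rhs)), 1e-6)
    }
  }
})

test_that("the octahedral group has 24 elements and is closed", {
  octa <- octahedral_rotations()
  expect_length(octa, 24)
  expect_true(all(octa[[1]] == diag(3)))
  key <- function(R) paste(round(as.vector(R)), collapse = ",")
  keys <- vapply(octa, key, "")
  expect_identical(anyDuplicated(keys), 0L)
  for (A in octa) {
    expect_true(key(t(A)) %in% keys)           # inverse closure
    for (B in octa) expect_true(key(A %*% B) %in% keys)
  }
})

test_that("wigner_block at l=1 restricted to the grid rotations is faithful", {
  octa <- octahedral_rotations()
  mats <- lapply(octa, function(R) wigner_block(1, R))
  key <- function(M) paste(round(as.vector(M), 8), collapse = ",")
  expect_identical(anyDuplicated(vapply(mats, key, "")), 0L)  # 24 distinct
  # and a group: product of two images is the image of the product
  A <- octa[[5]]; B <- octa[[17]]
  expect_equal(wigner_block(1, A %*% B), mats[[5]] %*% mats[[17]],
               tolerance = 1e-10)
})
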