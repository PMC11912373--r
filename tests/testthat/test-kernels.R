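test_that("anti_hermitize projects onto exact anti-Hermiticity", {
  # i * Laplacian is already anti-Hermitian
  A <- kernel_ilap3(2)
  expect_identical(anti_hermitize(A), A)
  # a purely real symmetric kernel has no anti-Hermitian part
  s <- matrix(c(1, 2, 1, 2, 5, 2, 1, 2, 1), 3, 3)
  expect_true(all(anti_hermitize(s) == 0))
  # random kernels pass the identity at every offset, exactly
  set.seed(7)
  raw <- matrix(complex(real = rnorm(49), imaginary = rnorm(49)), 7, 7)
  A7 <- anti_hermitize(raw)
  flip <- A7[7:1, 7:1]
  expect_identical(max(Mod(A7 + Conj(flip))), 0)
  expect_error(anti_hermitize(matrix(0i, 4, 4)), "odd")
})

test_that("disk_mask keeps exactly the offsets inside the radius", {
  k <- matrix(1 + 0i, 7, 7)
  # strict Euclidean disk of radius 3: 29 integer offsets
  expect_identical(sum(disk_mask(k, 3) != 0), 29L)
  # radius 4 rounds only the corners (offset sqrt(18)): 45 offsets kept
  m4 <- disk_mask(k, 4)
  expect_identical(sum(m4 != 0), 45L)
  expect_true(all(m4[c(1, 7), c(1, 7)] == 0))
  expect_identical(sum(disk_mask(k, 0) != 0), 1L)
  expect_identical(disk_mask(k, 10), k)
})

test_that("conv_exp produces unit-modulus spectra and checks its input", {
  # zero generator -> convolution identity
  U0 <- conv_exp(matrix(0i, 3, 3), c(16, 16))
  expect_equal(U0$spectrum, matrix(1 + 0i, 16, 16), tolerance = 1e-15)
  # closed-form 1D dispersion of the [1, -2, 1] stencil
  U1 <- conv_exp(kernel_ilap3(1), 64)
  k <- 0:63
  expect_equal(U1$gen_spectrum, 1i * (2 * cos(2 * pi * k / 64) - 2),
               tolerance = 1e-12)
  # non-anti-Hermitian input is refused, naming the offset
  bad <- kernel_ilap3(2)
  bad[1, 2] <- bad[1, 2] + 0.5
  expect_error(conv_exp(bad, c(16, 16)), "offset")
})

test_that("preset kernels are unitary on the lattice and norm-preserving", {
  for (shape in list(64L, c(32L, 32L))) {
    dim <- length(shape)
    for (A in list(kernel_ilap3(dim), kernel_random7(3, dim))) {
      U <- conv_exp(A, shape)
      expect_lt(max(abs(Mod(U$spectrum) - 1)), 1e-12)
      Z <- rcfield(shape, seed = dim)
      expect_lt(abs(sqrt(sum(Mod(conv_apply(U, Z))^2)) -
                      sqrt(sum(Mod(Z)^2))), 1e-10)
    }
  }
})

test_that("FFT convolution, circulant matrix, and direct summation agree", {
  set.seed(11)
  for (rep in 1:3) {
    k <- anti_hermitize(matrix(complex(real = rnorm(9), imaginary = rnorm(9)),
                               3, 3))
    Z <- rcfield(c(16, 16), seed = rep)
    M <- build_circulant_matrix(k, c(16, 16))
    U <- conv_exp(k, c(16, 16))
    via_fft <- wavegate:::fft_inv(stats::fft(wavegate:::embed_kernel(k, c(16, 16))) * stats::fft(Z))
    via_mat <- matrix(M %*% as.vector(Z), 16, 16)
    via_sum <- direct_conv(k, Z)
    expect_lt(max(Mod(via_fft - via_mat)), 1e-10)
    expect_lt(max(Mod(via_fft - via_sum)), 1e-10)
  }
  expect_error(build_circulant_matrix(kernel_ilap3(2), c(128, 128)),
               "guarded")
})

test_that("circulant eigenvalues are the spectrum of the kernel", {
  k <- kernel_random7(5, 2)
  M <- build_circulant_matrix(k, c(12, 12))
  ev <- eigen(M, only.values = TRUE)$values
  FK <- as.vector(stats::fft(wavegate:::embed_kernel(k, c(12, 12))))
  # multiset agreement via spectral moments and pointwise nearest distance
  for (p in 1:3)
    expect_equal(sum(ev^p), sum(FK^p), tolerance = 1e-8)
  for (e in ev[1:20])
    expect_lt(min(Mod(e - FK)), 1e-8)
})

test_that("identity kernel produces the identity circulant", {
  ident <- matrix(0i, 3, 3); ident[2, 2] <- 1
  expect_equal(build_circulant_matrix(ident, c(8, 8)), diag(64) + 0i,
               tolerance = 1e-15)
})

test_that("conv_exp obeys the one-parameter group property", {
  A <- kernel_random7(1, 2)
  U1 <- conv_exp(A, c(32, 32))
  U2 <- conv_exp(2 * A, c(32, 32))
  expect_lt(max(Mod(U2$spectrum - U1$spectrum^2)), 1e-12)
})

test_that("pick_eigenfrequency returns unit-circle dispersion values", {
  U <- conv_exp(kernel_ilap3(2), c(32, 32))
  expect_equal(pick_eigenfrequency(U, c(0, 0)), 1 + 0i, tolerance = 1e-14)
  set.seed(12)
  for (rep in 1:10) {
    k <- sample(0:31, 2, replace = TRUE)
    lam <- pick_eigenfrequency(U, k)
    expect_lt(abs(Mod(lam) - 1), 1e-12)
    # even real stencil times i: the dispersion is even in k, so the
    # eigenvalue at -k equals (not conjugates) the one at k
    k_neg <- (32 - k) %% 32
    expect_equal(pick_eigenfrequency(U, k_neg), lam, tolerance = 1e-12)
  }
  expect_error(pick_eigenfrequency(U, c(32, 0)), "wavenumber")
})
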