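test_that("phi matches its closed form and preserves phase", {
  expect_identical(phi(0), 0)
  expect_equal(phi(1), 0.7071067811865475, tolerance = 1e-15)
  set.seed(1)
  z <- complex(real = rnorm(50, sd = 3), imaginary = rnorm(50, sd = 3))
  expect_equal(Arg(phi(z)), Arg(z), tolerance = 1e-12)
  expect_true(all(Mod(phi(z)) < 1))
  expect_error(phi(c(1, NaN)), "non-finite")
})

test_that("phi is a contraction everywhere off the origin", {
  set.seed(2)
  a <- complex(real = rnorm(100, sd = 5), imaginary = rnorm(100, sd = 5))
  b <- complex(real = rnorm(100, sd = 5), imaginary = rnorm(100, sd = 5))
  keep <- a != b
  expect_true(all(Mod(phi(a[keep]) - phi(b[keep])) < Mod(a[keep] - b[keep])))
})

test_that("phi_prime is the radial slope of |phi|", {
  expect_identical(phi_prime(0), 1)
  expect_equal(phi_prime(1), 0.3535533905932738, tolerance = 1e-15)
  set.seed(3)
  z <- complex(real = rnorm(20), imaginary = rnorm(20))
  expect_true(all(phi_prime(z) < 1))
  # central differences of |phi| along the ray through z
  h <- 1e-6
  u <- z / Mod(z)
  num <- (Mod(phi(z + h * u)) - Mod(phi(z - h * u))) / (2 * h)
  expect_equal(num, phi_prime(z), tolerance = 1e-6)
})

test_that("phi_inverse round-trips and rejects the closed disk boundary", {
  # round-trip precision is limited by the cancellation in 1 - |w|^2,
  # which loses a relative |z|^2 * eps near the disk boundary
  set.seed(4)
  z_small <- complex(real = rnorm(40, sd = 5), imaginary = rnorm(40, sd = 5))
  expect_equal(phi_inverse(phi(z_small)), z_small, tolerance = 1e-12)
  z <- c(complex(real = rnorm(20, sd = 100), imaginary = rnorm(20, sd = 100)),
         1000 + 0i, 1e3 * 1i)
  expect_equal(phi_inverse(phi(z)), z, tolerance = 1e-9)
  expect_equal(phi(phi_inverse(phi(2.0))), phi(2.0), tolerance = 1e-15)
  expect_error(phi_inverse(c(0.5 + 0i, 1 + 0i)), "index 2")
  expect_error(phi_inverse(1.2), "\\|w\\| < 1")
})

test_that("scalar fixed point follows the singular cubic-root laws", {
  fp0 <- scalar_fixed_point(0)
  expect_identical(Mod(fp0$z_star), 0)
  expect_identical(fp0$gamma, 1)
  expect_identical(fp0$tau, Inf)

  fp <- scalar_fixed_point(1e-3)
  expect_lt(Mod(fp$z_star + fp$input_I - phi_inverse(fp$z_star)), 1e-10)
  expect_equal(Mod(fp$z_star), (2e-3)^(1 / 3), tolerance = 0.05)

  fp4 <- scalar_fixed_point(1e-4)
  expect_equal(fp4$tau, (2 / 3) * (2e-4)^(-2 / 3), tolerance = 0.05)

  I <- 10^seq(-6, -4, length.out = 8)
  fps <- lapply(I, scalar_fixed_point)
  z <- vapply(fps, function(f) Mod(f$z_star), numeric(1))
  tau <- vapply(fps, function(f) f$tau, numeric(1))
  expect_equal(unname(coef(lm(log(z) ~ log(I)))[2]), 1 / 3, tolerance = 0.03)
  expect_equal(unname(coef(lm(log(tau) ~ log(I)))[2]), -2 / 3,
               tolerance = 0.03)
})

test_that("the fixed-point solver reports non-convergence", {
  expect_error(scalar_fixed_point(0.5, tol = 1e-12, max_iter = 3),
               "did not converge")
})
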