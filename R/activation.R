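#' Phase-preserving complex sigmoid activation
#'
#' The element-wise activation `phi(z) = z / sqrt(1 + |z|^2)`. It maps the
#' complex plane into the open unit disk, preserves the complex phase of its
#' argument, satisfies `phi(0) = 0` with unit slope at the origin, and is a
#' contraction everywhere else (`0 < phi'(z) < 1` for `z != 0`). These
#' properties place the quiescent state of a unitary-coupled network exactly
#' at a critical (marginally stable) point.
#'
#' @param z Complex (or real) scalar or field; applied element-wise.
#' @return Same shape as `z`; all moduli are strictly below 1.
#' @seealso [phi_prime()], [phi_inverse()], [scalar_fixed_point()]
#' @examples
#' phi(0)        # 0
#' phi(1)        # 1/sqrt(2)
#' Arg(phi(2i))  # phase preserved
#' @export
phi <- function(z) {
  check_finite(z, "phi() argument")
  z / sqrt(1 + Mod(z)^2)
}

#' Radial slope of the activation
#'
#' The scalar derivative `phi'(z) = (1 + |z|^2)^(-3/2)`: the slope of the
#' modulus of [phi()] along the ray through `z`. This is the quantity that
#' plays the role of the local attenuation factor Gamma in the linearized
#' dynamics. The activation is not holomorphic; all linearization in this
#' package follows this radial-slope convention.
#'
#' @inheritParams phi
#' @return Real, same shape as `z`; values in `(0, 1]`, equal to 1 only at
#'   `z = 0`.
#' @export
phi_prime <- function(z) {
  check_finite(z, "phi_prime() argument")
  (1 + Mod(z)^2)^(-1.5)
}

#' Inverse of the activation
#'
#' `phi_inverse(w) = w / sqrt(1 - |w|^2)`, defined on the open unit disk.
#' Required by the inverse-design formula, which reads the desired steady
#' state back through the activation.
#'
#' @param w Complex scalar or field with `|w| < 1` element-wise.
#' @return Same shape as `w`; `phi(phi_inverse(w))` equals `w` to round-off.
#' @export
phi_inverse <- function(w) {
  check_finite(w, "phi_inverse() argument")
  m2 <- Mod(w)^2
  if (any(m2 >= 1)) {
    bad <- which(m2 >= 1)
    stop(sprintf(
      "phi_inverse() requires |w| < 1; violated at %d site(s), first at index %d (|w| = %g)",
      length(bad), bad[1], sqrt(m2[bad[1]])), call. = FALSE)
  }
  w / sqrt(1 - m2)
}

#' Scalar fixed point of the driven single-neuron map
#'
#' Iterates the scalar recurrence `z <- phi(z + I)` from `z = 0` until
#' convergence. For constant input `I` the map is globally attracting and the
#' iteration converges to the fixed point `z*` satisfying
#' `z* = phi(z* + I)`. The function also reports the slope
#' `gamma = phi'(z* + I)` at the fixed point and the relaxation time
#' `tau = -1 / log(gamma)` (in steps).
#'
#' For small real `I > 0` the fixed point obeys the singular cubic-root law
#' `z* ~ (2 I)^(1/3)` and the relaxation time the companion power law
#' `tau ~ (2/3) (2 I)^(-2/3)`: tiny inputs move the operating point, and
#' hence the local attenuation, enormously. At `I = 0` the fixed point sits
#' exactly at criticality: `gamma = 1` and `tau` is reported as `Inf`
#' (relaxation is algebraic, not exponential).
#'
#' @param I Complex (or real) scalar input.
#' @param tol Convergence tolerance on `|z_{n+1} - z_n|`.
#' @param max_iter Iteration budget.
#' @return An object of class `"scalar_fixed_point"`: a list with elements
#'   `input_I`, `z_star`, `gamma`, `tau`, `iterations`.
#' @examples
#' fp <- scalar_fixed_point(1e-3)
#' fp$z_star                      # close to (2e-3)^(1/3)
#' scalar_fixed_point(0)$tau      # Inf
#' @export
scalar_fixed_point <- function(I, tol = 1e-12, max_iter = 1e6) {
  stopifnot(length(I) == 1L, tol > 0)
  check_finite(I, "scalar_fixed_point() input")
  z <- 0i
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    z_new <- .phi(z + I)
    if (Mod(z_new - z) < tol) {
      z <- z_new
      converged <- TRUE
      break
    }
    z <- z_new
  }
  if (!converged)
    stop(sprintf(
      "scalar fixed point did not converge within %d iterations (last iterate %s)",
      as.integer(max_iter), format(z)), call. = FALSE)
  gamma <- phi_prime(z + I)
  tau <- if (gamma >= 1) Inf else -1 / log(gamma)
  structure(list(input_I = I, z_star = z, gamma = gamma, tau = tau,
                 iterations = it, tol = tol),
            class = "scalar_fixed_point")
}

#' @export
print.scalar_fixed_point <- function(x, ...) {
  cat("Scalar fixed point of z <- phi(z + I)\n")
  cat(sprintf("  I      : %s\n", format(x$input_I)))
  cat(sprintf("  z*     : %s\n", format(x$z_star)))
  cat(sprintf("  gamma  : %.12g\n", x$gamma))
  cat(sprintf("  tau    : %s steps\n",
              if (is.finite(x$tau)) format(x$tau, digits = 6) else "Inf"))
  cat(sprintf("  (converged in %d iterations, tol %g)\n", x$iterations, x$tol))
  invisible(x)
}
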