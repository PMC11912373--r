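# Anti-Hermitian generators, their unitary convolutional exponentials, and
# the explicit circulant-matrix realization used as a cross-validation oracle.
#
# Compact kernels are plain complex vectors (1D) or matrices (2D) with odd
# side lengths; the center entry is the offset-0 coefficient and entries are
# indexed by signed offsets around it. When embedded on the periodic lattice
# the offset-0 coefficient lands at lattice index 1 (DFT origin), so kernel
# spectra are directly comparable across lattice sizes.

kernel_flip <- function(k) {
  if (is.matrix(k)) k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]
  else rev(k)
}

check_odd_kernel <- function(k) {
  d <- shape_of(k)
  if (any(d %% 2L == 0L))
    stop("kernel must have odd side lengths (a defined center)", call. = FALSE)
  invisible(k)
}

# Max violation of A(-x) = -conj(A(x)) plus the offending offset.
anti_hermiticity_violation <- function(k) {
  v <- Mod(k + Conj(kernel_flip(k)))
  i <- which.max(v)
  d <- shape_of(k)
  off <- if (is.matrix(k)) {
    c((i - 1) %% d[1] + 1 - (d[1] + 1) / 2, (i - 1) %/% d[1] + 1 - (d[2] + 1) / 2)
  } else i - (d + 1) / 2
  list(max = v[i], offset = off)
}

#' Project a compact kernel onto its anti-Hermitian part
#'
#' Returns `(A(x) - conj(A(-x))) / 2`, the anti-Hermitian component of a
#' compact convolution kernel (offset negation is index reflection about the
#' kernel center). The convolutional exponential of an anti-Hermitian
#' generator is unitary, so this is the standard way to manufacture valid
#' generators from arbitrary raw kernels.
#'
#' @param raw Complex vector (1D) or matrix (2D) with odd side lengths.
#' @return A kernel of the same shape satisfying `A(-x) = -conj(A(x))`
#'   exactly.
#' @examples
#' anti_hermitize(kernel_ilap3(2))  # already anti-Hermitian: unchanged
#' @export
anti_hermitize <- function(raw) {
  check_odd_kernel(raw)
  check_finite(raw, "kernel")
  (raw - Conj(kernel_flip(raw))) / 2
}

#' Restrict a compact kernel to a disk of given radius
#'
#' Zeroes all kernel entries whose Euclidean offset from the center exceeds
#' `radius` (in sites). A 7x7 kernel masked at radius 3 becomes the
#' "7x7 kernel with rounded corners" used for random local generators.
#'
#' @param kernel Compact kernel (odd side lengths).
#' @param radius Nonnegative disk radius in sites.
#' @return The masked kernel.
#' @export
disk_mask <- function(kernel, radius) {
  check_odd_kernel(kernel)
  stopifnot(radius >= 0)
  d <- shape_of(kernel)
  if (is.matrix(kernel)) {
    r <- (d - 1L) / 2L
    ox <- seq_len(d[1]) - r[1] - 1L
    oy <- seq_len(d[2]) - r[2] - 1L
    keep <- outer(ox^2, oy^2, "+") <= radius^2
  } else {
    keep <- abs(seq_len(d) - (d + 1L) / 2L) <= radius
  }
  kernel[!keep] <- 0i
  kernel
}

#' Built-in kernel generators
#'
#' `kernel_ilap3(dim)` is `i` times the finite-difference Laplacian stencil
#' (`[1, -2, 1]` in 1D; the five-point stencil with center `-4` in 2D), the
#' workhorse wave generator: its dispersion relation is that of a discrete
#' wave equation. `kernel_random7(seed, dim)` is a seeded random complex
#' Gaussian kernel of side 7, projected onto its anti-Hermitian part and
#' restricted to a disk: only the four corner offsets (Euclidean distance
#' `sqrt(18)`) are zeroed, leaving a 45-coefficient rounded-corner support.
#'
#' @param dim Lattice dimensionality, 1 or 2.
#' @param seed Integer seed for the random kernel.
#' @return A compact anti-Hermitian kernel.
#' @export
kernel_ilap3 <- function(dim = 2) {
  if (dim == 1) 1i * c(1, -2, 1)
  else 1i * matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
}

#' @rdname kernel_ilap3
#' @export
kernel_random7 <- function(seed = 0L, dim = 2) {
  raw <- with_seed(seed, {
    if (dim == 1) rcnorm(7) else matrix(rcnorm(49), 7, 7)
  })
  disk_mask(anti_hermitize(raw), 4)
}

#' Look up a kernel preset by name
#'
#' @param name `"ilap3"` or `"random7"`.
#' @inheritParams kernel_random7
#' @export
kernel_preset <- function(name, dim = 2, seed = 0L) {
  switch(name,
         ilap3 = kernel_ilap3(dim),
         random7 = kernel_random7(seed, dim),
         stop(sprintf("unknown kernel preset '%s' (available: ilap3, random7)",
                      name), call. = FALSE))
}

# Embed a compact kernel on the periodic lattice with its center at the DFT
# origin (lattice index 1), wrapping negative offsets.
embed_kernel <- function(k, shape) {
  shape <- as.integer(shape)
  d <- shape_of(k)
  if (length(shape) != length(d))
    stop("kernel and lattice dimensionality differ", call. = FALSE)
  if (any(shape < d))
    stop("lattice dimensions must be at least the kernel dimensions",
         call. = FALSE)
  E <- field_zero(shape)
  if (is.matrix(k)) {
    r <- (d - 1L) / 2L
    ri <- ((-r[1]:r[1]) %% shape[1]) + 1L
    ci <- ((-r[2]:r[2]) %% shape[2]) + 1L
    E[ri, ci] <- k
  } else {
    r <- (d - 1L) / 2L
    E[((-r:r) %% shape) + 1L] <- k
  }
  E
}

#' Exponentiate an anti-Hermitian generator into a unitary convolution kernel
#'
#' Computes the convolutional exponential `U = exp_conv(A)`: the generator is
#' embedded on the periodic lattice, Fourier transformed, exponentiated
#' element-wise, and the resulting spectrum `F[U] = exp(F[A])` is cached.
#' Because `F[A]` is purely imaginary for anti-Hermitian `A` (this is the
#' dispersion relation, assigning a temporal frequency to each spatial
#' wavenumber), every element of `F[U]` lies on the unit circle and
#' convolution with `U` preserves the L2 norm exactly.
#'
#' @param A Compact anti-Hermitian kernel (see [anti_hermitize()]).
#' @param lattice_shape Integer `N` (1D) or `c(H, W)` (2D).
#' @param tol Tolerance for the anti-Hermiticity check.
#' @return An object of class `"unitary_kernel"`: list with `A`, `shape`,
#'   `ndim`, `support_radius`, `spectrum` (`F[U]`, full lattice) and
#'   `gen_spectrum` (`F[A]`).
#' @examples
#' U <- conv_exp(kernel_ilap3(1), 64)
#' max(abs(Mod(U$spectrum) - 1))   # ~1e-16: all eigenvalues on unit circle
#' @export
conv_exp <- function(A, lattice_shape, tol = 1e-12) {
  check_odd_kernel(A)
  viol <- anti_hermiticity_violation(A)
  if (viol$max > tol)
    stop(sprintf(
      "generator is not anti-Hermitian: |A(x) + conj(A(-x))| = %g at offset (%s)",
      viol$max, paste(viol$offset, collapse = ", ")), call. = FALSE)
  shape <- as.integer(lattice_shape)
  FA <- fft_fwd(embed_kernel(A, shape))
  structure(list(A = A, shape = shape, ndim = length(shape),
                 support_radius = max((shape_of(A) - 1L) %/% 2L),
                 gen_spectrum = FA, spectrum = exp(FA)),
            class = "unitary_kernel")
}

#' @export
print.unitary_kernel <- function(x, ...) {
  cat(sprintf("Unitary convolution kernel on %s lattice\n",
              paste(x$shape, collapse = "x")))
  cat(sprintf("  generator support: %s (radius %d)\n",
              paste(shape_of(x$A), collapse = "x"), x$support_radius))
  cat(sprintf("  max | |F[U]| - 1 |: %.3g\n", max(abs(Mod(x$spectrum) - 1))))
  invisible(x)
}

#' Apply a unitary kernel to a field by spectral multiplication
#'
#' Computes the periodic convolution `U (x) Z` as
#' `ifft(F[U] * fft(Z))`; this is the only coupling operation the full
#' nonlinear map needs.
#'
#' @param U A `"unitary_kernel"` from [conv_exp()].
#' @param Z Complex field matching `U$shape`.
#' @return The convolved field.
#' @export
conv_apply <- function(U, Z) {
  stopifnot_same_shape(U$spectrum, Z, "kernel lattice", "field")
  fft_inv(U$spectrum * fft_fwd(Z))
}

#' Materialize the circulant matrix of a compact kernel
#'
#' Builds the dense matrix `[k (x)]` acting on unrolled fields (column
#' concatenation for 2D lattices), such that
#' `M %*% as.vector(Z)` equals the periodic convolution `k (x) Z` exactly.
#' In 1D this is a circulant matrix; in 2D it is a block-circulant
#' arrangement of circulant blocks. Its eigenvalues are exactly the multiset
#' of values of `F[k]` over the lattice, which makes it the natural
#' linear-algebra cross-check for the FFT path.
#'
#' @param kernel Compact kernel (odd side lengths).
#' @inheritParams conv_exp
#' @return A dense complex matrix of size `prod(lattice_shape)` squared.
#' @export
build_circulant_matrix <- function(kernel, lattice_shape) {
  shape <- as.integer(lattice_shape)
  n <- prod(shape)
  if (n > 4096)
    stop(sprintf("lattice has %d sites; build_circulant_matrix() is guarded at 4096",
                 n), call. = FALSE)
  E <- embed_kernel(kernel, shape)
  idx <- seq_len(n)
  if (length(shape) == 2L) {
    r <- (idx - 1L) %% shape[1]
    c_ <- (idx - 1L) %/% shape[1]
    dr <- outer(r, r, "-") %% shape[1]
    dc <- outer(c_, c_, "-") %% shape[2]
    M <- matrix(E[cbind(as.vector(dr) + 1L, as.vector(dc) + 1L)], n, n)
  } else {
    d <- outer(idx, idx, "-") %% shape
    M <- matrix(E[as.vector(d) + 1L], n, n)
  }
  M
}

#' Eigenvalue of a unitary kernel at a given wavenumber
#'
#' The eigenvalues of convolution with `U` are the elements of `F[U]` and the
#' corresponding eigenvectors are the Fourier modes. This accessor returns
#' the unit-circle eigenvalue at an integer wavenumber, the natural choice
#' of forcing frequency for resonant point sources.
#'
#' @param U A `"unitary_kernel"`.
#' @param wavenumber Integer wavenumber per axis, each in `[0, N)` (standard
#'   DFT ordering).
#' @return Complex scalar of unit modulus.
#' @export
pick_eigenfrequency <- function(U, wavenumber) {
  k <- as.integer(wavenumber)
  if (length(k) != U$ndim || any(k < 0L) || any(k >= U$shape))
    stop(sprintf("wavenumber must have %d component(s), each in [0, N)",
                 U$ndim), call. = FALSE)
  if (U$ndim == 2L) U$spectrum[k[1] + 1L, k[2] + 1L] else U$spectrum[k + 1L]
}
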