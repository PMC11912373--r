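# Internal helpers shared across modules. Fields are plain complex vectors
# (1D, length N) or matrices (2D, H x W); lattices are always periodic.

fft_fwd <- function(x) stats::fft(x)

fft_inv <- function(x) stats::fft(x, inverse = TRUE) / length(x)

shape_of <- function(x) if (is.matrix(x)) dim(x) else length(x)

stopifnot_same_shape <- function(a, b, what_a = "a", what_b = "b") {
  if (!identical(as.integer(shape_of(a)), as.integer(shape_of(b))))
    stop(sprintf("shape mismatch: %s is %s, %s is %s", what_a,
                 paste(shape_of(a), collapse = "x"), what_b,
                 paste(shape_of(b), collapse = "x")), call. = FALSE)
  invisible(NULL)
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

# Unchecked activation for hot loops; the exported phi() validates its input.
.phi <- function(z) z / sqrt(1 + Mod(z)^2)

#' Create an all-zero complex field
#'
#' @param shape Lattice shape: a single integer `N` for a 1D field or a
#'   length-2 integer vector `c(H, W)` for a 2D field.
#' @return A complex vector (1D) or matrix (2D) of zeros.
#' @export
field_zero <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) complex(shape)
  else if (length(shape) == 2L) matrix(complex(prod(shape)), shape[1], shape[2])
  else stop("shape must have length 1 or 2", call. = FALSE)
}

#' Create a delta field (single unit impulse)
#'
#' @inheritParams field_zero
#' @param site Lattice site: scalar index (1D) or `c(row, col)` (2D), 1-based.
#' @return A complex field that is 1 at `site` and 0 elsewhere.
#' @export
field_delta <- function(shape, site) {
  z <- field_zero(shape)
  si <- site_index(shape, site)
  z[si] <- 1 + 0i
  z
}

# Linear (column-major) index of a site given as scalar (1D) or c(row, col).
site_index <- function(shape, site) {
  shape <- as.integer(shape)
  site <- as.integer(site)
  if (length(shape) == 1L) {
    if (length(site) != 1L || site < 1L || site > shape)
      stop("site out of range for 1D lattice", call. = FALSE)
    site
  } else {
    if (length(site) != 2L || any(site < 1L) || any(site > shape))
      stop("site out of range for 2D lattice", call. = FALSE)
    (site[2] - 1L) * shape[1] + site[1]
  }
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Standard complex Gaussian draws (unit variance: Re and Im each N(0, 1/2)).
rcnorm <- function(n) complex(real = stats::rnorm(n, sd = sqrt(0.5)),
                              imaginary = stats::rnorm(n, sd = sqrt(0.5)))

#' Root-mean-square amplitude over a region
#'
#' Computes `sqrt(mean(|x[mask]|^2))`. Used as the standard signal-amplitude
#' readout: `x` is typically either a trailing-window RMS field returned by
#' [evolve()] or a complex deviation field.
#'
#' @param x Real or complex field.
#' @param mask Logical array of the same shape (or missing for the whole
#'   field).
#' @return A nonnegative scalar.
#' @export
region_rms <- function(x, mask = NULL) {
  v <- if (is.null(mask)) x else x[mask]
  sqrt(mean(Mod(v)^2))
}
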