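# Independent oracles used across tests. These deliberately avoid the
# package's FFT path: convolution by direct sliding-window summation and
# region filling by iterated dilation.

# Periodic convolution by direct summation: out(x) = sum_o k(o) Z(x - o).
direct_conv <- function(kernel, Z) {
  if (is.matrix(Z)) {
    H <- nrow(Z); W <- ncol(Z)
    r <- (dim(kernel) - 1) / 2
    out <- matrix(0i, H, W)
    for (oi in -r[1]:r[1]) for (oj in -r[2]:r[2]) {
      kv <- kernel[oi + r[1] + 1, oj + r[2] + 1]
      if (kv == 0) next
      rows <- ((seq_len(H) - 1 - oi) %% H) + 1
      cols <- ((seq_len(W) - 1 - oj) %% W) + 1
      out <- out + kv * Z[rows, cols]
    }
    out
  } else {
    N <- length(Z)
    r <- (length(kernel) - 1) / 2
    out <- rep(0i, N)
    for (o in -r:r) {
      kv <- kernel[o + r + 1]
      if (kv == 0) next
      out <- out + kv * Z[((seq_len(N) - 1 - o) %% N) + 1]
    }
    out
  }
}

# Connected component by iterated 4-neighbor dilation masked to the go
# region (morphological flood fill), periodic wrap.
dilation_fill <- function(go, seed_site) {
  H <- nrow(go); W <- ncol(go)
  cur <- matrix(FALSE, H, W)
  cur[seed_site[1], seed_site[2]] <- TRUE
  repeat {
    g <- cur
    grown <- g |
      rbind(g[-1, , drop = FALSE], g[1, , drop = FALSE]) |
      rbind(g[H, , drop = FALSE], g[-H, , drop = FALSE]) |
      cbind(g[, -1, drop = FALSE], g[, 1, drop = FALSE]) |
      cbind(g[, W, drop = FALSE], g[, -W, drop = FALSE])
    grown <- grown & go
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

# One application of the dense map.
.phi_dense_step <- function(U, Z, I) phi(as.vector(U %*% Z) + I)

rcfield <- function(shape, seed = 1) {
  set.seed(seed)
  if (length(shape) == 2) {
    matrix(complex(real = rnorm(prod(shape)), imaginary = rnorm(prod(shape))),
           shape[1], shape[2])
  } else {
    complex(real = rnorm(shape), imaginary = rnorm(shape))
  }
}
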