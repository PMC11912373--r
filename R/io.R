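# File IO: attenuation maps as grayscale images, complex fields as RDS and
# plain-text CSV, field snapshots as color PNG of log|Z|, metrics as JSON.

#' Read an attenuation map from a grayscale image
#'
#' Reads a PNG (or TIFF, if the tiff package is installed) image and maps
#' gray levels linearly from `[0, 1]` to `[gamma_min, gamma_max]`. Color
#' images are converted to gray by channel averaging. This is the
#' "circuit drawing" input path: any grayscale picture becomes a wall
#' pattern.
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @param gamma_min,gamma_max Attenuation values assigned to black and
#'   white.
#' @return Numeric matrix of attenuation values.
#' @export
read_gamma_image <- function(path, gamma_min = 0.01, gamma_max = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package", call. = FALSE)
    tiff::readTIFF(path)
  } else stop(sprintf("unsupported image format '%s'", ext), call. = FALSE)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                              drop = FALSE], c(1, 2), mean)
  gamma_min + img * (gamma_max - gamma_min)
}

#' Write an attenuation map as a grayscale PNG
#'
#' Values are clipped to `[0, 1]` (valid for designable maps).
#'
#' @param Gamma Numeric matrix.
#' @param path Output path.
#' @export
write_gamma_image <- function(Gamma, path) {
  png::writePNG(pmin(pmax(Gamma, 0), 1), path)
  invisible(path)
}

#' Write a color-mapped PNG of log amplitude
#'
#' Renders `log10(|Z| + floor)` through a viridis palette; the standard way
#' to look at wave fields spanning several orders of magnitude.
#'
#' @param Z Complex field (matrix).
#' @param path Output path.
#' @param floor Additive floor inside the log (default `1e-12`).
#' @export
write_field_png <- function(Z, path, floor = 1e-12) {
  v <- log10(Mod(Z) + floor)
  rng <- range(v)
  u <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255
  idx <- pmin(pmax(1L + as.integer(u * 255), 1L), 256L)
  img <- array(0, c(nrow(Z), ncol(Z), 3))
  img[, , 1] <- pal[1, idx]
  img[, , 2] <- pal[2, idx]
  img[, , 3] <- pal[3, idx]
  png::writePNG(img, path)
  invisible(path)
}

#' Write a complex field as plain-text CSV
#'
#' Columns `row`, `col` (omitted in 1D), `re`, `im`.
#'
#' @param Z Complex field.
#' @param path Output path.
#' @export
write_field_csv <- function(Z, path) {
  df <- if (is.matrix(Z)) {
    data.frame(row = as.vector(row(Z)), col = as.vector(col(Z)),
               re = as.vector(Re(Z)), im = as.vector(Im(Z)))
  } else {
    data.frame(index = seq_along(Z), re = Re(Z), im = Im(Z))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a complex field from CSV written by [write_field_csv()]
#'
#' @param path CSV path.
#' @return Complex vector or matrix.
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  z <- complex(real = df$re, imaginary = df$im)
  if ("row" %in% names(df)) {
    H <- max(df$row); W <- max(df$col)
    M <- matrix(0i, H, W)
    M[cbind(df$row, df$col)] <- z
    M
  } else z
}

write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
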