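# Generators for the wave-gating input geometries (attenuation bands, boxes
# with walls, labyrinths from band-passed noise, rotating annuli) and region
# analysis utilities (flood fill, filled-region detection, frequency maps,
# synchrony diagnostics).
#
# Attenuation maps are plain numeric arrays; generators attach an integer
# "labels" attribute naming the regions they create.

#' Region labels of a generated attenuation map
#'
#' @param Gamma A map produced by one of the pattern generators.
#' @return Integer array of region codes (see the generator's documentation),
#'   or `NULL`.
#' @export
region_labels <- function(Gamma) attr(Gamma, "labels")

#' 1D two-box attenuation profile with a central band
#'
#' Background attenuation 1, absorbing flanks at both ends of the lattice
#' (preventing waves from wrapping around the periodic boundary), and a
#' central band of attenuation `exp(-0.01 * band_L)`. The flanks and the
#' band divide the lattice into a left and a right box; a signal injected in
#' the left box must traverse the band to reach the right box, attenuating
#' exponentially on the way, with the drop graded continuously by `band_L`.
#'
#' Region codes in the `"labels"` attribute: 1 left box, 2 right box,
#' 3 flank, 4 band.
#'
#' @param N Lattice length.
#' @param flank_value Attenuation of the flanks (default 0.5).
#' @param flank_width Width of each flank in sites.
#' @param band_range Integer range `c(first, last)` of the band; default a
#'   centered band of width `N %/% 8`.
#' @param band_L Band strength `L >= 0`; the band attenuation is
#'   `exp(-0.01 * L)` (so `L = 0` means no attenuation).
#' @return Numeric vector of length `N` with a `"labels"` attribute.
#' @export
make_band_1d <- function(N, flank_value = 0.5,
                         flank_width = max(8L, N %/% 16L),
                         band_range = NULL, band_L = 0) {
  N <- as.integer(N)
  if (is.null(band_range)) {
    w <- max(4L, N %/% 8L)
    band_range <- c(N %/% 2L - w %/% 2L + 1L, N %/% 2L + w %/% 2L)
  }
  band <- seq.int(band_range[1], band_range[2])
  if (band_range[1] < 1L || band_range[2] > N)
    stop("band lies outside the lattice", call. = FALSE)
  flank <- c(seq_len(flank_width), seq.int(N - flank_width + 1L, N))
  if (any(band %in% flank))
    stop("band overlaps the flanks: overlapping ranges", call. = FALSE)
  g <- rep(1, N)
  g[flank] <- flank_value
  g[band] <- exp(-0.01 * band_L)
  labels <- integer(N)
  labels[seq.int(flank_width + 1L, band_range[1] - 1L)] <- 1L
  labels[seq.int(band_range[2] + 1L, N - flank_width)] <- 2L
  labels[flank] <- 3L
  labels[band] <- 4L
  attr(g, "labels") <- labels
  g
}

#' 2D two-box attenuation map with an optional hole in the middle wall
#'
#' Two side-by-side boxes with interior attenuation 1, enclosed by strongly
#' attenuating walls (default 0.1) and separated by a middle wall; an
#' optional hole restores attenuation 1 on a span of rows of the middle
#' wall, letting waves leak from one box to the other. This is the
#' "geometric IF" configuration: whether a signal injected in the left box
#' reaches the right box is decided purely by the input pattern.
#'
#' Region codes: 1 left box, 2 right box, 3 hole, 0 wall.
#'
#' @param shape `c(H, W)` lattice shape.
#' @param wall_gamma Wall attenuation (default 0.1).
#' @param wall_thickness Wall thickness in sites.
#' @param hole Optional integer range `c(first_row, last_row)` of the hole
#'   in the middle wall; must lie strictly inside the box rows.
#' @return Numeric matrix with a `"labels"` attribute.
#' @export
make_boxes_2d <- function(shape, wall_gamma = 0.1, wall_thickness = 6L,
                          hole = NULL) {
  shape <- as.integer(shape)
  H <- shape[1]; W <- shape[2]
  t <- as.integer(wall_thickness)
  stopifnot(t >= 1L)
  g <- matrix(1, H, W)
  labels <- matrix(0L, H, W)
  border_r <- c(seq_len(t), seq.int(H - t + 1L, H))
  border_c <- c(seq_len(t), seq.int(W - t + 1L, W))
  g[border_r, ] <- wall_gamma
  g[, border_c] <- wall_gamma
  mid <- seq.int(W %/% 2L - t %/% 2L, W %/% 2L - t %/% 2L + t - 1L)
  g[, mid] <- wall_gamma
  left_c <- seq.int(t + 1L, mid[1] - 1L)
  right_c <- seq.int(mid[length(mid)] + 1L, W - t)
  inner_r <- seq.int(t + 1L, H - t)
  labels[inner_r, left_c] <- 1L
  labels[inner_r, right_c] <- 2L
  if (!is.null(hole)) {
    hole <- as.integer(hole)
    rows <- seq.int(hole[1], hole[2])
    if (hole[1] <= t || hole[2] > H - t)
      stop("hole outside the middle wall (must lie within the box rows)",
           call. = FALSE)
    g[rows, mid] <- 1
    labels[rows, mid] <- 3L
  }
  attr(g, "labels") <- labels
  g
}

#' Labyrinthine go/no-go pattern from thresholded band-passed noise
#'
#' Seeded Gaussian white noise is filtered through an annular Fourier
#' band-pass (raised-cosine edges in radial wavenumber) and thresholded at a
#' quantile; sites above the threshold form the "go" region where waves may
#' propagate. The band limits control the corridor width of the labyrinth.
#'
#' @param shape `c(H, W)` lattice shape.
#' @param band_low,band_high Radial wavenumber band (cycles per lattice,
#'   scaled to the smaller axis for non-square lattices); defaults give
#'   corridor widths of several kernel radii.
#' @param threshold_quantile Quantile of the filtered field used as the
#'   go/no-go threshold (0.5 = median split).
#' @param min_wall Radius (sites) of the morphological closing applied to
#'   the go region after thresholding. Closing removes hairline walls
#'   (thinner than about `2 * min_wall`), so the remaining walls are thick
#'   enough to actually block waves -- at full scale band-passed noise gives
#'   walls many sites thick automatically; at desk scale the raw threshold
#'   occasionally leaves 1--2-site walls that waves tunnel through. Set to 0
#'   to disable.
#' @param seed Integer seed; the pattern is deterministic per seed.
#' @return Logical matrix (`TRUE` = go).
#' @export
make_labyrinth <- function(shape, band_low = NULL, band_high = NULL,
                           threshold_quantile = 0.5, min_wall = 4L,
                           seed = 0L) {
  shape <- as.integer(shape)
  H <- shape[1]; W <- shape[2]
  m <- min(shape)
  if (is.null(band_low)) band_low <- max(2, round(0.015 * m))
  if (is.null(band_high)) band_high <- max(band_low + 2, round(0.03 * m))
  if (!(band_low > 0 && band_low < band_high && band_high < m / 2))
    stop("need 0 < band_low < band_high < Nyquist", call. = FALSE)
  noise <- with_seed(seed, matrix(stats::rnorm(H * W), H, W))
  kr <- pmin(0:(H - 1), H:1 %% H) * (m / H)
  kc <- pmin(0:(W - 1), W:1 %% W) * (m / W)
  r <- sqrt(outer(kr^2, kc^2, "+"))
  tw <- max(1, 0.2 * (band_high - band_low))
  ramp_up <- pmin(pmax((r - (band_low - tw)) / tw, 0), 1)
  ramp_dn <- pmin(pmax(((band_high + tw) - r) / tw, 0), 1)
  w <- (1 - cos(pi * ramp_up)) / 2 * (1 - cos(pi * ramp_dn)) / 2
  filtered <- Re(fft_inv(fft_fwd(noise) * w))
  go <- filtered > stats::quantile(filtered, threshold_quantile)
  if (min_wall > 0) go <- erode4(dilate4(go, min_wall), min_wall)
  if (!any(go)) stop("empty go region", call. = FALSE)
  go
}

# Periodic dilation / erosion with a square (Chebyshev-ball) structuring
# element, separable into row and column passes; the square element leaves
# no diagonal thin spots.
dilate4 <- function(mask, radius = 1L) {
  H <- nrow(mask); W <- ncol(mask)
  for (k in seq_len(radius)) {
    g <- mask
    mask <- g |
      rbind(g[-1, , drop = FALSE], g[1, , drop = FALSE]) |
      rbind(g[H, , drop = FALSE], g[-H, , drop = FALSE])
  }
  for (k in seq_len(radius)) {
    g <- mask
    mask <- g |
      cbind(g[, -1, drop = FALSE], g[, 1, drop = FALSE]) |
      cbind(g[, W, drop = FALSE], g[, -W, drop = FALSE])
  }
  mask
}

erode4 <- function(mask, radius = 1L) !dilate4(!mask, radius)

#' Map a go/no-go mask to an attenuation map
#'
#' @param mask Logical array (`TRUE` = go).
#' @param gamma_go Attenuation in the go region (default 1; supercritical
#'   values such as 1.2 are allowed here and routed to the modulated map).
#' @param gamma_nogo Attenuation in the no-go region (default 0.01).
#' @return Numeric array of the same shape.
#' @export
gamma_from_mask <- function(mask, gamma_go = 1, gamma_nogo = 0.01) {
  stopifnot(gamma_go > 0, gamma_nogo > 0)
  g <- array(gamma_nogo, dim = dim(as.array(mask)))
  g[mask] <- gamma_go
  if (!is.matrix(mask)) dim(g) <- NULL
  g
}

#' Annular wall with a missing quarter and an absorbing tapered border
#'
#' Builds the "lighthouse" attenuation map: an annular wall of strongly
#' attenuating sites with one quarter turn deleted at `rotation_angle`
#' (raised-cosine angular smoothing, half-amplitude exactly at the quarter
#' boundaries), plus an absorbing outer border whose attenuation tapers with
#' a raised cosine from 1 down to the wall value over `taper_width` sites --
#' so outgoing waves are absorbed rather than reflected or wrapped around
#' the periodic boundary. Waves emitted by a source at the center can only
#' escape through the gap; rotating the gap sweeps the emission direction.
#'
#' @param shape `c(H, W)` lattice shape.
#' @param radii `c(inner, outer)` annulus radii in sites.
#' @param rotation_angle Direction of the gap center (radians); the map is
#'   2*pi-periodic in this angle.
#' @param wall_gamma Attenuation of the annulus wall and of the outer border
#'   floor.
#' @param taper_width Width (sites) of the raised-cosine border taper.
#' @param radial_smooth Half-width (sites) of the raised-cosine smoothing of
#'   the annulus edges.
#' @param angular_taper Half-width (radians) of the angular smoothing at the
#'   gap edges.
#' @return Numeric matrix of attenuation values.
#' @export
make_annulus <- function(shape, radii, rotation_angle = 0,
                         wall_gamma = 0.1, taper_width = 8L,
                         radial_smooth = 2, angular_taper = pi / 16) {
  shape <- as.integer(shape)
  H <- shape[1]; W <- shape[2]
  stopifnot(length(radii) == 2, radii[1] > 0, radii[2] > radii[1])
  if (radii[2] + radial_smooth > min(shape) / 2 - taper_width)
    stop("annulus radii do not fit inside the lattice", call. = FALSE)
  cx <- (H + 1) / 2; cy <- (W + 1) / 2
  dx <- matrix(seq_len(H) - cx, H, W)
  dy <- matrix(seq_len(W) - cy, H, W, byrow = TRUE)
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  smooth01 <- function(u) (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2
  # radial wall profile: 1 inside [r_in, r_out], raised-cosine shoulders
  p_r <- smooth01((r - (radii[1] - radial_smooth)) / radial_smooth) *
    smooth01(((radii[2] + radial_smooth) - r) / radial_smooth)
  # angular gap: quarter turn centered on rotation_angle, half-amplitude at
  # the quarter boundaries
  dtheta <- abs(((theta - rotation_angle + pi) %% (2 * pi)) - pi)
  p_a <- smooth01((dtheta - (pi / 4 - angular_taper)) / (2 * angular_taper))
  wall <- p_r * p_a
  g <- 1 - (1 - wall_gamma) * wall
  # absorbing border taper: exactly wall_gamma at the lattice edge, exactly
  # 1 at taper_width sites in
  d_edge <- pmin(matrix(pmin(seq_len(H) - 1L, H - seq_len(H)), H, W),
                 matrix(pmin(seq_len(W) - 1L, W - seq_len(W)), H, W,
                        byrow = TRUE))
  border <- wall_gamma + (1 - wall_gamma) *
    smooth01(pmin(d_edge, taper_width) / taper_width)
  pmin(g, border)
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    o <- expand.grid(dr = -1:1, dc = -1:1)
    as.matrix(o[!(o$dr == 0 & o$dc == 0), ])
  } else stop("connectivity must be 4 or 8", call. = FALSE)
}

#' Flood fill: connected component of a seed site
#'
#' Classical breadth-first flood fill on a logical go/no-go mask with
#' periodic wrap. This is the discrete connectedness oracle that the wave
#' dynamics implements physically: a wave injected at the seed fills exactly
#' the connected go component.
#'
#' @param go_mask Logical array (`TRUE` = go). 1D vectors and 2D matrices
#'   are supported.
#' @param seed_site Seed site inside the go region.
#' @param connectivity 4 (default, matching the propagation footprint of the
#'   five-point Laplacian kernel) or 8.
#' @param periodic Wrap neighbors around the lattice boundary.
#' @return Logical array: the connected component containing the seed.
#' @export
floodfill_oracle <- function(go_mask, seed_site, connectivity = 4,
                             periodic = TRUE) {
  if (is.matrix(go_mask)) {
    H <- nrow(go_mask); W <- ncol(go_mask)
    si <- site_index(c(H, W), seed_site)
    if (!go_mask[si]) stop("seed site is in the no-go region", call. = FALSE)
    offs <- neighbor_offsets(connectivity)
    visited <- matrix(FALSE, H, W)
    queue <- integer(H * W)
    queue[1] <- si
    visited[si] <- TRUE
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      r <- (cur - 1L) %% H + 1L
      c_ <- (cur - 1L) %/% H + 1L
      for (k in seq_len(nrow(offs))) {
        nr <- r + offs[k, 1]; nc <- c_ + offs[k, 2]
        if (periodic) {
          nr <- (nr - 1L) %% H + 1L; nc <- (nc - 1L) %% W + 1L
        } else if (nr < 1L || nr > H || nc < 1L || nc > W) next
        ni <- (nc - 1L) * H + nr
        if (go_mask[ni] && !visited[ni]) {
          visited[ni] <- TRUE
          tail <- tail + 1L
          queue[tail] <- ni
        }
      }
    }
    visited
  } else {
    N <- length(go_mask)
    si <- site_index(N, seed_site)
    if (!go_mask[si]) stop("seed site is in the no-go region", call. = FALSE)
    visited <- logical(N)
    queue <- integer(N)
    queue[1] <- si; visited[si] <- TRUE
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      for (d in c(-1L, 1L)) {
        ni <- cur + d
        if (periodic) ni <- (ni - 1L) %% N + 1L
        else if (ni < 1L || ni > N) next
        if (go_mask[ni] && !visited[ni]) {
          visited[ni] <- TRUE
          tail <- tail + 1L
          queue[tail] <- ni
        }
      }
    }
    visited
  }
}

#' Label all connected components of a go mask
#'
#' Repeated flood fill; component 0 is the no-go region.
#'
#' @inheritParams floodfill_oracle
#' @return Integer array of component labels (0 = no-go).
#' @export
label_components <- function(go_mask, connectivity = 4, periodic = TRUE) {
  labels <- array(0L, dim = dim(as.array(go_mask)))
  if (!is.matrix(go_mask)) dim(labels) <- NULL
  nxt <- 0L
  remaining <- go_mask
  while (any(remaining)) {
    nxt <- nxt + 1L
    si <- which(remaining)[1]
    seed <- if (is.matrix(go_mask))
      c((si - 1L) %% nrow(go_mask) + 1L, (si - 1L) %/% nrow(go_mask) + 1L)
    else si
    comp <- floodfill_oracle(remaining, seed, connectivity, periodic)
    labels[comp] <- nxt
    remaining[comp] <- FALSE
  }
  labels
}

#' Detect the region filled by wave activity
#'
#' Classifies as "filled" the sites whose steady amplitude exceeds
#' `threshold_rel` times the median amplitude over a reference component
#' (normally the flood-fill component of the injection site). Comparing the
#' detected region against the flood-fill oracle quantifies how faithfully
#' the wave dynamics computes connectedness.
#'
#' @param amplitude Real nonnegative field (e.g. the trailing-window RMS
#'   from [evolve()]).
#' @param seed_component Logical array: the reference (seed) component.
#' @param threshold_rel Relative threshold in `(0, 1)`. The default sits
#'   between the through-wall leakage level (below `1e-3` of the seed
#'   median for default wall geometry) and the faintest genuinely filled
#'   corridors at desk scale.
#' @return Logical array of detected sites.
#' @export
detect_filled_region <- function(amplitude, seed_component,
                                 threshold_rel = 3e-4) {
  stopifnot(threshold_rel > 0, threshold_rel < 1)
  if (all(amplitude == 0)) stop("amplitude field is identically zero",
                                call. = FALSE)
  stopifnot_same_shape(amplitude, seed_component, "amplitude", "component")
  ref <- stats::median(amplitude[seed_component])
  amplitude > threshold_rel * ref
}

#' Sites within a given Chebyshev distance of the no-go region
#'
#' Utility for excluding a wall-adjacent margin (of about one kernel radius)
#' when scoring region detection: waves penetrate walls over roughly one
#' attenuation length, so boundaries are graded, not hard.
#'
#' @param go_mask Logical matrix (`TRUE` = go).
#' @param radius Margin radius in sites.
#' @return Logical matrix: `TRUE` where a no-go site lies within `radius`.
#' @export
wall_margin <- function(go_mask, radius = 1L) {
  near <- !go_mask
  H <- nrow(go_mask); W <- ncol(go_mask)
  for (k in seq_len(radius)) {
    g <- near
    near <- g |
      rbind(g[-1, , drop = FALSE], g[1, , drop = FALSE]) |
      rbind(g[H, , drop = FALSE], g[-H, , drop = FALSE]) |
      cbind(g[, -1, drop = FALSE], g[, 1, drop = FALSE]) |
      cbind(g[, W, drop = FALSE], g[, -W, drop = FALSE])
  }
  near & go_mask
}

#' Per-site oscillation frequency from two snapshots
#'
#' Estimates each site's oscillation frequency (radians per step) as
#' `Arg(Z_a * Conj(Z_b)) / lag`, where `Z_a` is the later snapshot and `Z_b`
#' the snapshot `lag` steps earlier. Values are wrapped to
#' `(-pi/lag, pi/lag]`; sites where either amplitude vanishes are returned
#' as `NA` (undefined phase).
#'
#' @param Z_a,Z_b Complex snapshot fields, `Z_a` taken `lag` steps after
#'   `Z_b`.
#' @param lag Snapshot separation in steps (default 200).
#' @return Real array of per-step frequencies with `NA` at silent sites.
#' @export
frequency_map <- function(Z_a, Z_b, lag = 200) {
  stopifnot(lag >= 1)
  stopifnot_same_shape(Z_a, Z_b, "Z_a", "Z_b")
  w <- Arg(Z_a * Conj(Z_b)) / lag
  w[Mod(Z_a) == 0 | Mod(Z_b) == 0] <- NA_real_
  w
}

# Circular standard deviation of angles (radians): sqrt(-2 log |mean phasor|).
circ_sd <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0) return(NA_real_)
  rbar <- Mod(mean(exp(1i * angles)))
  rbar <- min(rbar, 1)
  if (rbar == 0) return(Inf)
  sqrt(-2 * log(rbar))
}

#' Synchrony of oscillation frequencies within connected domains
#'
#' For each connected go domain of at least `min_size` sites, computes the
#' circular standard deviation of the per-site frequencies (from
#' [frequency_map()]) within the domain, and compares it with the
#' across-domain spread of the domain mean frequencies. A domain counts as
#' synchronized when its internal spread is below `sync_factor` times the
#' across-domain spread. All circular statistics are taken on the phase
#' angles `frequency * lag` and converted back to per-step units.
#'
#' @param freq Frequency map (per-step radians; `NA` allowed).
#' @param domain_labels Integer array of domain labels from
#'   [label_components()] (0 = no-go, excluded).
#' @param lag Snapshot separation used to build `freq`.
#' @param min_size Minimum domain size in sites.
#' @param sync_factor Synchrony criterion factor (default 0.1).
#' @return A list with `domains` (data frame: `id`, `size`, `mean_freq`,
#'   `circ_sd`), `across_spread`, and `frac_synchronized`.
#' @export
synchrony_summary <- function(freq, domain_labels, lag = 200,
                              min_size = 50, sync_factor = 0.1) {
  ids <- setdiff(sort(unique(as.vector(domain_labels))), 0L)
  rows <- lapply(ids, function(id) {
    sel <- domain_labels == id
    if (sum(sel) < min_size) return(NULL)
    ang <- freq[sel] * lag
    data.frame(id = id, size = sum(sel),
               mean_freq = Arg(mean(exp(1i * ang[!is.na(ang)]))) / lag,
               circ_sd = circ_sd(ang) / lag)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 2)
    stop("need at least two domains of the requested minimum size",
         call. = FALSE)
  across <- circ_sd(rows$mean_freq * lag) / lag
  list(domains = rows, across_spread = across,
       frac_synchronized = mean(rows$circ_sd < sync_factor * across))
}
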