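#' Estimate the per-channel background level
#'
#' Background is estimated from down-sampled data in two steps: pixels at or
#' below `noise_floor + k_sigma * sigma` (detector offset plus four standard
#' deviations of read noise, by default) are discarded as "black", and the
#' background `b` is the `percentile`-th percentile of the surviving pixels.
#' This captures tissue autofluorescence plus nonspecific staining, which is
#' then subtracted uniformly from the channel. If nothing survives the
#' threshold, `b = 0` with a warning (densely stained tissue may need a
#' different percentile).
#'
#' @param x numeric vector/matrix/array of intensities (typically the 16x
#'   down-sampled channel volume).
#' @param noise_floor detector offset, in intensity counts.
#' @param sigma detector read-noise standard deviation, in counts.
#' @param k_sigma threshold multiplier (default 4).
#' @param percentile background percentile of the surviving pixels
#'   (default 20).
#' @return A `background_model`: list with `b`, `threshold`, the parameters,
#'   and the survivor count.
#' @export
compute_background <- function(x, noise_floor, sigma, k_sigma = 4, percentile = 20) {
  if (length(x) == 0) stop("empty input")
  if (percentile < 0 || percentile > 100) stop("percentile must be in [0, 100]")
  if (k_sigma < 0 || sigma < 0) stop("sigma and k_sigma must be >= 0")
  threshold <- noise_floor + k_sigma * sigma
  surv <- x[x > threshold]
  if (length(surv) == 0) {
    warning("no pixels above the detector threshold (", format(threshold),
            "); background set to 0")
    b <- 0
  } else {
    b <- unname(stats::quantile(surv, percentile / 100, names = FALSE))
  }
  structure(list(b = b, threshold = threshold, noise_floor = noise_floor,
                 sigma = sigma, k_sigma = k_sigma, percentile = percentile,
                 n_survivors = length(surv)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> b = %s (threshold %s, %d survivors, p%g)\n",
              format(x$b), format(x$threshold), x$n_survivors, x$percentile))
  invisible(x)
}

#' Estimate detector noise parameters from data
#'
#' Fallback for when camera metadata are unavailable: the noise floor is the
#' modal intensity of the data (detector-offset pixels cluster tightly at
#' the floor while signal spreads over a wide range), and sigma comes from
#' the half-normal spread of the pixels below the mode, which signal cannot
#' contaminate. Biased when the data contain almost no background pixels,
#' e.g. on heavily down-sampled volumes of densely stained tissue - prefer
#' real camera metadata when available.
#'
#' @param x numeric intensities.
#' @return list with `noise_floor` and `sigma`.
#' @export
estimate_noise <- function(x) {
  tab <- table(round(x))
  floor_ <- as.numeric(names(tab)[which.max(tab)])
  below <- x[x <= floor_]
  list(noise_floor = floor_,
       sigma = sqrt(mean((below - floor_)^2)))
}

#' Subtract a uniform background level
#'
#' Clamps at zero (intensities are unsigned).
#'
#' @param x numeric intensities (any shape).
#' @param b background level, `>= 0`.
#' @return `pmax(x - b, 0)`, shape preserved.
#' @export
subtract_background <- function(x, b) {
  if (inherits(b, "background_model")) b <- b$b
  if (b < 0) stop("b must be >= 0")
  if (b == 0) return(x)
  out <- pmax(x - b, 0)
  dim(out) <- dim(x)
  out
}

#' Build the 3D intensity-leveling map
#'
#' Partitions the (background-subtracted) down-sampled volume into data cubes
#' (default 256 full-resolution voxels per edge, i.e. 16 voxels at the 16x
#' level, about 100 um of tissue) and assigns each cube one level `M`:
#' \itemize{
#'   \item if the cube's median exceeds `b`, `M` is the median of the cube's
#'     pixels strictly above `b` (the local stain level);
#'   \item otherwise (a no-signal cube, median `<= b`) `M` falls back to the
#'     constant `A`, by default the 95th percentile of the whole channel
#'     volume, so empty regions level to small values and render near white.
#' }
#' Every grid entry is strictly positive (`A` is floored at 1 count on
#' signal-free volumes). Cubes partially overhanging the volume edge use the
#' pixels they contain; a cube edge exceeding the volume collapses to a
#' single cube along that axis with a warning.
#'
#' @param lowres background-subtracted down-sampled channel volume, 3D array
#'   `(y, x, z)`.
#' @param background a [compute_background()] result, or a number `b`.
#' @param cube_shape cube edge length(s) in full-resolution voxels; scalar or
#'   `(y, x, z)` triple. Default 256.
#' @param level down-sampling factor of `lowres` relative to full resolution.
#' @param alpha per-channel leveling constant applied when maps are
#'   interpolated (1.5 nuclear / 3.7 eosin for the reference calibration);
#'   lower alpha renders the stain darker.
#' @param A_percentile percentile of `lowres` defining the fallback `A`.
#' @param full_shape full-resolution shape `(y, x, z)`; defaults to
#'   `dim(lowres) * level`.
#' @param channel_id optional label carried along.
#' @return A `leveling_map`.
#' @export
build_leveling_map <- function(lowres, background, cube_shape = 256, level = 16,
                               alpha = 1, A_percentile = 95, full_shape = NULL,
                               channel_id = NULL) {
  b <- if (inherits(background, "background_model")) background$b else background
  d <- dim(lowres)
  if (length(d) != 3L) stop("lowres must be a 3D array (y, x, z)")
  if (alpha <= 0) stop("alpha must be positive")
  if (length(cube_shape) == 1L) cube_shape <- rep(cube_shape, 3L)
  cube_lr <- pmax(1L, as.integer(round(cube_shape / level)))
  if (any(cube_lr > d)) {
    warning("cube larger than volume along axis ",
            paste(which(cube_lr > d), collapse = ","),
            "; using a single cube there")
    cube_lr <- pmin(cube_lr, d)
  }
  A <- max(stats::quantile(lowres, A_percentile / 100, names = FALSE), 1)
  g <- ceiling(d / cube_lr)
  grid <- array(NA_real_, g)
  for (iz in seq_len(g[3])) for (ix in seq_len(g[2])) for (iy in seq_len(g[1])) {
    ys <- ((iy - 1) * cube_lr[1] + 1):min(iy * cube_lr[1], d[1])
    xs <- ((ix - 1) * cube_lr[2] + 1):min(ix * cube_lr[2], d[2])
    zs <- ((iz - 1) * cube_lr[3] + 1):min(iz * cube_lr[3], d[3])
    vals <- lowres[ys, xs, zs]
    m <- stats::median(vals)
    grid[iy, ix, iz] <- if (m > b) stats::median(vals[vals > b]) else A
  }
  if (is.null(full_shape)) full_shape <- d * level
  structure(list(grid = grid, cube_full = cube_lr * level,
                 full_shape = full_shape, alpha = alpha, A = A, b = b,
                 level = level, channel_id = channel_id),
            class = "leveling_map")
}

#' @export
print.leveling_map <- function(x, ...) {
  g <- dim(x$grid)
  cat(sprintf("<leveling_map>%s grid %d x %d x %d (cube %s px), alpha = %g\n",
              if (is.null(x$channel_id)) "" else paste0(" '", x$channel_id, "'"),
              g[1], g[2], g[3], paste(x$cube_full, collapse = "x"), x$alpha))
  cat(sprintf("  levels M in [%s, %s]; fallback A = %s; b = %s\n",
              format(min(x$grid)), format(max(x$grid)), format(x$A), format(x$b)))
  invisible(x)
}

#' Interpolate the full-resolution 2D leveling map for one depth
#'
#' Grid samples are anchored at cube centers. Interpolation is separable:
#' bilinear in `(y, x)` between cube centers, linear in z between the two
#' bracketing cube layers, with constant (nearest-center) extrapolation
#' beyond the outermost centers. The result is multiplied by the channel's
#' `alpha`. Linear interpolation smooths the steps between adjacent cubes so
#' the divided image shows no grid artifacts; the map is strictly positive
#' everywhere by construction.
#'
#' @param map a [build_leveling_map()] result.
#' @param z full-resolution plane index (1-based).
#' @param alpha override of the map's leveling constant.
#' @return Numeric matrix `(y, x)` of `alpha * M` at full resolution.
#' @export
interpolate_plane_map <- function(map, z, alpha = map$alpha) {
  fs <- map$full_shape
  if (z < 1 || z > fs[3]) stop("z out of range [1, ", fs[3], "]")
  g <- dim(map$grid)
  cz <- .cube_centers(fs[3], map$cube_full[3])
  Gz <- if (g[3] == 1L) {
    map$grid[, , 1, drop = TRUE]
  } else {
    j <- findInterval(z, cz)
    if (j < 1L) map$grid[, , 1, drop = TRUE]
    else if (j >= g[3]) map$grid[, , g[3], drop = TRUE]
    else {
      t <- (z - cz[j]) / (cz[j + 1] - cz[j])
      (1 - t) * map$grid[, , j, drop = TRUE] + t * map$grid[, , j + 1, drop = TRUE]
    }
  }
  Gz <- matrix(Gz, g[1], g[2])
  Wy <- .lin_weights(fs[1], .cube_centers(fs[1], map$cube_full[1]))
  Wx <- .lin_weights(fs[2], .cube_centers(fs[2], map$cube_full[2]))
  alpha * (Wy %*% Gz %*% t(Wx))
}

#' Divide a plane by its leveling map
#'
#' The leveled image `I_f = I / (alpha M)` has approximately equal local
#' medians everywhere, flattening coarse staining and illumination
#' non-uniformities while leaving fine structure intact.
#'
#' @param plane background-subtracted full-resolution plane `(y, x)`.
#' @param plane_map strictly positive map `alpha * M` of the same shape,
#'   from [interpolate_plane_map()].
#' @param z,channel_id optional metadata carried into the result.
#' @return A `leveled_plane`: list with `values` (unitless, finite, `>= 0`),
#'   `z` and `channel_id`.
#' @export
level_plane <- function(plane, plane_map, z = NA_integer_, channel_id = NULL) {
  if (!identical(dim(plane), dim(plane_map)))
    stop("plane and map shapes differ")
  if (min(plane_map) <= 0)
    stop("internal invariant violated: leveling map must be strictly positive")
  structure(list(values = plane / plane_map, z = z, channel_id = channel_id),
            class = "leveled_plane")
}

#' @export
print.leveled_plane <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<leveled_plane>%s %d x %d, range [%s, %s]\n",
              if (is.null(x$channel_id)) "" else paste0(" '", x$channel_id, "'"),
              d[1], d[2], format(min(x$values)), format(max(x$values))))
  invisible(x)
}

#' Optional CLAHE pre-processing
#'
#' Contrast-limited adaptive histogram equalization for specimens whose
#' intensity varies too steeply for leveling alone (e.g. poorly penetrating
#' labels). Off by default in the standard workflow; use judiciously, as it
#' amplifies noise.
#'
#' @param plane numeric matrix.
#' @param clip_limit CLAHE clip limit (> 0).
#' @param tiles number of tiles `(ny, nx)` of the adaptive grid.
#' @return Equalized plane on the input intensity scale.
#' @export
clahe_preprocess <- function(plane, clip_limit = 2, tiles = c(8, 8)) {
  if (length(plane) == 0) stop("empty plane")
  if (clip_limit <= 0) stop("clip_limit must be positive")
  rng <- range(plane)
  if (rng[1] == rng[2]) return(plane)  # nothing to equalize
  xn <- (plane - rng[1]) / (rng[2] - rng[1])
  y <- EBImage::clahe(EBImage::Image(xn), nx = tiles[2], ny = tiles[1],
                      limit = clip_limit, keep.range = TRUE)
  out <- as.numeric(EBImage::imageData(y)) * (rng[2] - rng[1]) + rng[1]
  dim(out) <- dim(plane)
  out
}

#' Optional unsharp-mask sharpening
#'
#' `plane + amount * (plane - blur(plane, radius))`, clamped at zero.
#'
#' @param plane numeric matrix.
#' @param amount sharpening strength (`>= 0`; 0 is the identity).
#' @param radius Gaussian blur sigma, in pixels.
#' @return Sharpened plane.
#' @export
sharpen_plane <- function(plane, amount = 1, radius = 2) {
  if (amount < 0) stop("amount must be >= 0")
  if (amount == 0) return(plane)
  blur <- EBImage::imageData(EBImage::gblur(EBImage::Image(plane), sigma = radius))
  dim(blur) <- dim(plane)
  out <- pmax(plane + amount * (plane - blur), 0)
  dim(out) <- dim(plane)
  out
}
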