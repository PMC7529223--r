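#' Beer-Lambert digital staining of two leveled channels
#'
#' Converts a pair of leveled fluorescence planes into an 8-bit RGB image via
#' the Beer-Lambert absorption model. For each pixel and color
#' `n in {R, G, B}`:
#' \deqn{out_n = round(255 \exp(-j_n h) \exp(-k_n e))}
#' where `h` and `e` are the leveled intensities of the nuclear
#' (hematoxylin-analog) and eosin channels, and `j`, `k` come from the
#' palette. Zero signal renders pure white; the output is monotone
#' non-increasing in both inputs, and color mixing is multiplicative
#' (physically plausible spectral mixing of absorbing dyes), never additive.
#'
#' Leveled intensities are clipped to `ceiling` before exponentiation; pixels
#' at or beyond the ceiling are black to within one count anyway, and the
#' clip avoids denormal underflow. Rounding to 8 bits is half-away-from-zero
#' and isolated here so the choice is made in exactly one place.
#'
#' `engine = "fast"` runs a compiled per-pixel loop; `engine = "reference"`
#' runs plain vectorized R. The two are bit-identical by contract (the
#' compiled kernel mirrors the reference arithmetic exactly); the reference
#' path is the readable specification of the model.
#'
#' @param h,e numeric matrices of equal shape: leveled intensities (unitless,
#'   >= 0, finite) of channel 1 and channel 2.
#' @param palette a [chromogen_palette()], or a name accepted by
#'   [get_palette()]. Default `"HE"`.
#' @param ceiling clip level for leveled intensities before exponentiation.
#' @param engine `"fast"` (compiled) or `"reference"` (vectorized R).
#' @param z optional plane index carried into the result.
#' @return A `rendered_plane`: integer array `dim = c(nrow, ncol, 3)`, values
#'   in 0..255, with attributes `palette` and `z`.
#' @examples
#' h <- matrix(c(0, 1), 1, 2)
#' beer_lambert_render(h, h * 0)[1, , ]
#' @export
beer_lambert_render <- function(h, e, palette = "HE", ceiling = 50,
                                engine = c("fast", "reference"), z = NA_integer_) {
  engine <- match.arg(engine)
  palette <- get_palette(palette)
  if (!is.numeric(h) || !is.numeric(e)) stop("h and e must be numeric")
  if (!identical(dim(h), dim(e))) stop("h and e must have identical shapes")
  if (anyNA(h) || anyNA(e)) stop("NaN/NA in leveled input")
  if (ceiling <= 0) stop("ceiling must be positive")
  dm <- dim(h)
  if (is.null(dm)) dm <- c(1L, length(h))
  out <- if (engine == "fast") {
    .bl_render_cpp(as.numeric(h), as.numeric(e), palette$j, palette$k, ceiling)
  } else {
    .bl_render_r(as.numeric(h), as.numeric(e), palette$j, palette$k, ceiling)
  }
  dim(out) <- c(dm, 3L)
  structure(out, class = "rendered_plane", palette = palette$name, z = z)
}

# Reference arithmetic for the Beer-Lambert kernel. Mirrored in
# src/render_fast.cpp; any change here must be made there too.
.bl_render_r <- function(h, e, j, k, ceiling) {
  h <- pmin(h, ceiling)
  e <- pmin(e, ceiling)
  out <- integer(length(h) * 3L)
  for (c in 1:3) {
    v <- 255 * exp(-j[c] * h) * exp(-k[c] * e)
    v <- floor(v + 0.5)                     # round half away from zero
    out[seq_along(h) + (c - 1L) * length(h)] <- as.integer(pmin(pmax(v, 0), 255))
  }
  out
}

#' @rdname beer_lambert_render
#' @param ... passed on to [beer_lambert_render()].
#' @export
render_fast <- function(h, e, ...) beer_lambert_render(h, e, ..., engine = "fast")

#' @rdname beer_lambert_render
#' @export
render_reference <- function(h, e, ...) beer_lambert_render(h, e, ..., engine = "reference")

#' @export
print.rendered_plane <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rendered_plane> %d x %d, palette %s, z = %s\n",
              d[1], d[2], attr(x, "palette"), format(attr(x, "z"))))
  invisible(x)
}

#' Full per-plane rendering pipeline
#'
#' Composes the plane-level stages in workflow order: background subtraction,
#' optional sharpening and CLAHE, division by the interpolated leveling map,
#' then Beer-Lambert rendering. This is the single-plane unit that
#' [run_pipeline()] applies across a volume.
#'
#' @param raw_h,raw_e raw full-resolution planes (matrices) of the nuclear
#'   and eosin channels.
#' @param map_h,map_e strictly positive leveling-map planes (already scaled
#'   by alpha), same shape as the raw planes. See [interpolate_plane_map()].
#' @param b_h,b_e per-channel background levels (intensity counts).
#' @param sharpen `NULL`, or `list(amount=, radius=)` for unsharp masking.
#' @param clahe `NULL`, or `list(clip_limit=, tiles=)` for contrast-limited
#'   adaptive histogram equalization (off by default; see
#'   [clahe_preprocess()]).
#' @inheritParams beer_lambert_render
#' @return A `rendered_plane`.
#' @export
render_plane_pipeline <- function(raw_h, raw_e, map_h, map_e, b_h, b_e,
                                  palette = "HE", sharpen = NULL, clahe = NULL,
                                  ceiling = 50, engine = "fast", z = NA_integer_) {
  stage <- function(raw, map, b) {
    x <- subtract_background(raw, b)
    if (!is.null(sharpen))
      x <- sharpen_plane(x, amount = sharpen$amount, radius = sharpen$radius)
    if (!is.null(clahe))
      x <- clahe_preprocess(x, clip_limit = clahe$clip_limit, tiles = clahe$tiles)
    level_plane(x, map)
  }
  h <- stage(raw_h, map_h, b_h)
  e <- stage(raw_e, map_e, b_e)
  beer_lambert_render(h$values, e$values, palette = palette, ceiling = ceiling,
                      engine = engine, z = z)
}
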