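#' Chromogen palettes for Beer-Lambert rendering
#'
#' A chromogen palette holds the per-color absorption weights used by the
#' Beer-Lambert digital-staining model: `j` weights the first (nuclear /
#' hematoxylin-analog) channel and `k` the second (eosin) channel, each a
#' length-3 vector ordered (R, G, B). Larger weights absorb more of that
#' color, so e.g. hematoxylin's strong G absorption yields purple nuclei.
#'
#' The `"HE"` palette ships the reference virtual-H&E constants
#' `j = (0.17, 0.27, 0.105)`, `k = (0.05, 1.00, 0.54)` calibrated against
#' standard H&E whole-slide imagery. The `"DAB"` palette mimics
#' DAB (brown) chromogen plus a hematoxylin counterstain; DAB absorption
#' constants are calibration defaults of this package (chosen to give the
#' characteristic brown/blue IHC look), not published reference values.
#'
#' @param name palette label.
#' @param j numeric length-3, absorption weights of channel 1 (R, G, B).
#' @param k numeric length-3, absorption weights of channel 2 (R, G, B).
#' @return An object of class `chromogen_palette`.
#' @examples
#' he <- palette_he()
#' he$j
#' @export
chromogen_palette <- function(name, j, k) {
  j <- as.numeric(j); k <- as.numeric(k)
  if (length(j) != 3L || length(k) != 3L)
    stop("palette vectors must have length 3 (R, G, B)")
  if (any(!is.finite(j)) || any(!is.finite(k)) || any(j < 0) || any(k < 0))
    stop("palette weights must be finite and >= 0")
  if (all(j == 0) || all(k == 0))
    stop("each stain vector needs at least one positive component")
  structure(list(name = as.character(name)[1], j = j, k = k),
            class = "chromogen_palette")
}

#' @rdname chromogen_palette
#' @export
palette_he <- function() {
  chromogen_palette("HE", j = c(0.17, 0.27, 0.105), k = c(0.05, 1.00, 0.54))
}

#' @rdname chromogen_palette
#' @export
palette_dab <- function() {
  # DAB (brown) on channel 2, hematoxylin (blue) on channel 1.
  # Calibration defaults of this package; the brown vector absorbs B > G > R.
  chromogen_palette("DAB", j = c(0.30, 0.20, 0.08), k = c(0.26, 0.57, 0.85))
}

#' @param x palette name (`"HE"` or `"DAB"`) or a `chromogen_palette`.
#' @rdname chromogen_palette
#' @export
get_palette <- function(x) {
  if (inherits(x, "chromogen_palette")) return(x)
  switch(toupper(as.character(x)[1]),
         HE = palette_he(),
         DAB = palette_dab(),
         stop("unknown palette: ", x))
}

#' @export
print.chromogen_palette <- function(x, ...) {
  cat(sprintf("<chromogen_palette> %s\n", x$name))
  cat(sprintf("  j (channel 1, RGB): %s\n", paste(format(x$j), collapse = " ")))
  cat(sprintf("  k (channel 2, RGB): %s\n", paste(format(x$k), collapse = " ")))
  invisible(x)
}
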