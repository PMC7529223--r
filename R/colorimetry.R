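#' Optical-density stain bases
#'
#' Rows are unit optical-density (OD) absorption vectors per stain, columns
#' (R, G, B). `"HE"` uses the standard published hematoxylin and eosin
#' vectors; `"HDAB"` hematoxylin + DAB. A third, residual axis orthogonal to
#' the first two completes the basis at unmixing time.
#'
#' @param name `"HE"` or `"HDAB"`, or a 2x3 numeric matrix of OD vectors
#'   (rows = stains) which is normalized and passed through.
#' @return 2x3 matrix with unit rows, rownames = stain names.
#' @export
stain_od_matrix <- function(name = "HE") {
  if (is.matrix(name)) {
    M <- name
    if (!all(dim(M) == c(2, 3))) stop("stain basis must be 2 x 3")
    if (is.null(rownames(M))) rownames(M) <- c("stain1", "stain2")
  } else {
    M <- switch(toupper(name),
      HE = rbind(hematoxylin = c(0.65, 0.70, 0.29),
                 eosin       = c(0.07, 0.99, 0.11)),
      HDAB = rbind(hematoxylin = c(0.65, 0.70, 0.29),
                   dab         = c(0.27, 0.57, 0.78)),
      stop("unknown stain basis: ", name))
  }
  M / sqrt(rowSums(M^2))
}

#' Unmix an RGB image into per-stain concentration maps
#'
#' Converts the image to optical density, `OD = -log((rgb + 1) / 256)`, and
#' solves the per-pixel linear system against the stain basis (two stain
#' vectors plus their orthogonal residual). Negative concentrations are
#' clipped to zero and each stain's map is rescaled to `[0, 1]` by its
#' maximum, giving a probability-like map of where that stain dominates.
#'
#' @param rgb integer RGB array `(y, x, 3)`, values 0..255 (or a
#'   `rendered_plane`).
#' @param basis a [stain_od_matrix()] name or matrix.
#' @return A `stain_deconvolution`: list with `prob` (list of two `[0,1]`
#'   maps), `conc` (raw concentrations incl. residual), `basis`, `stains`.
#' @export
deconvolve_stains <- function(rgb, basis = "HE") {
  M2 <- stain_od_matrix(basis)
  resid <- c(M2[1, 2] * M2[2, 3] - M2[1, 3] * M2[2, 2],
             M2[1, 3] * M2[2, 1] - M2[1, 1] * M2[2, 3],
             M2[1, 1] * M2[2, 2] - M2[1, 2] * M2[2, 1])
  nr <- sqrt(sum(resid^2))
  if (nr < 1e-6) stop("degenerate (collinear) stain basis")
  M <- rbind(M2, residual = resid / nr)
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("rgb must be (y, x, 3)")
  v <- as.numeric(rgb)
  od <- -log((v + 1) / 256)
  dim(od) <- c(d[1] * d[2], 3L)
  conc <- od %*% solve(M)          # pixels x stains
  prob <- lapply(1:2, function(i) {
    p <- pmax(conc[, i], 0)
    mx <- max(p)
    if (mx > 0) p <- p / mx
    matrix(p, d[1], d[2])
  })
  names(prob) <- rownames(M2)
  structure(list(prob = prob, conc = conc, basis = M, stains = rownames(M2)),
            class = "stain_deconvolution")
}

#' Segment stain components from deconvolved probability maps
#'
#' Per stain: median filter, Otsu threshold on the filtered map, removal of
#' connected components below `area_min` pixels, then binary opening with a
#' disk of radius `opening_radius`. A constant map cannot be thresholded and
#' yields an empty mask with a warning. Pixels claimed by both stains after
#' independent thresholding are assigned to the stain with the higher
#' deconvolved concentration.
#'
#' @param decon a [deconvolve_stains()] result (or a list of two `[0,1]`
#'   probability maps).
#' @param median_size median filter window width (odd; default 3 for a
#'   3x3 window).
#' @param area_min minimum connected-component area, in pixels.
#' @param opening_radius disk radius of the binary opening.
#' @return A `stain_segmentation`: list with `masks` (list of two logical
#'   matrices), `prob`, and `params`.
#' @export
segment_structures <- function(decon, median_size = 3, area_min = 64,
                               opening_radius = 3) {
  maps <- if (inherits(decon, "stain_deconvolution")) decon$prob else decon
  if (length(maps) != 2L) stop("expected two probability maps")
  radius <- max(1L, as.integer((median_size - 1) / 2))
  brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, shape = "disc")
  masks <- lapply(maps, function(p) {
    if (min(p) < 0 || max(p) > 1) stop("probability maps must lie in [0, 1]")
    mf <- if (median_size <= 1) p
    else if (median_size == 3) .median3x3(p)
    else EBImage::imageData(EBImage::medianFilter(EBImage::Image(p), size = radius))
    if (diff(range(mf)) == 0) {
      warning("constant probability map; returning an empty mask")
      return(matrix(FALSE, nrow(p), ncol(p)))
    }
    thr <- EBImage::otsu(EBImage::Image(mf), range = c(0, 1))
    mask <- mf > thr
    lbl <- EBImage::bwlabel(EBImage::Image(mask))
    lbl <- EBImage::imageData(lbl)
    sizes <- tabulate(lbl[lbl > 0])
    keep <- which(sizes >= area_min)
    mask <- matrix(lbl %in% keep, nrow(p), ncol(p))
    opened <- EBImage::opening(EBImage::Image(mask), brush)
    matrix(EBImage::imageData(opened) > 0.5, nrow(p), ncol(p))
  })
  names(masks) <- names(maps)
  both <- masks[[1]] & masks[[2]]
  if (any(both)) {
    first_wins <- maps[[1]][both] >= maps[[2]][both]
    masks[[1]][both] <- first_wins
    masks[[2]][both] <- !first_wins
  }
  structure(list(masks = masks, prob = maps,
                 params = list(median_size = median_size, area_min = area_min,
                               opening_radius = opening_radius)),
            class = "stain_segmentation")
}

#' Median HSV color properties of segmented stains
#'
#' Converts the image to HSV (each component normalized to `[0, 1]`) and
#' reports, per stain, the median hue, saturation and value over the masked
#' pixels. Pure-black pixels (all channels zero, e.g. areas blanked by
#' masking) are ignored. An empty mask yields `NA` statistics, not zeros.
#' Hue medians are taken on raw `[0, 1]` values: both H&E hue clusters sit
#' far from the 0/1 wrap point, so no circular statistics are needed
#' (a documented limitation for palettes near red).
#'
#' @param rgb integer RGB array `(y, x, 3)`, 0..255.
#' @param segmentation a [segment_structures()] result (or a named list of
#'   logical masks).
#' @return A `color_report`: data.frame with columns `stain`, `hue`,
#'   `saturation`, `value`, `n`.
#' @export
measure_hsv <- function(rgb, segmentation) {
  masks <- if (inherits(segmentation, "stain_segmentation")) segmentation$masks
           else segmentation
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("rgb must be (y, x, 3)")
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  rows <- lapply(names(masks), function(nm) {
    sel <- masks[[nm]] & !(r == 0 & g == 0 & b == 0)
    if (!any(sel))
      return(data.frame(stain = nm, hue = NA_real_, saturation = NA_real_,
                        value = NA_real_, n = 0L))
    hsv <- grDevices::rgb2hsv(r[sel], g[sel], b[sel], maxColorValue = 255)
    data.frame(stain = nm,
               hue = stats::median(hsv[1, ]),
               saturation = stats::median(hsv[2, ]),
               value = stats::median(hsv[3, ]),
               n = sum(sel))
  })
  structure(do.call(rbind, rows), class = c("color_report", "data.frame"))
}

#' @export
print.color_report <- function(x, ...) {
  cat("<color_report> median HSV per stain\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sample tissue-bearing regions of interest from a large RGB image
#'
#' Draws candidate ROI positions uniformly at random and keeps those whose
#' non-white (tissue) pixel fraction reaches `tissue_min`, emulating the
#' selection of equally sized fields of view from a whole-slide image.
#' Deterministic for a fixed `seed`. If fewer than `n_rois` valid ROIs are
#' found the available ones are returned with a warning.
#'
#' @param rgb integer RGB array `(y, x, 3)`, 0..255.
#' @param n_rois number of ROIs requested.
#' @param roi_shape `(height, width)` of each ROI in pixels.
#' @param tissue_min minimum fraction of tissue pixels per ROI.
#' @param white_level mean-RGB level at or above which a pixel counts as
#'   background white.
#' @param seed RNG seed (restores the caller's RNG state).
#' @param max_tries candidate draws before giving up.
#' @return List of ROI arrays, with attribute `origins` (matrix of 1-based
#'   top-left corners).
#' @export
sample_rois <- function(rgb, n_rois = 10, roi_shape = c(128, 128),
                        tissue_min = 0.2, white_level = 235, seed = NULL,
                        max_tries = 2000) {
  d <- dim(rgb)
  if (d[1] < roi_shape[1] || d[2] < roi_shape[2])
    stop("image smaller than roi_shape")
  tissue <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3 < white_level
  rois <- list(); origins <- NULL
  .with_seed(seed, {
    tries <- 0L
    while (length(rois) < n_rois && tries < max_tries) {
      tries <- tries + 1L
      y0 <- sample.int(d[1] - roi_shape[1] + 1L, 1L)
      x0 <- sample.int(d[2] - roi_shape[2] + 1L, 1L)
      frac <- mean(tissue[y0:(y0 + roi_shape[1] - 1L), x0:(x0 + roi_shape[2] - 1L)])
      if (frac >= tissue_min) {
        rois[[length(rois) + 1L]] <-
          rgb[y0:(y0 + roi_shape[1] - 1L), x0:(x0 + roi_shape[2] - 1L), , drop = FALSE]
        origins <- rbind(origins, c(y = y0, x = x0))
      }
    }
  })
  if (length(rois) < n_rois)
    warning("found only ", length(rois), " of ", n_rois, " requested ROIs")
  attr(rois, "origins") <- origins
  rois
}

#' Summarize color reports across ROIs or planes
#'
#' Aggregates per-ROI median HSV reports into the distribution summary used
#' for inter-specimen consistency analysis: per stain and per HSV component,
#' the median, standard deviation, and 10th/90th percentiles across reports.
#'
#' @param reports list of [measure_hsv()] results (at least 2).
#' @return A `consistency_report`: data.frame with columns `stain`,
#'   `component`, `median`, `std`, `p10`, `p90`, `n`.
#' @export
consistency_report <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 reports")
  all <- do.call(rbind, lapply(reports, as.data.frame))
  comps <- c("hue", "saturation", "value")
  rows <- list()
  for (st in unique(all$stain)) for (cc in comps) {
    v <- all[all$stain == st, cc]
    v <- v[!is.na(v)]
    rows[[length(rows) + 1L]] <- data.frame(
      stain = st, component = cc,
      median = stats::median(v), std = stats::sd(v),
      p10 = stats::quantile(v, 0.10, names = FALSE),
      p90 = stats::quantile(v, 0.90, names = FALSE),
      n = length(v))
  }
  structure(do.call(rbind, rows), class = c("consistency_report", "data.frame"))
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("<consistency_report> distribution of median color properties\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
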