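#' Locate a two-channel multi-resolution volume on disk
#'
#' A locator names the container file and the dataset-path scheme inside it,
#' without reading any data. The default layout mirrors the BigStitcher-style
#' HDF5 scheme `t00000/s{channel}/{level}/cells`, where `{channel}` comes
#' from the `channels` map and `{level}` is the pyramid-level key of the
#' `levels` map (level key -> down-sampling factor). TIFF input (a directory
#' of per-plane files, or one multi-page file) carries full resolution only;
#' coarser levels are synthesized on the fly by block-mean pooling.
#'
#' @param path HDF5 file, multi-page TIFF file, or directory of TIFF planes.
#' @param format `"auto"` (from the file extension), `"hdf5"`, or `"tiff"`.
#' @param dataset_template dataset path template with `{channel}` and
#'   `{level}` placeholders (HDF5 only).
#' @param channels named character vector mapping channel labels to the
#'   `{channel}` substitution, e.g. `c(nuclear = "00", eosin = "01")`.
#' @param levels named numeric vector mapping `{level}` keys to
#'   down-sampling factors, e.g. `c("0" = 1, "1" = 16)`.
#' @return A `volume_locator`.
#' @export
volume_locator <- function(path,
                           format = c("auto", "hdf5", "tiff"),
                           dataset_template = "t00000/s{channel}/{level}/cells",
                           channels = c(nuclear = "00", eosin = "01"),
                           levels = c("0" = 1, "1" = 16)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "tiff"
              else if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
              else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) "tiff"
              else stop("cannot infer container format from path: ", path)
  }
  structure(list(path = path, format = format,
                 dataset_template = dataset_template,
                 channels = channels, levels = levels),
            class = "volume_locator")
}

.resolve_dataset <- function(locator, channel, level_key) {
  ds <- locator$dataset_template
  ds <- gsub("{channel}", locator$channels[[channel]], ds, fixed = TRUE)
  gsub("{level}", level_key, ds, fixed = TRUE)
}

#' Open one channel of a fluorescence volume
#'
#' Resolves a [volume_locator()] into a `fluor_volume` handle with lazily
#' readable planes; the full-resolution volume is never loaded whole. Reported
#' shapes follow the `(z, y, x)` axis convention; planes are `(y, x)`
#' matrices; all z indices in this package are 1-based.
#'
#' @param locator a [volume_locator()].
#' @param channel channel label, one of `names(locator$channels)`.
#' @param voxel_pitch named numeric `(z, y, x)`, micrometres per voxel at
#'   full resolution; must be strictly positive.
#' @return A `fluor_volume`.
#' @export
open_volume <- function(locator, channel, voxel_pitch = c(z = 1, y = 1, x = 1)) {
  if (!inherits(locator, "volume_locator")) stop("not a volume_locator")
  if (!channel %in% names(locator$channels))
    stop("unknown channel '", channel, "'; locator has: ",
         paste(names(locator$channels), collapse = ", "))
  if (any(voxel_pitch <= 0)) stop("voxel_pitch must be strictly positive")
  if (locator$format == "hdf5") {
    if (!file.exists(locator$path)) stop("container not found: ", locator$path)
    keys <- names(locator$levels)
    paths <- vapply(keys, function(k) .resolve_dataset(locator, channel, k), "")
    fid <- rhdf5::H5Fopen(locator$path, flags = "H5F_ACC_RDONLY")
    on.exit(rhdf5::H5Fclose(fid))
    ok <- vapply(paths, function(p) rhdf5::H5Lexists(fid, p), logical(1))
    if (!any(ok))
      stop("no dataset matched the locator template; paths tried: ",
           paste(paths, collapse = ", "))
    dims <- lapply(paths[ok], function(p) {
      did <- rhdf5::H5Dopen(fid, p)
      on.exit(rhdf5::H5Dclose(did), add = TRUE)
      sid <- rhdf5::H5Dget_space(did)
      on.exit(rhdf5::H5Sclose(sid), add = TRUE)
      rhdf5::H5Sget_simple_extent_dims(sid)$size   # stored (y, x, z)
    })
    lv <- locator$levels[ok]
    if (!any(lv == 1)) stop("locator resolves no full-resolution (factor 1) level")
    full <- dims[[which(lv == 1)[1]]]
    vol <- list(backend = "hdf5", path = locator$path,
                datasets = stats::setNames(paths[ok], lv),
                dim_yxz = full, levels = sort(unname(lv)),
                channel_id = channel, voxel_pitch = voxel_pitch,
                dtype = "uint16")
  } else {
    files <- if (dir.exists(locator$path)) {
      sort(list.files(locator$path, pattern = "\\.(tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE))
    } else {
      if (!file.exists(locator$path)) stop("container not found: ", locator$path)
      locator$path
    }
    if (length(files) == 0) stop("no TIFF planes found under ", locator$path)
    first <- tiff::readTIFF(files[1], all = TRUE, as.is = TRUE)
    nz <- if (length(files) == 1) length(first) else length(files)
    p1 <- first[[1]]
    vol <- list(backend = "tiff", path = locator$path, files = files,
                multipage = length(files) == 1,
                dim_yxz = c(nrow(p1), ncol(p1), nz), levels = 1,
                channel_id = channel, voxel_pitch = voxel_pitch,
                dtype = "uint16")
  }
  structure(vol, class = "fluor_volume")
}

#' Wrap an in-memory array as a fluorescence volume
#'
#' @param x 3D numeric array with dimensions ordered `(y, x, z)`.
#' @param channel_id channel label.
#' @inheritParams open_volume
#' @return A `fluor_volume` backed by the array.
#' @export
as_fluor_volume <- function(x, channel_id = "channel",
                            voxel_pitch = c(z = 1, y = 1, x = 1)) {
  if (length(dim(x)) != 3L) stop("x must be a 3D array (y, x, z)")
  if (any(voxel_pitch <= 0)) stop("voxel_pitch must be strictly positive")
  if (min(x) < 0) stop("intensities must be >= 0")
  structure(list(backend = "array", data = x, dim_yxz = dim(x), levels = 1,
                 channel_id = channel_id, voxel_pitch = voxel_pitch,
                 dtype = "uint16"),
            class = "fluor_volume")
}

#' Shape of a volume at a pyramid level
#'
#' @param vol a `fluor_volume`.
#' @param level down-sampling factor (1 = full resolution).
#' @return Named integer vector `(z, y, x)`: `ceiling(full shape / level)`.
#' @export
vol_shape <- function(vol, level = 1) {
  d <- ceiling(vol$dim_yxz / level)
  c(z = d[3], y = d[1], x = d[2])
}

#' @export
print.fluor_volume <- function(x, ...) {
  s <- vol_shape(x)
  cat(sprintf("<fluor_volume> channel '%s' (%s backend)\n", x$channel_id, x$backend))
  cat(sprintf("  shape (z,y,x): %d x %d x %d; levels: %s\n",
              s["z"], s["y"], s["x"], paste(x$levels, collapse = ", ")))
  cat(sprintf("  voxel pitch (um): %s\n",
              paste(format(x$voxel_pitch), collapse = ", ")))
  invisible(x)
}

.read_plane_full <- function(vol, z) {
  switch(vol$backend,
    array = vol$data[, , z],
    hdf5 = {
      ds <- vol$datasets[["1"]]
      out <- rhdf5::h5read(vol$path, ds, index = list(NULL, NULL, z))
      dim(out) <- vol$dim_yxz[1:2]
      storage.mode(out) <- "double"
      out
    },
    tiff = {
      p <- if (vol$multipage) tiff::readTIFF(vol$files[1], all = TRUE, as.is = TRUE)[[z]]
           else tiff::readTIFF(vol$files[z], as.is = TRUE)
      storage.mode(p) <- "double"
      p
    })
}

#' Read one 2D plane from a volume
#'
#' Returns the `(y, x)` plane at depth `z` (1-based) at the requested pyramid
#' level. Levels absent from the container are synthesized by block-mean
#' pooling of the full-resolution data: the level-`f` plane `z` averages
#' full-resolution planes `((z-1)*f + 1) .. min(z*f, Z)`.
#'
#' @inheritParams vol_shape
#' @param z 1-based plane index at the requested level.
#' @return Numeric matrix `(y, x)`.
#' @export
read_plane <- function(vol, z, level = 1) {
  s <- vol_shape(vol, level)
  if (z < 1 || z > s["z"]) stop("z out of range [1, ", s["z"], "] at level ", level)
  if (level == 1) return(.read_plane_full(vol, z))
  if (vol$backend == "hdf5" && level %in% vol$levels) {
    ds <- vol$datasets[[as.character(level)]]
    out <- rhdf5::h5read(vol$path, ds, index = list(NULL, NULL, z))
    dim(out) <- ceiling(vol$dim_yxz[1:2] / level)
    storage.mode(out) <- "double"
    return(out)
  }
  zfull <- ((z - 1) * level + 1):min(z * level, vol$dim_yxz[3])
  planes <- lapply(zfull, function(zz) downsample_block_mean(.read_plane_full(vol, zz), level))
  Reduce(`+`, planes) / length(planes)
}

#' Read a whole volume at a pyramid level
#'
#' Intended for the coarse levels (e.g. 16x) feeding background estimation
#' and the leveling map; reading level 1 of a large volume loads it whole.
#'
#' @inheritParams vol_shape
#' @return Numeric 3D array `(y, x, z)`.
#' @export
read_volume <- function(vol, level = 16) {
  if (vol$backend == "array" && level == 1) return(vol$data)
  if (vol$backend == "hdf5" && level %in% vol$levels) {
    out <- rhdf5::h5read(vol$path, vol$datasets[[as.character(level)]])
    storage.mode(out) <- "double"
    dim(out) <- ceiling(vol$dim_yxz / level)
    return(out)
  }
  s <- vol_shape(vol, level)
  out <- array(0, c(s["y"], s["x"], s["z"]))
  for (z in seq_len(s["z"])) out[, , z] <- read_plane(vol, z, level)
  out
}

#' Write an 8-bit RGB image
#'
#' @param image `rendered_plane` or integer array `(y, x, 3)` with values
#'   in 0..255.
#' @param path output file; the format is inferred from the extension unless
#'   given explicitly.
#' @param format `"auto"`, `"png"`, or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path, format = c("auto", "png", "tiff")) {
  format <- match.arg(format)
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be (y, x, 3)")
  v <- image
  attributes(v) <- list(dim = d)
  if (min(v) < 0 || max(v) > 255) stop("image values must lie in 0..255")
  if (format == "auto")
    format <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) "tiff" else "png"
  ok <- tryCatch({
    if (format == "png") png::writePNG(v / 255, path)
    else tiff::writeTIFF(v / 255, path, bits.per.sample = 8)
    TRUE
  }, error = function(e) stop("failed to write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read an 8-bit RGB image back as integer counts
#'
#' @param path PNG or TIFF file.
#' @return Integer array `(y, x, 3)`, values 0..255.
#' @export
read_rgb <- function(path) {
  x <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  out <- array(as.integer(round(x * 255)), dim(x))
  if (length(dim(out)) == 2L) out <- array(out, c(dim(out), 3L))  # grayscale guard
  out[, , 1:3, drop = FALSE]
}

#' Deferred-write RGB output queue
#'
#' Write-behind contract for plane output: with `async = FALSE` every
#' [write_rgb()] happens at submit time. With `async = TRUE` submissions are
#' buffered in a bounded queue (`queue_size`); the oldest entry is flushed
#' when the queue is full, and `drain()` flushes everything. A plane is never
#' reported submitted before it is durably queued, and closing the pipeline
#' blocks until the queue drains, so pipeline completion implies all files
#' exist. The buffering is in-process (R runs the queue on the main thread);
#' the contract, not a kernel thread, is what downstream code relies on.
#'
#' @param async buffer writes (default `FALSE` for deterministic error
#'   reporting at submit time).
#' @param queue_size maximum buffered planes when `async = TRUE`.
#' @return An object with `$submit(image, path, format)`, `$drain()`, and
#'   `$written()` (paths written so far).
#' @export
rgb_writer <- function(async = FALSE, queue_size = 8) {
  env <- new.env(parent = emptyenv())
  env$queue <- list()
  env$written <- character()
  flush1 <- function() {
    it <- env$queue[[1]]
    env$queue <- env$queue[-1]
    write_rgb(it$image, it$path, it$format)
    env$written <- c(env$written, it$path)
  }
  submit <- function(image, path, format = "auto") {
    if (!async) {
      write_rgb(image, path, format)
      env$written <- c(env$written, path)
    } else {
      env$queue[[length(env$queue) + 1L]] <- list(image = image, path = path,
                                                  format = format)
      while (length(env$queue) > queue_size) flush1()
    }
    invisible(path)
  }
  drain <- function() {
    while (length(env$queue) > 0L) flush1()
    invisible(env$written)
  }
  structure(list(submit = submit, drain = drain,
                 written = function() env$written,
                 pending = function() length(env$queue)),
            class = "rgb_writer")
}
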