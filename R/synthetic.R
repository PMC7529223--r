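#' Specify a synthetic two-channel tissue phantom
#'
#' The phantom emulates the statistical structure the leveling and staining
#' method assumes: Poisson-placed nuclear blobs over a cytoplasmic floor in
#' the nuclear channel, band-limited stromal texture in the eosin channel,
#' tissue-wide autofluorescence in both, a smooth multiplicative staining
#' gain field (e.g. exterior-bright/interior-dim, as seen in thick,
#' incompletely penetrated specimens), and an sCMOS-like detector noise
#' floor. Identical specs and seeds give bit-identical volumes.
#'
#' Default intensity levels describe a realistically stained cleared
#' specimen: a stained tissue core (an ellipse) surrounded by cleared,
#' weakly autofluorescent unstained matrix, so the field of view contains an
#' above-noise-floor but dim population from which the background estimator
#' reads the autofluorescence level, as in real specimens. Within tissue the
#' nuclear channel has roughly 10:1 contrast between nucleus peaks and
#' nonspecific cytoplasmic signal; the eosin channel is roughly uniform
#' across tissue, with nuclei at 85 percent of the local stroma (nuclei
#' retain some eosin); the camera contributes a 100-count offset and
#' 10-count read noise (16-bit sCMOS-like). Noise is Gaussian about the
#' floor; shot noise is omitted for test determinism at these intensities.
#' Nuclei are isotropic super-Gaussian plateaus (filled nuclei blurred by a
#' sub-micron point-spread function) without internal chromatin texture -
#' sufficient for leveling and colorimetry work, and a stated limitation of
#' the fixture.
#'
#' @param shape named `(z, y, x)` voxel counts.
#' @param voxel_pitch named `(z, y, x)` micrometres per voxel (the default
#'   0.39 um matches raw data in which 100 um spans 256 pixels).
#' @param nucleus_density expected nuclei per 100 um^3 of tissue.
#' @param nucleus_radius `(mean, sd)` nuclear radius in um.
#' @param texture_corr_length stromal texture correlation length, um.
#' @param texture_cv coefficient of variation of the stromal texture.
#' @param autofluorescence field-wide autofluorescence signal, counts
#'   (present in both channels, inside and outside the stained core; not
#'   modulated by the staining gain).
#' @param nuclear_levels `(stroma, nucleus)` counts in the nuclear channel:
#'   nonspecific cytoplasmic level and nucleus peak amplitude (added on
#'   top).
#' @param eosin_levels `(stroma, nucleus_factor)`: stromal mean counts and
#'   the relative eosin level inside nuclei.
#' @param gain_profile `"uniform"`, `"linear"` (along x), or `"radial"`
#'   (bright rim, dim core).
#' @param gain_range `(min, max)` of the gain field.
#' @param global_gain overall staining-intensity multiplier (inter-specimen
#'   variation dial; 1 = reference specimen).
#' @param tissue `"ellipse"` (tissue ellipse on an empty background) or
#'   `"full"` (tissue fills the volume).
#' @param amplitude_cv relative spread of per-nucleus stain amplitude
#'   (0 makes every nucleus peak exactly `nuclear_levels["nucleus"]`).
#' @param noise_floor,noise_sigma detector offset and read noise, counts.
#' @param seed RNG seed.
#' @return A `tissue_phantom_spec`.
#' @export
tissue_phantom_spec <- function(shape = c(z = 24, y = 512, x = 512),
                                voxel_pitch = c(z = 0.39, y = 0.39, x = 0.39),
                                nucleus_density = 0.15,
                                nucleus_radius = c(mean = 3.5, sd = 0.5),
                                texture_corr_length = 8,
                                texture_cv = 0.3,
                                autofluorescence = 150,
                                nuclear_levels = c(stroma = 700, nucleus = 4000),
                                eosin_levels = c(stroma = 2800, nucleus_factor = 0.85),
                                gain_profile = c("radial", "linear", "uniform"),
                                gain_range = c(0.6, 1.0),
                                global_gain = 1,
                                tissue = c("ellipse", "full"),
                                amplitude_cv = 0.08,
                                noise_floor = 100, noise_sigma = 10,
                                seed = 1) {
  gain_profile <- match.arg(gain_profile)
  tissue <- match.arg(tissue)
  stopifnot(all(shape > 0), all(voxel_pitch > 0), nucleus_density >= 0,
            nucleus_radius[1] > 0, texture_corr_length > 0, texture_cv >= 0,
            all(gain_range > 0), global_gain > 0, amplitude_cv >= 0,
            noise_sigma >= 0)
  structure(list(shape = shape, voxel_pitch = voxel_pitch,
                 nucleus_density = nucleus_density,
                 nucleus_radius = nucleus_radius,
                 texture_corr_length = texture_corr_length,
                 texture_cv = texture_cv,
                 autofluorescence = autofluorescence,
                 nuclear_levels = nuclear_levels,
                 eosin_levels = eosin_levels,
                 gain_profile = gain_profile, gain_range = gain_range,
                 global_gain = global_gain, tissue = tissue,
                 amplitude_cv = amplitude_cv,
                 noise_floor = noise_floor, noise_sigma = noise_sigma,
                 seed = seed),
            class = "tissue_phantom_spec")
}

# Smooth 3D unit-variance Gaussian field with the requested correlation
# length, built by trilinear upsampling of a coarse white-noise grid.
.smooth_field <- function(dims_yxz, corr_vox) {
  g <- pmax(2L, ceiling(dims_yxz / corr_vox) + 1L)
  grid <- array(stats::rnorm(prod(g)), g)
  Wy <- .lin_weights(dims_yxz[1], seq(1, dims_yxz[1], length.out = g[1]))
  Wx <- .lin_weights(dims_yxz[2], seq(1, dims_yxz[2], length.out = g[2]))
  Wz <- .lin_weights(dims_yxz[3], seq(1, dims_yxz[3], length.out = g[3]))
  out <- array(0, dims_yxz)
  for (z in seq_len(dims_yxz[3])) {
    Gz <- matrix(0, g[1], g[2])
    for (k in seq_len(g[3])) if (Wz[z, k] != 0) Gz <- Gz + Wz[z, k] * grid[, , k]
    out[, , z] <- Wy %*% Gz %*% t(Wx)
  }
  out / stats::sd(out)
}

.gain_field <- function(spec, Y, X) {
  g0 <- spec$gain_range[1]; g1 <- spec$gain_range[2]
  switch(spec$gain_profile,
    uniform = matrix(g1, Y, X),
    linear = matrix(rep(g0 + (g1 - g0) * (seq_len(X) - 1) / max(X - 1, 1),
                        each = Y), Y, X),
    radial = {
      cy <- (Y + 1) / 2; cx <- (X + 1) / 2
      dy <- (seq_len(Y) - cy) / (Y / 2)
      dx <- (seq_len(X) - cx) / (X / 2)
      d <- sqrt(outer(dy^2, dx^2, `+`))
      g0 + (g1 - g0) * pmin(d, 1)       # bright exterior, dim core
    })
}

#' Generate a two-channel tissue phantom
#'
#' @param spec a [tissue_phantom_spec()].
#' @return A `tissue_phantom`: list with `nuclear` and `eosin`
#'   (`fluor_volume`s), `labels` (integer array `(y, x, z)`: 0 background,
#'   1 nucleus, 2 stroma), `gain` (the 2D gain field), `nuclei` (ground-truth
#'   table of centers, radii and amplitudes), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "tissue_phantom_spec"))
  Z <- spec$shape[["z"]]; Y <- spec$shape[["y"]]; X <- spec$shape[["x"]]
  pitch <- spec$voxel_pitch
  dims <- c(Y, X, Z)
  .with_seed(spec$seed, {
    # tissue support (2D, replicated along z)
    tissue2d <- if (spec$tissue == "full") matrix(1, Y, X) else {
      cy <- (Y + 1) / 2; cx <- (X + 1) / 2
      dy <- (seq_len(Y) - cy) / (0.45 * Y)
      dx <- (seq_len(X) - cx) / (0.45 * X)
      (outer(dy^2, dx^2, `+`) <= 1) * 1
    }
    gain2d <- .gain_field(spec, Y, X)

    # stromal texture, lognormal about mean 1
    corr_vox <- spec$texture_corr_length / mean(pitch[c("y", "x")])
    tex <- exp(spec$texture_cv * .smooth_field(dims, corr_vox))
    tex <- tex / mean(tex)

    # nuclei: Poisson count over the tissue volume, uniform positions
    vox_um3 <- prod(pitch)
    tissue_um3 <- sum(tissue2d) * Z * vox_um3
    n_exp <- spec$nucleus_density * tissue_um3 / 100
    n_nuc <- if (n_exp > 0) stats::rpois(1, n_exp) else 0L
    nuc <- array(0, dims)
    if (n_nuc > 0) {
      cand <- which(tissue2d > 0)
      pos <- cand[sample.int(length(cand), n_nuc, replace = TRUE)]
      py <- ((pos - 1) %% Y) + 1
      px <- ((pos - 1) %/% Y) + 1
      pz <- sample.int(Z, n_nuc, replace = TRUE)
      radii <- pmax(stats::rnorm(n_nuc, spec$nucleus_radius[1],
                                 spec$nucleus_radius[2]),
                    spec$nucleus_radius[1] / 2)
      amps <- if (spec$amplitude_cv > 0)
        pmax(stats::rnorm(n_nuc, 1, spec$amplitude_cv), 0.5) else rep(1, n_nuc)
      occupancy <- n_nuc * (4 / 3) * pi * mean(radii)^3 / tissue_um3
      if (occupancy > 0.6)
        warning("nucleus density so high that blobs fill ",
                round(100 * occupancy), "% of the tissue; heavy overlap")
      for (i in seq_len(n_nuc)) {
        # filled nucleus: super-Gaussian plateau with half-maximum at the
        # radius (chromatin-dense interior blurred by a sub-micron PSF)
        r <- radii[i]
        ext <- ceiling(1.6 * r / c(pitch[["y"]], pitch[["x"]], pitch[["z"]]))
        ys <- max(1, py[i] - ext[1]):min(Y, py[i] + ext[1])
        xs <- max(1, px[i] - ext[2]):min(X, px[i] + ext[2])
        zs <- max(1, pz[i] - ext[3]):min(Z, pz[i] + ext[3])
        dy2 <- ((ys - py[i]) * pitch[["y"]])^2
        dx2 <- ((xs - px[i]) * pitch[["x"]])^2
        dz2 <- ((zs - pz[i]) * pitch[["z"]])^2
        d2 <- outer(outer(dy2, dx2, `+`), dz2, `+`)
        nuc[ys, xs, zs] <- nuc[ys, xs, zs] +
          amps[i] * exp(-log(2) * (d2 / r^2)^2)
      }
    }

    soft <- pmin(nuc, 1)
    af <- spec$autofluorescence
    # stain signal is confined to the tissue core and modulated by the gain
    # field; autofluorescence pervades the whole (cleared) field of view
    stain_n <- (spec$nuclear_levels[["stroma"]] +
                  spec$nuclear_levels[["nucleus"]] * nuc)
    stain_e <- (spec$eosin_levels[["stroma"]] * tex *
                  (1 - (1 - spec$eosin_levels[["nucleus_factor"]]) * soft))
    shade <- c(tissue2d * gain2d) * spec$global_gain   # recycles along z
    noise <- function() if (spec$noise_sigma > 0)
      array(stats::rnorm(prod(dims), 0, spec$noise_sigma), dims) else 0
    quantize <- function(stain) {
      v <- round(af + stain * shade + spec$noise_floor + noise())
      array(pmin(pmax(v, 0), 65535), dims)
    }
    nuclear <- quantize(stain_n)
    eosin <- quantize(stain_e)
    labels <- array(0L, dims)
    in_tissue <- rep(c(tissue2d) > 0, Z)
    labels[in_tissue] <- 2L                   # stroma wherever tissue
    labels[nuc > 0.5 & in_tissue] <- 1L       # kernel spill outside stays 0
    nuclei <- if (n_nuc > 0)
      data.frame(y = py, x = px, z = pz, radius = radii, amp = amps)
    else data.frame(y = integer(), x = integer(), z = integer(),
                    radius = numeric(), amp = numeric())
  })
  structure(list(
    nuclear = as_fluor_volume(nuclear, "nuclear", spec$voxel_pitch),
    eosin = as_fluor_volume(eosin, "eosin", spec$voxel_pitch),
    labels = labels, gain = gain2d, nuclei = nuclei, spec = spec),
    class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  s <- x$spec$shape
  cat(sprintf("<tissue_phantom> %d x %d x %d (z,y,x), %d nucleus voxels, seed %d\n",
              s[["z"]], s[["y"]], s[["x"]], sum(x$labels == 1L), x$spec$seed))
  invisible(x)
}

.h5_ensure_groups <- function(path, ds) {
  parts <- strsplit(ds, "/")[[1]]
  parts <- parts[-length(parts)]
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  cur <- ""
  for (p in parts) {
    cur <- if (cur == "") p else paste(cur, p, sep = "/")
    if (!rhdf5::H5Lexists(fid, cur)) rhdf5::h5createGroup(fid, cur)
  }
}

#' Write a phantom to a multi-resolution HDF5 container
#'
#' Stores both channels at full resolution and 16x block-mean down-sampled,
#' under the BigStitcher-style layout that [volume_locator()] expects by
#' default, as unsigned 16-bit integers.
#'
#' @param phantom a [generate_phantom()] result.
#' @param path output `.h5` file.
#' @param dataset_template,channels,levels as in [volume_locator()].
#' @return The [volume_locator()] resolving the written container.
#' @export
write_phantom_container <- function(phantom, path,
                                    dataset_template = "t00000/s{channel}/{level}/cells",
                                    channels = c(nuclear = "00", eosin = "01"),
                                    levels = c("0" = 1, "1" = 16)) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  loc <- volume_locator(path, format = "hdf5",
                        dataset_template = dataset_template,
                        channels = channels, levels = levels)
  for (ch in names(channels)) {
    full <- phantom[[ch]]$data
    for (k in names(levels)) {
      f <- levels[[k]]
      arr <- if (f == 1) full else round(downsample_block_mean(full, f))
      storage.mode(arr) <- "integer"
      ds <- .resolve_dataset(loc, ch, k)
      .h5_ensure_groups(path, ds)
      rhdf5::h5createDataset(path, ds, dims = dim(arr),
                             H5type = "H5T_NATIVE_UINT16",
                             chunk = pmin(dim(arr), c(128, 128, 8)), level = 2)
      rhdf5::h5write(arr, path, ds)
    }
  }
  rhdf5::h5closeAll()
  loc
}
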