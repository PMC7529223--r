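test_that("phantom generation is bit-identical for identical spec and seed", {
  spec <- tissue_phantom_spec(shape = c(z = 4, y = 48, x = 48), seed = 5)
  a <- suppressWarnings(generate_phantom(spec))
  b <- suppressWarnings(generate_phantom(spec))
  expect_identical(a$nuclear$data, b$nuclear$data)
  expect_identical(a$eosin$data, b$eosin$data)
  expect_identical(a$labels, b$labels)
  c2 <- suppressWarnings(generate_phantom(
    tissue_phantom_spec(shape = c(z = 4, y = 48, x = 48), seed = 6)))
  expect_false(identical(a$nuclear$data, c2$nuclear$data))
})

test_that("zero nucleus density leaves only floor, autofluorescence and noise", {
  spec <- tissue_phantom_spec(shape = c(z = 4, y = 32, x = 32),
                              nucleus_density = 0, autofluorescence = 0,
                              nuclear_levels = c(stroma = 0, nucleus = 0),
                              noise_floor = 100, noise_sigma = 10, seed = 3)
  ph <- generate_phantom(spec)
  x <- ph$nuclear$data
  expect_lt(abs(mean(x) - 100), 2)
  expect_lt(abs(sd(x) - 10), 1)
  expect_equal(nrow(ph$nuclei), 0)
})

test_that("with unit gain and no noise, nucleus peaks hit the specified level", {
  spec <- tissue_phantom_spec(shape = c(z = 12, y = 96, x = 96),
                              nucleus_density = 0.01, amplitude_cv = 0,
                              gain_profile = "uniform", gain_range = c(1, 1),
                              noise_sigma = 0, tissue = "full", seed = 8)
  ph <- generate_phantom(spec)
  nuc <- ph$nuclei
  expect_gt(nrow(nuc), 0)
  expected <- spec$autofluorescence + spec$noise_floor +
    spec$nuclear_levels[["stroma"]] + spec$nuclear_levels[["nucleus"]]
  # isolated nuclei (far from all others) peak at exactly the specified level
  d <- as.matrix(dist(nuc[, c("y", "x", "z")] *
                        rep(spec$voxel_pitch[c("y", "x", "z")],
                            each = nrow(nuc))))
  diag(d) <- Inf
  iso <- which(apply(d, 1, min) > 4 * max(nuc$radius))
  skip_if(length(iso) == 0, "no isolated nucleus in this realization")
  for (i in iso) {
    peak <- ph$nuclear$data[nuc$y[i], nuc$x[i], nuc$z[i]]
    expect_equal(peak, round(expected))
  }
})

test_that("a linear gain field reproduces the specified brightness ratio", {
  spec <- tissue_phantom_spec(shape = c(z = 24, y = 192, x = 256),
                              gain_profile = "linear", gain_range = c(0.3, 1.0),
                              nucleus_density = 0.05,
                              amplitude_cv = 0, noise_sigma = 0,
                              autofluorescence = 0, tissue = "full", seed = 12)
  ph <- suppressWarnings(generate_phantom(spec))
  nuc <- ph$nuclei
  # isolated nuclei only, so overlap does not inflate peaks
  d <- as.matrix(dist(nuc[, c("y", "x", "z")])) * min(spec$voxel_pitch)
  diag(d) <- Inf
  iso <- apply(d, 1, min) > 9   # two plateau extents (~1.3 r each) apart
  expect_gt(sum(iso), 10)
  nuc <- nuc[iso, ]
  peaks <- ph$nuclear$data[cbind(nuc$y, nuc$x, nuc$z)] - spec$noise_floor
  gains <- ph$gain[cbind(nuc$y, nuc$x)]
  # peak counts are proportional to the local gain (ground-truth oracle)
  ratio <- peaks / gains
  expect_lt(sd(ratio) / mean(ratio), 0.02)
  # brightest vs dimmest third of the ramp shows the ~2x+ contrast
  bright <- nuc$x > 2 * 256 / 3; dim <- nuc$x < 256 / 3
  got <- mean(peaks[bright]) / mean(peaks[dim])
  expected <- mean(gains[bright]) / mean(gains[dim])
  expect_lt(abs(got / expected - 1), 0.05)
  expect_gt(got, 1.5)
})

test_that("phantom container stores two channels under distinct dataset paths", {
  ph <- small_phantom()
  path <- withr::local_tempfile(fileext = ".h5")
  loc <- write_phantom_container(ph, path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  expect_true(rhdf5::H5Lexists(fid, "t00000/s00/0/cells"))
  expect_true(rhdf5::H5Lexists(fid, "t00000/s01/0/cells"))
  expect_true(rhdf5::H5Lexists(fid, "t00000/s00/1/cells"))
})

test_that("leveling flattens a smooth gain field to uniform local medians", {
  # stationary texture times a strong linear gain across the tissue core:
  # raw per-cube medians spread by far more than half their mean, the
  # leveled ones by under 5% (interior tissue cubes; edge cubes mix in the
  # unstained matrix)
  # pure gain x texture volume (zero-background case of the scale
  # equivariance property): stroma only, no detector offset. Cubes hold
  # 16^3 coarse voxels (level 2, cube edge 32), the sampling density the
  # local-median estimate needs; fine-grained texture keeps those samples
  # nearly independent
  spec <- tissue_phantom_spec(shape = c(z = 64, y = 128, x = 512),
                              gain_profile = "linear", gain_range = c(0.3, 1.0),
                              tissue = "full", nucleus_density = 0,
                              texture_corr_length = 1, texture_cv = 0.1,
                              autofluorescence = 0, noise_floor = 0,
                              noise_sigma = 0, seed = 31)
  ph <- generate_phantom(spec)
  vol <- ph$eosin
  low <- read_volume(vol, 2)
  map <- suppressWarnings(
    build_leveling_map(low, background = 0, cube_shape = 32, level = 2,
                       alpha = 3.7, full_shape = vol$dim_yxz))
  spread <- function(m) (max(m) - min(m)) / mean(m)
  cube_medians <- function(vol3d, cube = 32) {
    out <- c()
    for (i in seq_len(128 / cube)) for (j in seq_len(512 / cube)) {
      ys <- ((i - 1) * cube + 1):(i * cube)
      xs <- ((j - 1) * cube + 1):(j * cube)
      out <- c(out, median(vol3d[ys, xs, ]))
    }
    out
  }
  zsel <- c(16, 32, 48)
  raw <- vapply(zsel, function(z) read_plane(vol, z), matrix(0, 128, 512))
  lev <- vapply(zsel, function(z)
    level_plane(read_plane(vol, z),
                interpolate_plane_map(map, z))$values, matrix(0, 128, 512))
  expect_gt(spread(cube_medians(raw)), 0.5)
  expect_lt(spread(cube_medians(lev)), 0.05)
})

test_that("leveling removes the dim-core artifact from rendered nuclei", {
  # radial exterior-bright gain (poorly penetrated thick specimen):
  # with a fixed normalization tuned on the dim core, rim nuclei render
  # much darker than core nuclei; leveling equalizes them. Ground-truth
  # gain defines the two zones.
  spec <- tissue_phantom_spec(shape = c(z = 12, y = 384, x = 384),
                              gain_profile = "radial", gain_range = c(0.2, 1.0),
                              amplitude_cv = 0, seed = 33)
  ph <- generate_phantom(spec)
  vol <- ph$nuclear
  low <- read_volume(vol, 16)
  bg <- compute_background(low, 100, 10)
  map <- suppressWarnings(
    build_leveling_map(subtract_background(low, bg), bg, cube_shape = 48,
                       level = 16, alpha = 1.5, full_shape = vol$dim_yxz))
  # unleveled normalization: leveling constant tuned on the specimen core
  s <- low - bg$b
  core <- s[10:15, 10:15, , drop = FALSE]
  divisor <- 1.5 * median(core[core > bg$b])
  e0 <- matrix(0, 384, 384)
  vL <- vU <- array(NA_real_, dim(ph$labels))
  for (z in 1:12) {
    raw <- subtract_background(read_plane(vol, z), bg$b)
    lev <- level_plane(raw, interpolate_plane_map(map, z))$values
    iL <- unclass(beer_lambert_render(lev, e0))
    iU <- unclass(beer_lambert_render(raw / divisor, e0))
    vL[, , z] <- pmax(pmax(iL[, , 1], iL[, , 2]), iL[, , 3]) / 255
    vU[, , z] <- pmax(pmax(iU[, , 1], iU[, , 2]), iU[, , 3]) / 255
  }
  g3 <- array(rep(c(ph$gain), 12), dim(ph$labels))
  dim_zone <- ph$labels == 1 & g3 < 0.5
  bright_zone <- ph$labels == 1 & g3 > 0.8
  skip_if(sum(dim_zone) < 2000 || sum(bright_zone) < 2000,
          "too few nuclei in a zone")
  expect_gt(abs(mean(vU[dim_zone]) - mean(vU[bright_zone])), 0.15)
  expect_lt(abs(mean(vL[dim_zone]) - mean(vL[bright_zone])), 0.05)
})

test_that("phantom warns when nuclei crowd the volume", {
  spec <- tissue_phantom_spec(shape = c(z = 4, y = 32, x = 32),
                              nucleus_density = 2, seed = 2)
  expect_warning(generate_phantom(spec), "density so high")
})
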