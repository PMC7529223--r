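# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small, fast phantom for unit tests (full defaults are exercised in the
# acceptance tests).
small_phantom <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_phantom(tissue_phantom_spec(
      shape = c(z = 8, y = 96, x = 96), seed = 42))
  }
  .fixture_cache$small
}

# Per-pixel Beer-Lambert oracle: naive scalar loop, independent of the
# package's vectorized and compiled paths.
bl_loop_oracle <- function(h, e, palette, ceiling = 50) {
  pal <- get_palette(palette)
  out <- array(0L, c(dim(h), 3L))
  for (i in seq_len(nrow(h))) for (j in seq_len(ncol(h))) {
    hv <- min(h[i, j], ceiling); ev <- min(e[i, j], ceiling)
    for (c in 1:3) {
      v <- 255 * exp(-pal$j[c] * hv) * exp(-pal$k[c] * ev)
      out[i, j, c] <- as.integer(min(max(floor(v + 0.5), 0), 255))
    }
  }
  out
}

# Exhaustive-search Otsu oracle: maximize between-class variance over a
# fixed grid of candidate thresholds.
otsu_oracle <- function(x, levels = 256) {
  cand <- seq(min(x), max(x), length.out = levels)
  best <- cand[1]; best_v <- -Inf
  for (t in cand) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(x)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best <- t }
  }
  best
}

# Sort-and-interpolate percentile oracle (linear interpolation between order
# statistics, the standard definition).
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Mean HSV "value" component of an RGB render at given pixel indices.
v_component <- function(rgb, idx) {
  r <- rgb[, , 1][idx]; g <- rgb[, , 2][idx]; b <- rgb[, , 3][idx]
  mean(pmax(pmax(r, g), b)) / 255
}
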