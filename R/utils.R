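# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the RNG alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Block-mean down-sampling
#'
#' Pools a 2D or 3D array by non-overlapping blocks of edge `factor`,
#' averaging the pixels in each block. Partial edge blocks average whatever
#' pixels they contain, so the output shape is `ceiling(dim / factor)`.
#' Mean pooling (rather than striding) suppresses detector noise, which
#' matters when the down-sampled data feed background estimation.
#'
#' @param x numeric 2D or 3D array.
#' @param factor integer down-sampling factor (>= 1), applied to every axis.
#' @return array of shape `ceiling(dim(x) / factor)`.
#' @export
downsample_block_mean <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(x)
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) stop("x must be 2D or 3D")
  for (ax in seq_along(d)) x <- .pool_axis(x, factor, ax)
  x
}

# Mean-pool one axis of an array by grouping indices into blocks of `f`.
.pool_axis <- function(x, f, axis) {
  d <- dim(x)
  n <- d[axis]
  if (n <= 1L) return(x)
  grp <- ceiling(seq_len(n) / f)
  ng <- max(grp)
  perm <- c(axis, seq_along(d)[-axis])
  xp <- aperm(x, perm)
  dim(xp) <- c(n, prod(d[-axis]))
  s <- rowsum(xp, grp, reorder = TRUE)
  s <- s / as.vector(tabulate(grp, nbins = ng))
  dim(s) <- c(ng, d[-axis])
  aperm(s, order(perm))
}

# Linear-interpolation weight matrix: maps g samples at positions `centers`
# (strictly increasing) to n query positions 1..n, with constant
# extrapolation beyond the outer centers. Returns an n x g matrix.
.lin_weights <- function(n, centers) {
  g <- length(centers)
  W <- matrix(0, n, g)
  p <- seq_len(n)
  if (g == 1L) {
    W[, 1] <- 1
    return(W)
  }
  j <- findInterval(p, centers)
  lo <- j < 1L | p <= centers[1]
  hi <- j >= g | p >= centers[g]
  mid <- !(lo | hi)
  W[cbind(which(lo), 1L)] <- 1
  W[cbind(which(hi), g)] <- 1
  if (any(mid)) {
    jm <- j[mid]
    t <- (p[mid] - centers[jm]) / (centers[jm + 1L] - centers[jm])
    W[cbind(which(mid), jm)] <- 1 - t
    W[cbind(which(mid), jm + 1L)] <- t
  }
  W
}

# Exact 3x3 median filter with edge replication, vectorized as an odd-even
# transposition sorting network over the nine shifted copies (36
# compare-exchanges guarantee a full sort of 9 elements; element 5 is the
# median). Much faster than a histogram median for float-valued maps.
.median3x3 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  xp <- x[c(1, seq_len(n), n), c(1, seq_len(m), m)]
  v <- vector("list", 9L)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    v[[k]] <- xp[dy + seq_len(n), dx + seq_len(m)]
  }
  for (pass in 1:9) {
    start <- if (pass %% 2 == 1) 1L else 2L
    for (i in seq(start, 8L, by = 2L)) {
      lo <- pmin(v[[i]], v[[i + 1L]])
      v[[i + 1L]] <- pmax(v[[i]], v[[i + 1L]])
      v[[i]] <- lo
    }
  }
  v[[5L]]
}

# Centers (1-based, full-resolution coordinates) of the cubes tiling an axis
# of length n with cube edge c: midpoint of each cube's actual extent, so the
# partial last cube is centered on the pixels it owns.
.cube_centers <- function(n, c) {
  g <- ceiling(n / c)
  i <- seq_len(g)
  ((i - 1) * c + pmin(i * c, n) + 1) / 2
}
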