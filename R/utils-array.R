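# Vectorized 3D array primitives used by the flow solver, the pyramid, the
# phantom generator and TFCE. All operate on plain numeric arrays.

# reflect (mirror about the edge voxel) index vector for offset d, length n
.reflectIdx <- function(n, d) {
  i <- seq_len(n) + d
  # single fold suffices for |d| < n
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

# shift a 3D array by +d along one axis with reflected boundaries:
# out[i] = a[i + d] (content moves by -d)
.shiftAxis <- function(a, d, axis) {
  if (d == 0L) return(a)
  n <- dim(a)[axis]
  idx <- .reflectIdx(n, d)
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# shift with constant padding (used by connected-component labeling)
.shiftAxisConst <- function(a, d, axis, fill) {
  if (d == 0L) return(a)
  n <- dim(a)[axis]
  i <- seq_len(n) + d
  out <- i >= 1L & i <= n
  idx <- pmin(pmax(i, 1L), n)
  r <- switch(axis,
              a[idx, , , drop = FALSE],
              a[, idx, , drop = FALSE],
              a[, , idx, drop = FALSE])
  if (!all(out)) {
    bad <- which(!out)
    switch(axis,
           r[bad, , ] <- fill,
           r[, bad, ] <- fill,
           r[, , bad] <- fill)
  }
  r
}

# central difference along an axis, reflected edges
.centralDiff <- function(a, axis) {
  (.shiftAxis(a, 1L, axis) - .shiftAxis(a, -1L, axis)) / 2
}

# normalized 1D Gaussian kernel
.gauss1d <- function(sigma, radius = max(1L, ceiling(2.5 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable same-size convolution with a symmetric odd-length kernel,
# reflected boundaries
.sepConv3 <- function(a, k) {
  r <- (length(k) - 1L) %/% 2L
  offs <- seq(-r, r)
  for (axis in 1:3) {
    acc <- a * k[r + 1L]
    for (j in seq_along(offs)) {
      if (offs[j] == 0L) next
      acc <- acc + k[j] * .shiftAxis(a, offs[j], axis)
    }
    a <- acc
  }
  a
}

# blur + stride-2 decimation (one pyramid level down)
.downsample2 <- function(a, blurSigma = 0.85) {
  b <- .sepConv3(a, .gauss1d(blurSigma))
  d <- dim(b)
  b[seq(1L, d[1], 2L), seq(1L, d[2], 2L), seq(1L, d[3], 2L), drop = FALSE]
}

# trilinear sampling of a 3D volume at fractional voxel coordinates
# (1-based); coordinates are clamped to the volume (nearest at the border)
.trilinear <- function(vol, xi, yi, zi) {
  d <- dim(vol)
  xi <- pmin(pmax(xi, 1), d[1])
  yi <- pmin(pmax(yi, 1), d[2])
  zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), d[2] - 1L); fy <- yi - y0
  z0 <- pmin(floor(zi), d[3] - 1L); fz <- zi - z0
  if (d[1] == 1L) { x0 <- rep(1, length(xi)); fx <- 0 }
  if (d[2] == 1L) { y0 <- rep(1, length(yi)); fy <- 0 }
  if (d[3] == 1L) { z0 <- rep(1, length(zi)); fz <- 0 }
  nx <- d[1]; nxy <- d[1] * d[2]
  i000 <- x0 + (y0 - 1) * nx + (z0 - 1) * nxy
  v <- as.vector(vol)
  c00 <- v[i000] * (1 - fx) + v[i000 + 1] * fx
  c10 <- v[i000 + nx] * (1 - fx) + v[i000 + nx + 1] * fx
  c01 <- v[i000 + nxy] * (1 - fx) + v[i000 + nxy + 1] * fx
  c11 <- v[i000 + nx + nxy] * (1 - fx) + v[i000 + nx + nxy + 1] * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# voxel-center coordinate grids of a 3D array
.coordGrids <- function(d) {
  list(
    x = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
    y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
    z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  )
}

# backward-warp a volume by a displacement field: out(x) = vol(x + u(x))
.warpVolume <- function(vol, u, v, w) {
  g <- .coordGrids(dim(vol))
  array(.trilinear(vol, g$x + u, g$y + v, g$z + w), dim(vol))
}

# trilinear upsampling of a coarse 3D array to a fine grid whose stride-2
# decimation produced the coarse one (fine voxel i maps to coarse (i+1)/2)
.upsample2 <- function(a, fineDim) {
  g <- .coordGrids(fineDim)
  array(.trilinear(a, (g$x + 1) / 2, (g$y + 1) / 2, (g$z + 1) / 2), fineDim)
}

# 26- or 6-connected component labels of a logical 3D mask via iterative
# minimum-label propagation; returns an integer array, 0 outside the mask
.connectedLabels <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- which(mask)
  if (!any(mask)) return(array(0L, d))
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (connectivity == 6L && abs(dx) + abs(dy) + abs(dz) != 1L) next
    offs[[length(offs) + 1L]] <- c(dx, dy, dz)
  }
  repeat {
    old <- lab
    for (o in offs) {
      nb <- lab
      if (o[1] != 0L) nb <- .shiftAxisConst(nb, o[1], 1L, Inf)
      if (o[2] != 0L) nb <- .shiftAxisConst(nb, o[2], 2L, Inf)
      if (o[3] != 0L) nb <- .shiftAxisConst(nb, o[3], 3L, Inf)
      lab <- pmin(lab, nb)
      lab[!mask] <- Inf
    }
    if (identical(lab, old)) break
  }
  out <- array(0L, d)
  out[mask] <- as.integer(match(lab[mask], sort(unique(lab[mask]))))
  out
}

# run expr with a private RNG state, restoring the caller's state after
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
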