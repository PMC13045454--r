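# Independent brute-force oracles and small fixture builders. These are
# deliberately naive re-derivations (explicit loops, direct linear algebra)
# kept separate from the package's vectorized implementations.

# direct weighted normal-equations Lucas-Kanade solve at every voxel,
# explicit window loops, reflected edges
oracleLK <- function(prev, nxt, wr = 2L, sigma = wr / 1.5) {
  d <- dim(prev)
  avg <- (prev + nxt) / 2
  refl <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  gx <- function(a, i, j, k)
    (a[refl(i + 1, d[1]), j, k] - a[refl(i - 1, d[1]), j, k]) / 2
  gy <- function(a, i, j, k)
    (a[i, refl(j + 1, d[2]), k] - a[i, refl(j - 1, d[2]), k]) / 2
  gz <- function(a, i, j, k)
    (a[i, j, refl(k + 1, d[3])] - a[i, j, refl(k - 1, d[3])]) / 2
  w1 <- exp(-(seq(-wr, wr))^2 / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  out <- array(0, c(d, 3))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    A <- matrix(0, 3, 3); b <- numeric(3)
    for (di in -wr:wr) for (dj in -wr:wr) for (dk in -wr:wr) {
      ii <- refl(i + di, d[1]); jj <- refl(j + dj, d[2])
      kk <- refl(k + dk, d[3])
      wgt <- w1[di + wr + 1] * w1[dj + wr + 1] * w1[dk + wr + 1]
      g <- c(gx(avg, ii, jj, kk), gy(avg, ii, jj, kk), gz(avg, ii, jj, kk))
      it <- nxt[ii, jj, kk] - prev[ii, jj, kk]
      A <- A + wgt * tcrossprod(g)
      b <- b - wgt * g * it
    }
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= 1e-4 * sum(diag(A)))
      out[i, j, k, ] <- solve(A, b)
  }
  out
}

# brute-force TFCE: per threshold, BFS cluster labeling (queue-based, a
# different algorithm than the propagation used by the implementation)
oracleTFCE <- function(stat, H = 2, E = 0.5, dh = max(stat) / 100,
                       connectivity = 26L) {
  d <- dim(stat)
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (connectivity == 6L && sum(abs(c(dx, dy, dz))) != 1) next
    offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  out <- array(0, d)
  hs <- dh * seq_len(max(1L, floor(max(stat) / dh + 1e-9)))
  for (h in hs) {
    mask <- stat >= h
    if (!any(mask)) break
    seen <- array(FALSE, d)
    idx <- which(mask, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      if (seen[v[1], v[2], v[3]]) next
      queue <- list(v); seen[v[1], v[2], v[3]] <- TRUE
      members <- list()
      while (length(queue) > 0) {
        p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
        members[[length(members) + 1]] <- p
        for (o in offs) {
          q <- p + o
          if (any(q < 1) || any(q > d)) next
          if (mask[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
            seen[q[1], q[2], q[3]] <- TRUE
            queue[[length(queue) + 1]] <- q
          }
        }
      }
      e <- length(members)
      for (p in members)
        out[p[1], p[2], p[3]] <- out[p[1], p[2], p[3]] + e^E * h^H * dh
    }
  }
  out
}

# von Mises-Fisher sampler on S^2 (tangent-normal decomposition)
sampleVMF <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- runif(n, 0, 2 * pi)
  # orthonormal basis completing mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  s <- sqrt(pmax(1 - w^2, 0))
  t(vapply(seq_len(n), function(i)
    w[i] * mu + s[i] * (cos(phi[i]) * e1 + sin(phi[i]) * e2),
    numeric(3)))
}

# smooth random 3D volume (blurred white noise)
smoothVolume <- function(d, sigma = 1.5) {
  a <- array(rnorm(prod(d)), d)
  k <- exp(-(seq(-3, 3))^2 / (2 * sigma^2)); k <- k / sum(k)
  for (axis in 1:3) {
    acc <- a * k[4]
    for (off in c(-3:-1, 1:3)) {
      idx <- seq_len(d[axis]) + off
      idx <- ifelse(idx < 1, 2 - idx, idx)
      idx <- ifelse(idx > d[axis], 2 * d[axis] - idx, idx)
      acc <- acc + k[off + 4] * switch(axis, a[idx, , ], a[, idx, ],
                                       a[, , idx])
    }
    a <- acc
  }
  a
}

# Gaussian blob volume
gaussBlob <- function(d, center, sigma = 2.5, sign = 1) {
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  array(sign * exp(-((g$x - center[1])^2 + (g$y - center[2])^2 +
                       (g$z - center[3])^2) / (2 * sigma^2)), d)
}

# series of a blob moving at constant velocity (voxels/frame)
movingBlobSeries <- function(d, start, vel, nFrames, sigma = 2.5,
                             sign = 1, fs = 10) {
  dat <- array(0, c(d, nFrames))
  for (t in seq_len(nFrames))
    dat[, , , t] <- gaussBlob(d, start + (t - 1) * vel, sigma, sign)
  VolumeSeries(dat, samplingRate = fs, voxelSize = 3)
}
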