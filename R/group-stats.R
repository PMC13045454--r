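# Paired sign-flip permutation testing with TFCE and max-statistic FWER
# control, directional-reversal mapping, spatial correlation and the
# log-power regression against slow-delta power.

#' Threshold-free cluster enhancement
#'
#' Enhances a non-negative 3D statistic map by integrating cluster support
#' across thresholds: enhanced(v) = sum over thresholds h of
#' e(h, v)^E * h^H * dh, where e(h, v) is the extent of the supra-threshold
#' cluster containing v at height h. Defaults H = 2, E = 0.5, dh =
#' max(stat)/100, 26-connectivity (the field-standard parameterization).
#' Raising any voxel never decreases any enhanced value; signed maps are
#' handled by the two-sided wrapper inside [pairedPermutationTest()].
#'
#' @param statMap non-negative 3D array.
#' @param H height exponent.
#' @param E extent exponent.
#' @param dh threshold step (> 0); default max(statMap)/100.
#' @param connectivity 6 or 26.
#' @return Enhanced 3D array.
#' @export
tfceEnhance <- function(statMap, H = 2, E = 0.5, dh = NULL,
                        connectivity = 26L) {
  if (length(dim(statMap)) != 3L) stop("statMap must be a 3D array")
  if (any(statMap < 0))
    stop("statMap must be non-negative (use the two-sided wrapper for ",
         "signed statistics)")
  mx <- max(statMap)
  if (mx == 0) return(array(0, dim(statMap)))
  if (is.null(dh)) dh <- mx / 100
  if (!is.finite(dh) || dh <= 0) stop("dh must be > 0")
  out <- array(0, dim(statMap))
  # multiples of dh (not seq(), whose endpoint snapping makes the top
  # threshold depend on the map maximum at the 1-ulp level and would break
  # monotonicity under single-voxel changes)
  hs <- dh * seq_len(max(1L, floor(mx / dh + 1e-9)))
  for (h in hs) {
    mask <- statMap >= h
    if (!any(mask)) break
    lab <- .connectedLabels(mask, connectivity)
    sizes <- tabulate(lab[mask])
    out[mask] <- out[mask] + sizes[lab[mask]]^E * h^H * dh
  }
  out
}

# one-sample t statistics for all sign flips at once: D is n x V differences,
# S is nPerm x n signs; the per-voxel sum of squares is flip-invariant
.signFlipT <- function(D, S) {
  n <- nrow(D)
  M <- (S %*% D) / n
  ssq <- colSums(D^2)
  Vv <- sweep(-M^2, 2, ssq / n, "+") * n / (n - 1)
  Vv[Vv < 0] <- 0
  se <- sqrt(Vv / n)
  Tm <- M / se
  Tm[se == 0 & M == 0] <- 0
  big <- is.infinite(Tm) | (se == 0 & M != 0)
  if (any(big)) Tm[big] <- sign(M[big]) * 1e12
  Tm
}

# sign matrix: exhaustive enumeration of 2^n flips when feasible, else
# nPerm random draws with the identity forced first
.signMatrix <- function(n, nPerm) {
  if (2^n <= nPerm) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(S) <- NULL
    list(S = S, exhaustive = TRUE)
  } else {
    S <- matrix(sample(c(1, -1), nPerm * n, replace = TRUE), nPerm, n)
    S[1L, ] <- 1
    list(S = S, exhaustive = FALSE)
  }
}

# signed TFCE: enhance positive and negative parts separately
.tfceSigned <- function(map, H, E, dh, connectivity) {
  pos <- pmax(map, 0); neg <- pmax(-map, 0)
  enh <- array(0, dim(map))
  if (max(pos) > 0) enh <- enh + tfceEnhance(pos, H, E, dh, connectivity)
  if (max(neg) > 0) enh <- enh - tfceEnhance(neg, H, E, dh, connectivity)
  enh
}

#' Paired permutation test with max-statistic FWER control
#'
#' One-sample sign-flip test on the paired differences A - B (the
#' randomise-equivalent paired design): per-voxel t statistics, optionally
#' TFCE-enhanced, compared against the permutation null distribution of the
#' map-wise maximum statistic, which controls the family-wise error rate
#' over the map. Sign flips are enumerated exhaustively when 2^n does not
#' exceed `nPerm`.
#'
#' @param mapsA,mapsB 4D arrays `[x, y, z, subject]`, same subjects in the
#'   same order.
#' @param nPerm number of permutations (default 5000).
#' @param alpha significance level (default 0.05).
#' @param useTfce enhance the statistic maps with TFCE.
#' @param seed RNG seed for the sign flips.
#' @param alternative `"two.sided"` (max |stat| null), `"greater"` or
#'   `"less"` (one-sided contrasts, as used by the reversal mapping).
#' @param mask optional logical 3D array restricting the tested voxels.
#' @param H,E,dh,connectivity TFCE parameters, see [tfceEnhance()].
#' @return A [PermutationResult-class].
#' @export
pairedPermutationTest <- function(mapsA, mapsB, nPerm = 5000L, alpha = 0.05,
                                  useTfce = TRUE, seed = 1L,
                                  alternative = c("two.sided", "greater",
                                                  "less"),
                                  mask = NULL, H = 2, E = 0.5, dh = NULL,
                                  connectivity = 26L) {
  alternative <- match.arg(alternative)
  dA <- dim(mapsA); dB <- dim(mapsB)
  if (is.null(dA) || length(dA) != 4L || !identical(dA, dB))
    stop("mapsA and mapsB must be 4D arrays [x, y, z, subject] of ",
         "identical shape (paired subjects)")
  n <- dA[4L]
  if (n < 5L) stop("need at least 5 subject pairs")
  d3 <- dA[1:3]
  V <- prod(d3)
  if (is.null(mask)) mask <- array(TRUE, d3)
  mvec <- as.vector(mask)
  D <- t(matrix(mapsA - mapsB, V, n))[, mvec, drop = FALSE]
  sm <- .withSeed(seed, .signMatrix(n, nPerm))
  S <- sm$S
  Tm <- .signFlipT(D, S)
  sgn <- if (alternative == "less") -1 else 1
  statOf <- function(tv) {
    full <- numeric(V); full[mvec] <- tv
    map3 <- array(full, d3)
    if (useTfce) {
      enh <- if (alternative == "two.sided")
        .tfceSigned(map3, H, E, dh, connectivity)
      else {
        p <- pmax(sgn * map3, 0)
        if (max(p) > 0) sgn * tfceEnhance(p, H, E, dh, connectivity)
        else array(0, d3)
      }
      enh
    } else map3
  }
  obsIdx <- if (sm$exhaustive) which(rowSums(S == 1) == n)[1L] else 1L
  obsMap <- statOf(Tm[obsIdx, ])
  obsCrit <- if (alternative == "two.sided") abs(obsMap) else sgn * obsMap
  nP <- nrow(S)
  nullMax <- numeric(nP)
  for (p in seq_len(nP)) {
    m <- if (p == obsIdx) obsMap else statOf(Tm[p, ])
    nullMax[p] <- if (alternative == "two.sided") max(abs(m[mask]))
      else max(sgn * m[mask], 0)
  }
  pc <- array(1, d3)
  ov <- obsCrit[mask]
  pc[mask] <- vapply(ov, function(x) mean(nullMax >= x), numeric(1))
  sig <- array(FALSE, d3)
  sig[mask] <- pc[mask] < alpha
  new("PermutationResult", statMap = obsMap, pCorr = pc, sigMask = sig,
      nPermutations = as.integer(nP), alpha = alpha,
      exhaustive = sm$exhaustive)
}

#' Map significant directional reversals between conditions
#'
#' Separates the x, y and z components of the per-subject mean direction
#' maps into positive and negative parts and tests each part separately with
#' the paired permutation test. A voxel is flagged as reversed when, for
#' some component, the positive part significantly decreases while the
#' negative part significantly increases between conditions (or vice versa);
#' the component maps are combined by union (optionally intersection).
#'
#' @param dirA,dirB 5D arrays `[x, y, z, 3, subject]` of per-subject mean
#'   directions (NA treated as zero contribution).
#' @param nPerm,alpha,seed as in [pairedPermutationTest()].
#' @param useTfce enhance with TFCE (default FALSE: component parts are
#'   short-range, voxelwise max-statistic is the cheaper default here).
#' @param combine `"union"` (default) or `"intersection"` over components.
#' @param mask optional logical 3D mask.
#' @return A [ReversalMap-class].
#' @export
directionalReversalMap <- function(dirA, dirB, nPerm = 1000L, alpha = 0.05,
                                   seed = 1L, useTfce = FALSE,
                                   combine = c("union", "intersection"),
                                   mask = NULL) {
  combine <- match.arg(combine)
  dA <- dim(dirA)
  if (length(dA) != 5L || dA[4L] != 3L || !identical(dA, dim(dirB)))
    stop("dirA and dirB must be matching 5D arrays [x, y, z, 3, subject]")
  dirA[is.na(dirA)] <- 0
  dirB[is.na(dirB)] <- 0
  comp <- vector("list", 3L)
  names(comp) <- c("x", "y", "z")
  for (c in 1:3) {
    a <- array(dirA[, , , c, ], dA[c(1:3, 5)])
    b <- array(dirB[, , , c, ], dA[c(1:3, 5)])
    aPos <- pmax(a, 0); aNeg <- pmax(-a, 0)
    bPos <- pmax(b, 0); bNeg <- pmax(-b, 0)
    posDec <- pairedPermutationTest(aPos, bPos, nPerm, alpha, useTfce,
                                    seed + c, alternative = "greater",
                                    mask = mask)@sigMask
    negInc <- pairedPermutationTest(aNeg, bNeg, nPerm, alpha, useTfce,
                                    seed + c + 10L, alternative = "less",
                                    mask = mask)@sigMask
    posInc <- pairedPermutationTest(aPos, bPos, nPerm, alpha, useTfce,
                                    seed + c + 20L, alternative = "less",
                                    mask = mask)@sigMask
    negDec <- pairedPermutationTest(aNeg, bNeg, nPerm, alpha, useTfce,
                                    seed + c + 30L, alternative = "greater",
                                    mask = mask)@sigMask
    comp[[c]] <- (posDec & negInc) | (posInc & negDec)
  }
  rev <- if (combine == "union") comp$x | comp$y | comp$z
    else comp$x & comp$y & comp$z
  new("ReversalMap", reversal = rev, componentMaps = comp, combine = combine)
}

#' Spatial Pearson correlation of two maps
#'
#' Correlation over in-mask voxels, e.g. between a band power map and the
#' corresponding mean velocity-magnitude map.
#'
#' @param mapA,mapB 3D arrays of identical shape.
#' @param mask optional logical 3D array (default: all finite voxels).
#' @return Pearson r.
#' @export
spatialCorrelation <- function(mapA, mapB, mask = NULL) {
  if (!identical(dim(mapA), dim(mapB)))
    stop("maps must share the same shape")
  if (is.null(mask)) mask <- array(TRUE, dim(mapA))
  a <- mapA[mask]; b <- mapB[mask]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 in-mask voxels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero-variance map")
  stats::cor(a, b)
}

#' Log band power vs log slow-delta power with Chebyshev outlier exclusion
#'
#' Correlates per-subject log band power sums against log slow-delta power
#' sums after removing outliers beyond `sigmaThreshold` standard deviations
#' from the mean in either coordinate (the stringent four-sigma acceptance
#' threshold per Chebyshev's theorem).
#'
#' @param logBandPower per-subject log band power.
#' @param logDeltaPower per-subject log slow-delta power.
#' @param sigmaThreshold exclusion threshold in SDs (default 4).
#' @return List with `r`, `slope`, `excluded` (subject indices) and `nUsed`.
#' @export
powerDeltaRegression <- function(logBandPower, logDeltaPower,
                                 sigmaThreshold = 4) {
  n <- length(logBandPower)
  if (n != length(logDeltaPower)) stop("inputs must have equal length")
  if (n < 4L) stop("need at least 4 subjects")
  zx <- (logDeltaPower - mean(logDeltaPower)) /
    max(stats::sd(logDeltaPower), 1e-300)
  zy <- (logBandPower - mean(logBandPower)) /
    max(stats::sd(logBandPower), 1e-300)
  excluded <- which(abs(zx) > sigmaThreshold | abs(zy) > sigmaThreshold)
  keep <- setdiff(seq_len(n), excluded)
  if (length(keep) < 3L) stop("too few subjects after outlier exclusion")
  x <- logDeltaPower[keep]; y <- logBandPower[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined after exclusion")
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(stats::lm(y ~ x))[2L]),
       excluded = excluded, nUsed = length(keep))
}
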