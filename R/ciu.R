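#' Assemble a collision-induced unfolding fingerprint
#'
#' Stacks voltage-stepped CCS profiles into a (voltage x CCS) matrix and
#' normalizes each voltage row to maximum 1, the convention of CIU heat
#' maps. Profiles on differing axes are resampled onto the first profile's
#' axis by linear interpolation (zero outside their range). Raw per-voltage
#' intensity totals are preserved in the metadata.
#'
#' @param series list of `list(voltage =, profile =)` pairs as produced by
#'   [genCIUSeries()] or [readCIUSeries()]; at least 3 voltages, strictly
#'   increasing.
#' @return a [CIUFingerprint-class].
#' @export
#' @examples
#' sp <- CIUSeriesSpec(states = data.frame(mean = c(22, 27, 32),
#'                                         fwhm = c(1.5, 2, 2.5)),
#'                     transitions = data.frame(midpoint = c(22, 28),
#'                                              steepness = c(1, 1)))
#' fp <- buildFingerprint(genCIUSeries(sp))
buildFingerprint <- function(series) {
  if (length(series) < 3) stop("need at least 3 voltages")
  v <- vapply(series, function(e) e$voltage, numeric(1))
  if (any(diff(v) <= 0)) stop("voltages must be strictly increasing")
  axis <- ccsAxis(series[[1]]$profile)
  m <- matrix(0, length(series), length(axis))
  rawTotals <- numeric(length(series))
  for (i in seq_along(series)) {
    p <- series[[i]]$profile
    y <- if (isTRUE(all.equal(ccsAxis(p), axis))) intensity(p)
    else {
      yy <- stats::approx(ccsAxis(p), intensity(p), xout = axis,
                          rule = 1)$y
      yy[is.na(yy)] <- 0
      yy
    }
    rawTotals[i] <- sum(y)
    if (max(y) == 0)
      stop("all-zero profile at voltage ", v[i], " V")
    m[i, ] <- y / max(y)
  }
  new("CIUFingerprint", voltages = v, ccsAxis = axis, matrix = m,
      metadata = list(rawTotals = rawTotals))
}

# local maxima of one normalized row above an absolute floor
.rowMaxima <- function(y, floor) {
  n <- length(y)
  idx <- which(y >= floor &
               y > c(-Inf, y[-n]) &
               y >= c(y[-1], -Inf))
  idx
}

# light Gaussian smoothing used for peak *detection* only (raw intensities
# are kept for everything else); suppresses noise maxima in the saddle
# between overlapping peaks
.smoothRow <- function(y, sdPts = 2) {
  half <- max(1L, as.integer(ceiling(3 * sdPts)))
  kern <- stats::dnorm(seq(-half, half), sd = sdPts)
  kern <- kern / sum(kern)
  padded <- c(rep(y[1], half), y, rep(y[length(y)], half))
  as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_along(y)]
}

# FWHM of the peak at index idx in row y (grid units -> ccs units)
.localFWHM <- function(axis, y, idx) {
  half <- y[idx] / 2
  iR <- idx; while (iR < length(y) && y[iR] > half) iR <- iR + 1
  iL <- idx; while (iL > 1 && y[iL] > half) iL <- iL - 1
  max((axis[iR] - axis[iL]), 2 * (axis[2] - axis[1]))
}

#' Detect stable and intermediate CIU features
#'
#' Tracks per-voltage local maxima (above `occupancyFloor` of the row
#' maximum) across consecutive voltages: a maximum extends the nearest
#' active track within `mergeTol` nm^2, otherwise founds a new track.
#' Tracks persisting for fewer than `minPersistence` voltage steps are
#' discarded; surviving tracks with overlapping voltage spans and centers
#' within `mergeTol` are merged. Typical CIU landscapes yield the initial
#' conformers, one or two partially unfolded intermediates, and a final
#' unfolded family.
#'
#' @param fp a [CIUFingerprint-class].
#' @param minPersistence minimum track length in voltage steps (default 2).
#' @param mergeTol linking/merging tolerance in nm^2 (default 1.0).
#' @param occupancyFloor minimum normalized intensity for a maximum to be
#'   tracked (default 0.2; suppresses noise maxima at ~1% noise).
#' @return data.frame with one row per feature: `center`, `width`
#'   (FWHM at the feature's strongest voltage), `vStart`, `vEnd`,
#'   `meanOccupancy` (see [featureOccupancy()]).
#' @export
detectFeatures <- function(fp, minPersistence = 2L, mergeTol = 1.0,
                           occupancyFloor = 0.2) {
  stopifnot(is(fp, "CIUFingerprint"))
  axis <- fp@ccsAxis; v <- fp@voltages; m <- fp@matrix
  sdPts <- max(2, round(0.1 / (axis[2] - axis[1]))) # ~0.1 nm^2 kernel
  tracks <- list()   # each: list(centers, ints, vis, active)
  for (vi in seq_along(v)) {
    idx <- .rowMaxima(.smoothRow(m[vi, ], sdPts), occupancyFloor)
    cand <- axis[idx]
    used <- rep(FALSE, length(cand))
    for (ti in seq_along(tracks)) {
      tr <- tracks[[ti]]
      if (!tr$active) next
      if (length(cand)) {
        d <- abs(cand - tr$centers[length(tr$centers)])
        j <- which.min(ifelse(used, Inf, d))
        if (length(j) && !used[j] && d[j] <= mergeTol) {
          tr$centers <- c(tr$centers, cand[j])
          tr$ints <- c(tr$ints, m[vi, idx[j]])
          tr$vis <- c(tr$vis, vi)
          used[j] <- TRUE
          tracks[[ti]] <- tr
          next
        }
      }
      tracks[[ti]]$active <- FALSE
    }
    for (j in which(!used))
      tracks[[length(tracks) + 1]] <- list(centers = cand[j],
                                           ints = m[vi, idx[j]],
                                           vis = vi, active = TRUE)
  }
  tracks <- Filter(function(tr) length(tr$vis) >= minPersistence, tracks)
  if (!length(tracks))
    return(data.frame(center = numeric(0), width = numeric(0),
                      vStart = numeric(0), vEnd = numeric(0),
                      meanOccupancy = numeric(0)))
  # merge overlapping tracks with close centers
  repeat {
    mergedAny <- FALSE
    for (a in seq_along(tracks)) {
      for (b in seq_along(tracks)) {
        if (b <= a) next
        ta <- tracks[[a]]; tb <- tracks[[b]]
        ca <- stats::weighted.mean(ta$centers, ta$ints)
        cb <- stats::weighted.mean(tb$centers, tb$ints)
        overlap <- max(ta$vis) >= min(tb$vis) && max(tb$vis) >= min(ta$vis)
        if (abs(ca - cb) <= mergeTol && overlap) {
          o <- order(c(ta$vis, tb$vis))
          tracks[[a]] <- list(centers = c(ta$centers, tb$centers)[o],
                              ints = c(ta$ints, tb$ints)[o],
                              vis = c(ta$vis, tb$vis)[o], active = FALSE)
          tracks[[b]] <- NULL
          mergedAny <- TRUE
          break
        }
      }
      if (mergedAny) break
    }
    if (!mergedAny) break
  }
  feats <- do.call(rbind, lapply(tracks, function(tr) {
    center <- stats::weighted.mean(tr$centers, tr$ints)
    strongest <- tr$vis[which.max(tr$ints)]
    idx <- which.min(abs(axis - tr$centers[which.max(tr$ints)]))
    data.frame(center = center,
               width = .localFWHM(axis, m[strongest, ], idx),
               vStart = v[min(tr$vis)], vEnd = v[max(tr$vis)])
  }))
  feats <- feats[order(feats$center), , drop = FALSE]
  rownames(feats) <- NULL
  occ <- featureOccupancy(fp, feats)
  feats$meanOccupancy <- vapply(seq_len(nrow(feats)), function(f) {
    span <- fp@voltages >= feats$vStart[f] & fp@voltages <= feats$vEnd[f]
    mean(occ[span, f])
  }, numeric(1))
  feats
}

#' Per-voltage occupancy of CIU features
#'
#' Occupancy of a feature at a voltage is the normalized intensity
#' integrated within one FWHM of the feature center, renormalized across
#' the supplied features so occupancies sum to 1 at every voltage. This
#' definition makes the CIU50 transition voltage well-posed.
#'
#' @param fp a [CIUFingerprint-class].
#' @param features data.frame with columns `center` and `width` (rows of
#'   [detectFeatures()] output).
#' @return matrix, rows = voltages, columns = features.
#' @export
featureOccupancy <- function(fp, features) {
  axis <- fp@ccsAxis; m <- fp@matrix
  raw <- vapply(seq_len(nrow(features)), function(f) {
    win <- abs(axis - features$center[f]) <= features$width[f]
    rowSums(m[, win, drop = FALSE])
  }, numeric(nrow(m)))
  raw <- matrix(raw, nrow = nrow(m))
  tot <- rowSums(raw)
  tot[tot == 0] <- 1
  raw / tot
}

#' CIU50: transition voltage between two CIU features
#'
#' Fits a logistic curve to the occupancy of the destination feature versus
#' collision voltage (occupancies renormalized across the two features) and
#' returns the fitted midpoint — the voltage at which half the population
#' has crossed into the destination feature. When the logistic fit does not
#' converge the linearly interpolated 50% crossing is returned instead.
#' The fitting window runs up to the voltage of maximum destination
#' occupancy, so later transitions that drain the destination feature do
#' not bias the midpoint.
#'
#' @param fp a [CIUFingerprint-class].
#' @param featureFrom,featureTo single rows of [detectFeatures()] output
#'   (source and destination feature); their voltage spans must be ordered.
#' @return the transition midpoint voltage (V).
#' @export
ciu50 <- function(fp, featureFrom, featureTo) {
  stopifnot(is(fp, "CIUFingerprint"))
  if (featureTo$vStart < featureFrom$vStart ||
      featureTo$vEnd < featureFrom$vEnd)
    stop("feature voltage spans must be ordered (from before to)")
  occ <- featureOccupancy(fp, rbind(featureFrom, featureTo))
  v <- fp@voltages
  o <- occ[, 2]
  iMax <- which.max(o)
  vWin <- v[seq_len(iMax)]
  oWin <- o[seq_len(iMax)]
  if (max(oWin) < 0.5)
    stop("transition incomplete in voltage window")
  # linear 50% crossing as starting value / fallback
  iAbove <- which(oWin >= 0.5)[1]
  v50lin <- if (iAbove == 1) vWin[1]
  else stats::approx(oWin[(iAbove - 1):iAbove], vWin[(iAbove - 1):iAbove],
                     xout = 0.5, ties = "ordered")$y
  fit <- tryCatch(minpack.lm::nls.lm(
    par = c(v0 = v50lin, k = 1),
    fn = function(p) oWin - stats::plogis(p["k"] * (vWin - p["v0"])),
    lower = c(min(v) - 20, 1e-3), upper = c(max(v) + 20, 1e3),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(unname(v50lin))
  unname(fit$par["v0"])
}

#' Root-mean-square difference between two CIU fingerprints
#'
#' Resamples both fingerprints onto their common voltage set and
#' overlapping CCS range (linear interpolation onto the first fingerprint's
#' grid), then returns the root mean square of element-wise differences of
#' the normalized matrices, times 100. Symmetric; zero iff the fingerprints
#' agree on the common grid.
#'
#' @param fpA,fpB [CIUFingerprint-class] objects with overlapping voltage
#'   ranges.
#' @return percentage RMSD.
#' @export
fingerprintRMSD <- function(fpA, fpB) {
  v <- intersect(fpA@voltages, fpB@voltages)
  if (!length(v)) stop("fingerprints have disjoint voltage ranges")
  lo <- max(min(fpA@ccsAxis), min(fpB@ccsAxis))
  hi <- min(max(fpA@ccsAxis), max(fpB@ccsAxis))
  if (hi <= lo) stop("fingerprints have disjoint CCS ranges")
  grid <- fpA@ccsAxis[fpA@ccsAxis >= lo & fpA@ccsAxis <= hi]
  resample <- function(fp) {
    rows <- match(v, fp@voltages)
    t(vapply(rows, function(r)
      stats::approx(fp@ccsAxis, fp@matrix[r, ], xout = grid,
                    rule = 2)$y, numeric(length(grid))))
  }
  a <- resample(fpA); b <- resample(fpB)
  sqrt(mean((a - b)^2)) * 100
}
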