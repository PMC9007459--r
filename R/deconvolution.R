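.gaussSum <- function(axis, p) {
  # p = c(mean1, sd1, area1, mean2, ...)
  k <- length(p) / 3
  y <- numeric(length(axis))
  for (m in seq_len(k)) {
    mu <- p[3 * m - 2]; s <- p[3 * m - 1]; a <- p[3 * m]
    y <- y + a * stats::dnorm(axis, mu, s)
  }
  y
}

# sequential peak picking: largest peak first, then maxima of the clamped
# residual; ties resolve to the lowest CCS (which.max takes the first index)
.pickInits <- function(axis, y, k) {
  step <- axis[2] - axis[1]
  r <- y
  out <- matrix(0, k, 3)
  for (m in seq_len(k)) {
    idx <- which.max(r)
    mu <- axis[idx]; pk <- r[idx]
    if (pk <= 0) { # residual exhausted; seed a broad low component
      mu <- stats::weighted.mean(axis, y + max(y) * 1e-6)
      pk <- max(y) / 20
      idx <- which.min(abs(axis - mu))
    }
    half <- pk / 2
    iR <- idx; while (iR < length(r) && r[iR] > half) iR <- iR + 1
    iL <- idx; while (iL > 1 && r[iL] > half) iL <- iL - 1
    s0 <- max(.fwhm2sd((iR - iL) * step), step)
    a0 <- pk * s0 * sqrt(2 * pi)
    r <- pmax(0, r - a0 * stats::dnorm(axis, mu, s0))
    out[m, ] <- c(mu, s0, a0)
  }
  out
}

#' Fit a sum of Gaussian conformers to a CCS profile
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nls.lm]) of a
#' sum of `k` Gaussians against the intensity trace. Initialization follows
#' the peak-assignment procedure used when fitting experimental profiles:
#' the most abundant peak is assigned first, further components at the
#' maxima of the running residual. Components are returned sorted by mean
#' CCS and labelled I, II, ... from most compact to most extended; widths
#' are reported as FWHM (the CCS distribution width, CCSD).
#'
#' When two fitted means fall closer than a quarter of the narrowest fitted
#' FWHM the fit is flagged `crowded` (likely over-fitting) with a warning.
#'
#' @param profile a [CCSProfile-class] (>= 10 k grid points).
#' @param k number of components (1-6), or `"auto"` to call
#'   [selectComponentCount()].
#' @param init optional k x 3 matrix of `(mean, sd, area)` starting values.
#' @param maxRestarts bounded jittered restarts on non-convergence.
#' @return a [ConformerFit-class].
#' @export
#' @examples
#' sp <- MixtureSpec(data.frame(mean = c(21.9, 23.2, 25.2),
#'                              fwhm = c(1.4, 1.7, 2.2),
#'                              fraction = c(0.25, 0.55, 0.20)),
#'                   noiseSD = 0.01, seed = 11)
#' fit <- fitConformers(averageProfiles(genMixtureProfile(sp)), k = 3)
#' components(fit)
fitConformers <- function(profile, k, init = NULL, maxRestarts = 5L) {
  stopifnot(is(profile, "CCSProfile"))
  axis <- ccsAxis(profile); y <- intensity(profile)
  if (identical(k, "auto")) k <- selectComponentCount(profile)
  k <- as.integer(k)
  if (k < 1 || k > 6) stop("k must be in 1..6")
  if (length(axis) < 10 * k)
    stop("profile needs at least 10 grid points per component")
  step <- axis[2] - axis[1]
  if (is.null(init)) init <- .pickInits(axis, y, k)
  init <- matrix(as.numeric(init), ncol = 3)

  lower <- as.numeric(t(matrix(c(rep(min(axis), k), rep(step / 2, k),
                                 rep(0, k)), ncol = 3)))
  upper <- as.numeric(t(matrix(c(rep(max(axis), k),
                                 rep(diff(range(axis)), k),
                                 rep(sum(y) * step * 10 + max(y), k)),
                               ncol = 3)))
  residFun <- function(p) y - .gaussSum(axis, p)

  best <- NULL
  set.seed(k * 1000L + length(axis))
  for (attempt in seq_len(maxRestarts)) {
    p0 <- as.numeric(t(init))
    if (attempt > 1) {
      jit <- stats::rnorm(length(p0), 0, 0.05)
      p0 <- pmin(pmax(p0 * (1 + jit), lower + 1e-9), upper - 1e-9)
    }
    res <- tryCatch(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper, fn = residFun,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
    if (res$info %in% 1:4) break
  }
  if (is.null(best))
    stop("conformer fit failed to converge after bounded restarts")
  if (!best$info %in% 1:4) {
    cond <- simpleError("conformer fit did not converge; best-so-far fit attached")
    cond$fit <- best
    stop(cond)
  }

  p <- best$par
  comp <- data.frame(mean = p[seq(1, 3 * k, 3)], sd = p[seq(2, 3 * k, 3)],
                     area = p[seq(3, 3 * k, 3)])
  comp <- comp[order(comp$mean), ]
  frac <- comp$area / sum(comp$area) * 100
  fitted <- .gaussSum(axis, as.numeric(t(as.matrix(comp))))
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  fwhm <- .sd2fwhm(comp$sd)
  crowded <- k > 1 && any(diff(comp$mean) < 0.25 * min(fwhm))
  if (crowded)
    warning("two component means closer than 0.25 * min(FWHM); ",
            "k may exceed the number of resolvable peaks")
  new("ConformerFit",
      components = data.frame(label = as.character(utils::as.roman(1:k)),
                              ccs = comp$mean, ccsd = fwhm,
                              area = comp$area, fraction = frac,
                              stringsAsFactors = FALSE),
      rSquared = r2, residuals = y - fitted, axis = axis,
      crowded = crowded)
}

#' Choose the number of Gaussian conformers
#'
#' Fits k = 1, 2, ... components in turn and returns the smallest k for
#' which adding one more component improves R^2 by less than `deltaR2`
#' (default 0.005), capped at `kMax`. This automates the manual
#' peak-addition protocol (assign the dominant conformer, add further
#' conformers only where they clearly improve the fit).
#'
#' @param profile a [CCSProfile-class].
#' @param kMax maximum components to consider (default 4, conformers I-IV).
#' @param deltaR2 minimum R^2 improvement that justifies a component.
#' @return integer k >= 1.
#' @export
selectComponentCount <- function(profile, kMax = 4L, deltaR2 = 0.005) {
  r2 <- rep(NA_real_, kMax)
  for (k in seq_len(kMax)) {
    f <- tryCatch(suppressWarnings(fitConformers(profile, k)),
                  error = function(e) NULL)
    r2[k] <- if (is.null(f)) -Inf else rSquared(f)
    if (k > 1 && r2[k] - r2[k - 1] < deltaR2) return(k - 1L)
  }
  as.integer(kMax)
}

#' Intensity-weighted mean CCS of a profile
#'
#' @param profile a [CCSProfile-class] with positive total intensity.
#' @return weighted average CCS, nm^2.
#' @export
weightedMeanCCS <- function(profile) {
  y <- intensity(profile)
  if (sum(y) <= 0) stop("profile has zero total intensity")
  stats::weighted.mean(ccsAxis(profile), y)
}

#' Percentage area per fitted conformer
#'
#' @param fit a [ConformerFit-class].
#' @return named numeric vector of percentages (sums to 100), ordered and
#'   named by conformer label (I = most compact).
#' @export
areaFractions <- function(fit) {
  stopifnot(is(fit, "ConformerFit"))
  stats::setNames(components(fit)$fraction, components(fit)$label)
}

#' Compare two fitted conformational landscapes
#'
#' Greedy nearest-mean matching of components between two fits: the closest
#' pair (by |delta mean CCS|) is matched first, provided the distance is
#' within `matchTol` (by default 3% of the pair's mean CCS, the variance
#' generally observed between replicate native IM-MS experiments), and so
#' on. Matched pairs report delta CCS, delta CCSD and delta area fraction
#' (B minus A); unmatched components are reported as lost (only in A) or
#' gained (only in B).
#'
#' @param fitA,fitB [ConformerFit-class] objects.
#' @param matchTol absolute matching tolerance in nm^2, or `NULL` for the
#'   3%-of-mean default.
#' @return a [LandscapeDelta-class].
#' @export
compareLandscapes <- function(fitA, fitB, matchTol = NULL) {
  ca <- components(fitA); cb <- components(fitB)
  pairs <- expand.grid(ia = seq_len(nrow(ca)), ib = seq_len(nrow(cb)))
  pairs$d <- abs(ca$ccs[pairs$ia] - cb$ccs[pairs$ib])
  pairs$tol <- if (is.null(matchTol))
    0.03 * (ca$ccs[pairs$ia] + cb$ccs[pairs$ib]) / 2 else matchTol
  pairs <- pairs[order(pairs$d), ]
  usedA <- usedB <- integer(0)
  matched <- data.frame()
  for (r in seq_len(nrow(pairs))) {
    ia <- pairs$ia[r]; ib <- pairs$ib[r]
    if (ia %in% usedA || ib %in% usedB || pairs$d[r] > pairs$tol[r]) next
    matched <- rbind(matched, data.frame(
      labelA = ca$label[ia], labelB = cb$label[ib],
      ccsA = ca$ccs[ia], ccsB = cb$ccs[ib],
      dCCS = cb$ccs[ib] - ca$ccs[ia],
      dCCSD = cb$ccsd[ib] - ca$ccsd[ia],
      dFraction = cb$fraction[ib] - ca$fraction[ia],
      stringsAsFactors = FALSE))
    usedA <- c(usedA, ia); usedB <- c(usedB, ib)
  }
  new("LandscapeDelta",
      matched = matched,
      lost = ca[setdiff(seq_len(nrow(ca)), usedA), , drop = FALSE],
      gained = cb[setdiff(seq_len(nrow(cb)), usedB), , drop = FALSE],
      tol = if (is.null(matchTol)) NA_real_ else matchTol)
}
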