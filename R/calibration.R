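#' Correct a traveling-wave drift time for the EDC delay
#'
#' Removes the mass-dependent enhanced-duty-cycle (EDC) delay from a measured
#' arrival time: `td' = td - edc * sqrt(m/z) / 1000` (td in ms, m/z in Th).
#'
#' @param td measured drift time, ms (> 0).
#' @param mz mass-to-charge ratio, Th.
#' @param edc EDC delay coefficient (instrument constant, default 1.41).
#' @return corrected drift time td', ms.
#' @export
#' @examples
#' correctDriftTime(10, 2500, 1.41)  # 9.9295
correctDriftTime <- function(td, mz, edc = 1.41) {
  if (any(td <= 0)) stop("drift times must be > 0")
  tdPrime <- td - edc * sqrt(mz) / 1000
  if (any(tdPrime <= 0))
    stop("corrected drift time <= 0; EDC coefficient invalid for this ion")
  tdPrime
}

#' Charge and reduced-mass scaling of a literature CCS
#'
#' Scales a literature CCS onto the calibration axis:
#' `ccs' = ccs / (z * sqrt(1/mu))` with reduced mass
#' `mu = m * m_gas / (m + m_gas)` (Da). Used to fit and apply the
#' traveling-wave power-law calibration.
#'
#' @param litCCS literature CCS, nm^2.
#' @param z charge state.
#' @param mass ion mass, Da.
#' @param gasMass drift-gas mass, Da (default nitrogen, 28.0134).
#' @return scaled CCS (arbitrary calibration units).
#' @export
reducedMassCorrection <- function(litCCS, z, mass, gasMass = 28.0134) {
  if (any(mass <= 0) || any(gasMass <= 0)) stop("masses must be positive")
  if (any(z < 1)) stop("charge must be >= 1")
  mu <- mass * gasMass / (mass + gasMass)
  litCCS / (z * sqrt(1 / mu))
}

#' Fit the traveling-wave CCS calibration power law
#'
#' Least-squares line on `(ln td', ln ccs')` over the calibrant ions, giving
#' `ccs' = A * td'^B` with `A = exp(intercept)`, `B = slope`. Drift times are
#' EDC-corrected with [correctDriftTime()] and literature CCS values scaled
#' with [reducedMassCorrection()] before fitting.
#'
#' @param calibrants data.frame with columns `name`, `mass_da`, `charge`,
#'   `mz` (optional; computed from mass and charge if absent),
#'   `drift_time_ms`, `lit_ccs_nm2`. At least 3 ions spanning a 1.5-fold
#'   range in corrected drift time.
#' @param edc EDC delay coefficient.
#' @param gasMass drift-gas mass, Da.
#' @param gas drift-gas label stored with the model.
#' @return a [CalibrationModel-class].
#' @export
#' @examples
#' tab <- data.frame(name = c("a","b","c","d"), mass_da = c(12e3, 18e3, 34e3, 66e3),
#'                   charge = c(7, 8, 11, 15), lit_ccs_nm2 = c(17, 20, 30, 41))
#' cal <- genCalibrants(2, 0.55, tab, noiseSD = 0)
#' fitCalibration(cal)
fitCalibration <- function(calibrants, edc = 1.41, gasMass = 28.0134,
                           gas = "N2") {
  cb <- as.data.frame(calibrants)
  if (nrow(cb) < 3)
    stop("need at least 3 calibrant points")
  if (is.null(cb$mz))
    cb$mz <- (cb$mass_da + cb$charge * 1.007276) / cb$charge
  tdP <- correctDriftTime(cb$drift_time_ms, cb$mz, edc)
  ccsP <- reducedMassCorrection(cb$lit_ccs_nm2, cb$charge, cb$mass_da,
                                gasMass)
  if (stats::sd(log(tdP)) < 1e-12)
    stop("degenerate design: corrected drift times are all equal")
  if (max(tdP) / min(tdP) < 1.5)
    warning("calibrant drift times span less than a 1.5-fold range")
  fit <- stats::lm(log(ccsP) ~ log(tdP))
  r2 <- summary(fit)$r.squared
  B <- unname(stats::coef(fit)[2])
  if (!is.finite(B) || B <= 0 || B >= 2)
    stop("degenerate calibrant design: fitted exponent ",
         format(B), " outside (0, 2)")
  new("CalibrationModel",
      A = exp(unname(stats::coef(fit)[1])),
      B = B,
      edc = edc, gasMass = gasMass, gas = gas, r2 = r2,
      residuals = data.frame(name = cb$name,
                             ln_residual = unname(stats::residuals(fit))))
}

#' Convert a measured drift time to a calibrated CCS
#'
#' Applies a fitted [CalibrationModel-class]:
#' `ccs = A * td'^B * z * sqrt(1/mu)` — the inverse of the scaling used when
#' fitting, returning the CCS in nm^2 (the "N2 -> He" frame when the
#' calibration used helium-frame literature values with nitrogen drift gas).
#'
#' @param model a [CalibrationModel-class].
#' @param td measured drift time(s), ms.
#' @param mz mass-to-charge ratio, Th.
#' @param z charge state.
#' @param mass ion mass, Da.
#' @return calibrated CCS, nm^2 (vectorized over `td`).
#' @export
applyCalibration <- function(model, td, mz, z, mass) {
  stopifnot(is(model, "CalibrationModel"))
  tdP <- correctDriftTime(td, mz, model@edc)
  mu <- mass * model@gasMass / (mass + model@gasMass)
  model@A * tdP^model@B * z * sqrt(1 / mu)
}

#' Calibrate an arrival-time profile onto a uniform CCS axis
#'
#' Maps each arrival-time grid point through [applyCalibration()], then
#' resamples the (now non-uniform) CCS axis onto a uniform grid by linear
#' interpolation so downstream deconvolution sees a valid
#' [CCSProfile-class].
#'
#' @param model a [CalibrationModel-class].
#' @param driftTimes arrival-time grid, ms (strictly increasing).
#' @param intensities intensity per grid point.
#' @param mz,z,mass ion descriptors as in [applyCalibration()].
#' @param step uniform CCS grid step, nm^2.
#' @param metadata optional list stored with the profile.
#' @return a [CCSProfile-class].
#' @export
calibrateProfile <- function(model, driftTimes, intensities, mz, z, mass,
                             step = 0.05, metadata = list()) {
  stopifnot(length(driftTimes) == length(intensities))
  ccs <- applyCalibration(model, driftTimes, mz, z, mass)
  grid <- seq(min(ccs), max(ccs), by = step)
  y <- stats::approx(ccs, intensities, xout = grid, rule = 2)$y
  new("CCSProfile", axis = grid, intensity = pmax(0, y),
      charge = as.integer(z), replicateSD = numeric(0),
      metadata = c(metadata, list(calibration = list(A = model@A,
                                                     B = model@B))))
}

#' Read a calibrant table from CSV
#'
#' Expected header: `name,mass_da,charge,mz,drift_time_ms,lit_ccs_nm2`
#' (`mz` optional). Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return data.frame of calibrants.
#' @export
readCalibrants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Persist / restore a calibration model as JSON
#'
#' @param model a [CalibrationModel-class].
#' @param path output / input JSON path.
#' @return `writeCalibrationModel` returns `path` invisibly;
#'   `readCalibrationModel` returns a [CalibrationModel-class].
#' @export
writeCalibrationModel <- function(model, path) {
  jsonlite::write_json(list(A = model@A, B = model@B, edc = model@edc,
                            gas_mass = model@gasMass, gas = model@gas,
                            r2 = model@r2),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationModel
#' @export
readCalibrationModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationModel", A = j$A, B = j$B, edc = j$edc,
      gasMass = j$gas_mass, gas = j$gas, r2 = j$r2,
      residuals = data.frame())
}
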