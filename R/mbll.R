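#' Molar extinction coefficients of hemoglobin at the acquisition wavelengths
#'
#' Literature-typical extinction coefficients of oxy- and deoxy-hemoglobin
#' (values after the Prahl/Cope compilation used throughout continuous-wave
#' NIRS, converted to uM^-1 cm^-1) at 730 and 850 nm. Rows are wavelengths,
#' columns chromophores.
#'
#' @param wavelengths_nm Two wavelengths; only 730 and 850 nm are tabulated.
#' @return 2x2 matrix with dimnames `("730","850") x ("HbO","HbR")`.
#' @export
extinction_coefficients <- function(wavelengths_nm = c(730, 850)) {
  tab <- matrix(c(0.390, 1.102,    # 730 nm: HbO, HbR  (mM^-1 cm^-1)
                  1.058, 0.691),   # 850 nm
                nrow = 2, byrow = TRUE,
                dimnames = list(c("730", "850"), c("HbO", "HbR")))
  key <- as.character(wavelengths_nm)
  if (!all(key %in% rownames(tab))) {
    abort("Extinction coefficients are tabulated for 730 and 850 nm only.")
  }
  tab[key, , drop = FALSE] / 1000   # -> uM^-1 cm^-1
}

#' Age- and wavelength-dependent differential pathlength factor
#'
#' General DPF formula of Scholkmann & Wolf (2013, J Biomed Opt 18:105004):
#' `DPF = 223.3 + 0.05624 * age^0.8493 - 5.723e-7 * l^3 + 0.001245 * l^2
#'  - 0.9025 * l`, with age in years and wavelength `l` in nm.
#'
#' @param wavelengths_nm Wavelength(s) in nm.
#' @param age_years Participant age in years.
#' @return Numeric DPF per wavelength.
#' @export
dpf_for_age <- function(wavelengths_nm = c(730, 850), age_years = 5.2) {
  assert_scalar_number(age_years, "age_years", positive = TRUE)
  l <- wavelengths_nm
  223.3 + 0.05624 * age_years^0.8493 -
    5.723e-7 * l^3 + 0.001245 * l^2 - 0.9025 * l
}

check_extinction <- function(extinction) {
  if (!is.matrix(extinction) || any(dim(extinction) != 2L) ||
      !all(is.finite(extinction))) {
    abort("`extinction` must be a finite 2x2 matrix (wavelength x chromophore).")
  }
  if (abs(det(extinction)) < 1e-12) {
    abort("Extinction matrix is singular; chromophores cannot be separated.")
  }
  invisible(extinction)
}

#' Forward modified Beer-Lambert law: hemoglobin to optical density
#'
#' Maps chromophore concentration changes to optical-density changes at the
#' two acquisition wavelengths: `dOD(l) = (eHbO(l) dHbO + eHbR(l) dHbR) * L *
#' DPF(l)` per channel, with `L` the source-detector separation in cm.
#'
#' @param rec A `nirs_recording` with planes `HbO`, `HbR` (uM).
#' @param extinction 2x2 matrix (wavelength x chromophore) in uM^-1 cm^-1.
#' @param dpf Length-2 differential pathlength factors; default from
#'   [dpf_for_age()] at `age_years`.
#' @param separation_cm Source-detector separation (cm); defaults to the
#'   recording's montage.
#' @param age_years Age used when `dpf` is `NULL`.
#' @return A `nirs_recording` with planes `OD730`, `OD850` (unitless).
#' @export
hb_to_optical_density <- function(rec,
                                  extinction = extinction_coefficients(),
                                  dpf = NULL,
                                  separation_cm = NULL,
                                  age_years = 5.2) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (!identical(rec$planes, c("HbO", "HbR"))) {
    abort("`rec` must hold (HbO, HbR) planes.")
  }
  check_extinction(extinction)
  dpf <- dpf %||% dpf_for_age(c(730, 850), age_years)
  separation_cm <- separation_cm %||% rec$montage$separation_cm %||% 3.0
  A <- diag(separation_cm * dpf) %*% extinction   # OD = A %*% c(HbO, HbR)
  od <- rec$data
  od[, , 1] <- A[1, 1] * rec$data[, , 1] + A[1, 2] * rec$data[, , 2]
  od[, , 2] <- A[2, 1] * rec$data[, , 1] + A[2, 2] * rec$data[, , 2]
  out <- rec
  out$data <- od
  out$planes <- c("OD730", "OD850")
  out$stage <- "od"
  out$stages <- c(rec$stages, "hb_to_optical_density")
  out
}

#' Inverse modified Beer-Lambert law: optical density to hemoglobin
#'
#' Solves the per-channel, per-sample 2x2 linear system of the modified
#' Beer-Lambert law for (dHbO, dHbR) given optical-density changes at 730 and
#' 850 nm, using a differential pathlength factor adjusted for participant
#' age.
#'
#' @param od A `nirs_recording` with planes ordered `(OD730, OD850)`.
#' @inheritParams hb_to_optical_density
#' @return A `nirs_recording` with planes `HbO`, `HbR` in uM (given
#'   extinction in uM^-1 cm^-1 and separation in cm).
#' @export
mbll_inverse <- function(od,
                         extinction = extinction_coefficients(),
                         dpf = NULL,
                         separation_cm = NULL,
                         age_years = 5.2) {
  stopifnot(inherits(od, "nirs_recording"))
  if (!identical(od$planes, c("OD730", "OD850"))) {
    abort("`od` must hold (OD730, OD850) planes, in that order.")
  }
  check_extinction(extinction)
  if (anyNA(od$data)) {
    bad <- which(is.na(od$data), arr.ind = TRUE)[1, ]
    abort(sprintf("NaN/NA in optical density at channel %d, sample %d.",
                  bad[1], bad[2]))
  }
  dpf <- dpf %||% dpf_for_age(c(730, 850), age_years)
  separation_cm <- separation_cm %||% od$montage$separation_cm %||% 3.0
  A <- diag(separation_cm * dpf) %*% extinction
  Ainv <- solve(A)
  hb <- od$data
  hb[, , 1] <- Ainv[1, 1] * od$data[, , 1] + Ainv[1, 2] * od$data[, , 2]
  hb[, , 2] <- Ainv[2, 1] * od$data[, , 1] + Ainv[2, 2] * od$data[, , 2]
  out <- od
  out$data <- hb
  out$planes <- c("HbO", "HbR")
  out$stage <- "hb"
  out$stages <- c(od$stages, "mbll_inverse")
  out
}
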