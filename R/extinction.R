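# Optical constants for the two-wavelength modified Beer-Lambert conversion.

# Molar extinction coefficients for oxy-/deoxyhemoglobin, 1/(mM*cm),
# at the two acquisition wavelengths. Values are from the standard compiled
# in-vitro tabulation (Prahl/Cope compilation) rounded to three figures;
# version frozen here so converted concentrations are reproducible.
.EXTINCTION_TABLE <- matrix(
  c(0.350, 2.051,   # 690 nm: HbO2, HbR
    1.058, 0.781),  # 830 nm: HbO2, HbR
  nrow = 2, byrow = TRUE,
  dimnames = list(c("690", "830"), c("HbO2", "HbR")))

#' Hemoglobin extinction coefficients
#'
#' Returns the 2 x 2 molar extinction matrix used by [mbll()] and by the
#' synthetic forward model, in 1/(mM*cm), rows = wavelengths, columns =
#' chromophores (HbO2, HbR).
#'
#' @param wavelengths_nm Two wavelengths; only 690 and 830 nm are tabulated.
#' @return Numeric 2 x 2 matrix with dimnames.
#' @export
extinction_coefficients <- function(wavelengths_nm = c(690, 830)) {
  keys <- as.character(wavelengths_nm)
  missing <- setdiff(keys, rownames(.EXTINCTION_TABLE))
  if (length(missing))
    stop("no tabulated extinction coefficients for ", paste(missing, collapse = ", "), " nm")
  .EXTINCTION_TABLE[keys, , drop = FALSE]
}

#' Default differential pathlength factors
#'
#' Partial pathlength factors applied in the modified Beer-Lambert law:
#' 6.4 at 690 nm and 5.8 at 830 nm.
#'
#' @return Named numeric vector of length 2.
#' @export
default_dpf <- function() c("690" = 6.4, "830" = 5.8)
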