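#' Standardize a urine concentration for urine specific gravity
#'
#' Urine concentrations depend strongly on hydration status. Doping-control
#' practice standardizes them to a reference specific gravity of 1.020 via
#'
#' \deqn{C_{corr} = \frac{1.020 - 1}{(USG + 0.002) - 1} \times C_{obs}}
#'
#' where 0.002 accounts for the uncertainty of the specific-gravity
#' measurement. At USG = 1.018 the factor is exactly 1. The correction is
#' applied whenever a USG value is present, irrespective of whether the
#' sample is dilute or concentrated; rows with missing USG are returned
#' unchanged.
#'
#' @param conc Numeric vector of observed concentrations (ng/mL), >= 0.
#' @param usg Numeric vector of urine specific gravities (dimensionless,
#'   physiologic range roughly 1.000-1.040). `NA` means not measured.
#' @return Numeric vector of standardized concentrations, same length.
#' @examples
#' usg_correct(10, 1.018) # exactly 10
#' usg_correct(10, 1.030) # 6.25, a concentrated sample is scaled down
#' @export
usg_correct <- function(conc, usg) {
  stopifnot(is.numeric(conc), is.numeric(usg))
  if (length(usg) == 1L) usg <- rep(usg, length(conc))
  if (length(conc) != length(usg)) {
    stop("`conc` and `usg` must have the same length", call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  bad <- !is.na(usg) & (usg <= 0.998 | usg >= 1.1)
  if (any(bad)) {
    stop("invalid USG value(s): ", paste(usg[bad], collapse = ", "), call. = FALSE)
  }
  factor <- ifelse(is.na(usg), 1, 0.020 / (usg + 0.002 - 1))
  conc * factor
}

#' Convert an inhaled dose in micrograms to nanomoles
#'
#' @param dose_ug Dose in micrograms (> 0); the label dose of salmeterol base.
#' @param compound Compound name; doses are only given as salmeterol.
#' @return Dose in nmol.
#' @examples
#' dose_to_nmol(100) # ~240.6 nmol
#' @export
dose_to_nmol <- function(dose_ug, compound = "salmeterol") {
  mw <- .mw_of(compound)
  if (any(!is.finite(dose_ug)) || any(dose_ug <= 0)) {
    stop("`dose_ug` must be strictly positive", call. = FALSE)
  }
  dose_ug / mw * 1000
}

#' @rdname dose_to_nmol
#' @param dose_nmol Dose in nmol (inverse mapping).
#' @export
nmol_to_ug <- function(dose_nmol, compound = "salmeterol") {
  dose_nmol * .mw_of(compound) / 1000
}

#' Convert between molar and mass concentration units
#'
#' Internal computations use nmol/L; assay results and reporting use ng/mL.
#'
#' @param conc Concentration, >= 0.
#' @param compound `"salmeterol"` or `"alpha-hydroxysalmeterol"`.
#' @return Converted concentration.
#' @examples
#' conc_to_ng_per_ml(1, "salmeterol") # ~0.4156 ng/mL
#' @export
conc_to_ng_per_ml <- function(conc, compound = "salmeterol") {
  if (any(conc < 0, na.rm = TRUE)) stop("concentration must be >= 0", call. = FALSE)
  conc * .mw_of(compound) / 1000
}

#' @rdname conc_to_ng_per_ml
#' @export
conc_to_nmol_per_l <- function(conc, compound = "salmeterol") {
  if (any(conc < 0, na.rm = TRUE)) stop("concentration must be >= 0", call. = FALSE)
  conc / .mw_of(compound) * 1000
}
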