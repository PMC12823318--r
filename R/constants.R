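#' Molar masses used for unit conversion
#'
#' Salmeterol base (the inhaler label dose refers to the base, not the
#' xinafoate salt) and alpha-hydroxysalmeterol (parent plus one oxygen).
#' All amounts are carried internally in nmol and all concentrations in
#' nmol/L; conversion to assay-native ng/mL happens only at the I/O
#' boundary, through these constants.
#'
#' @format Named numeric vector, g/mol.
#' @export
salm_molar_mass <- c(
  salmeterol = 415.57,
  `alpha-hydroxysalmeterol` = 431.57
)

# internal shorthands
.MW_SALM <- 415.57
.MW_AOH <- 431.57

#' Minimum reporting level for urinary salmeterol
#'
#' Concentration (ng/mL) above which an anti-doping laboratory reports a
#' finding for salmeterol in urine.
#' @export
salm_mrl <- 10

.compounds <- c("salmeterol", "alpha-hydroxysalmeterol")

.mw_of <- function(compound) {
  compound <- match.arg(compound, .compounds)
  unname(salm_molar_mass[[compound]])
}
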