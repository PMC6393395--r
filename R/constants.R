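# Physical constants shared by every module. Single source of truth:
# do not redefine these elsewhere.

#' Physical constants used throughout hairpintools
#'
#' @description
#' * `kB`: Boltzmann constant, 0.0138065 pN nm / K.
#' * `T_default`: default absolute temperature, 298.15 K (25 degrees C).
#' * `R_gas`: molar gas constant, 8.314 J / (mol K).
#' * `nm_per_nt`: contour length of single-stranded DNA per nucleotide,
#'   0.68 nm/nt, used for all contour-length / nucleotide conversions.
#' * `hairpin_closure_nm`: end-to-end distance (nm) between the 5' and 3'
#'   ends of a closed hairpin, subtracted once upon complete unfolding.
#'
#' @format A named list with elements `kB`, `T_default`, `R_gas`,
#'   `nm_per_nt`, `hairpin_closure_nm`.
#' @export
hp_constants <- list(
  kB = 0.0138065,        # pN nm / K
  T_default = 298.15,    # K
  R_gas = 8.314,         # J / (mol K)
  nm_per_nt = 0.68,      # nm per ssDNA nucleotide
  hairpin_closure_nm = 2 # nm, folded-hairpin end-to-end distance
)

# thermal energy in pN nm at temperature T (K)
kBT <- function(temperature = hp_constants$T_default) {
  hp_constants$kB * temperature
}
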