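# Physical constants and default biochemical kinetics.

#' Universal gas constant (J mol-1 K-1)
#' @export
R_GAS <- 8.314

#' Celsius/Kelvin offset
#' @keywords internal
T0_K <- 273.15

#' Default Rubisco and electron-transport kinetics for Nicotiana tabacum
#'
#' Temperature-dependent kinetic constants of C3 photosynthesis at a reference
#' temperature of 25 degC, with Arrhenius activation energies for scaling to
#' other leaf temperatures. Values are the tobacco set of Bernacchi et al.
#' (2001, Plant Cell Environ 24:253-259; 2002, Plant Physiol 130:1992-1998),
#' the de facto standard kinetics for C3 gas-exchange fitting.
#'
#' Units: `Gamma_star` and `K_c` in umol mol-1, `K_o` and `O` in mmol mol-1,
#' activation energies `Ea_*` in J mol-1, temperatures in K.
#'
#' @return A named list with elements `Gamma_star25`, `K_c25`, `K_o25`, `O`,
#'   `Ea_Gamma_star`, `Ea_K_c`, `Ea_K_o`, `Ea_V_cmax`, `Ea_J_max`, `Ea_R_d`,
#'   `T_ref`.
#' @examples
#' tobacco_kinetics()$Gamma_star25
#' @export
tobacco_kinetics <- function() {
  list(
    Gamma_star25 = 42.75, # umol mol-1
    K_c25        = 404.9, # umol mol-1
    K_o25        = 278.4, # mmol mol-1
    O            = 210,   # mmol mol-1, ambient oxygen
    Ea_Gamma_star = 37830, # J mol-1
    Ea_K_c        = 79430,
    Ea_K_o        = 36380,
    Ea_V_cmax     = 65330,
    Ea_J_max      = 43540,
    Ea_R_d        = 46390,
    T_ref         = 298.15
  )
}

#' Scale a kinetic constant from 25 degC to another leaf temperature
#'
#' Applies the Arrhenius scaling `k = k25 * exp(Ea * (T - T_ref) / (T_ref * R * T))`.
#'
#' @param k25 value at 298.15 K
#' @param Ea activation energy (J mol-1)
#' @param T_leaf leaf temperature (K)
#' @param T_ref reference temperature (K)
#' @return scaled value at `T_leaf`
#' @export
arrhenius_scale <- function(k25, Ea, T_leaf, T_ref = 298.15) {
  k25 * exp(Ea * (T_leaf - T_ref) / (T_ref * R_GAS * T_leaf))
}
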