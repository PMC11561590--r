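#' Cryoprotectant formulation presets
#'
#' Named CPA formulations used in skin cryopreservation protocols, all 15 wt%
#' total solute in PBS: single agents (betaine, trehalose, glycerol, DMSO)
#' and betaine/trehalose blends BT-1 (8+7), BT-2 (10+5) and BT-3 (12+3 wt%).
#' `"none"` is plain PBS.
#'
#' Each preset carries the solute weight fractions and molar masses from
#' which the freezing-point depression is computed colligatively
#' (\eqn{\Delta T_f = K_f m + \Delta T_{f,\mathrm{PBS}}}), plus a
#' nonfreezing-water fraction used to scale the latent heat, and the factor
#' applied to the frozen skin's thermal expansion coefficient (the BT blends
#' lower it by 40%).
#'
#' @param name preset name (case-insensitive); see Details
#' @return list describing the formulation
#' @export
cpa_preset <- function(name = "BT-2") {
  key <- toupper(gsub("[ _]", "-", name))
  tab <- list(
    "NONE"      = list(solutes = numeric(0), mw = numeric(0),
                       nonfreezing = 0.00, skin_alpha_factor = 1.0),
    "BETAINE"   = list(solutes = c(betaine = 0.15), mw = c(betaine = 117.15),
                       nonfreezing = 0.27, skin_alpha_factor = 0.75),
    "TREHALOSE" = list(solutes = c(trehalose = 0.15), mw = c(trehalose = 342.30),
                       nonfreezing = 0.15, skin_alpha_factor = 0.85),
    "BT-1"      = list(solutes = c(betaine = 0.08, trehalose = 0.07),
                       mw = c(betaine = 117.15, trehalose = 342.30),
                       nonfreezing = 0.27, skin_alpha_factor = 0.60),
    "BT-2"      = list(solutes = c(betaine = 0.10, trehalose = 0.05),
                       mw = c(betaine = 117.15, trehalose = 342.30),
                       nonfreezing = 0.27, skin_alpha_factor = 0.60),
    "BT-3"      = list(solutes = c(betaine = 0.12, trehalose = 0.03),
                       mw = c(betaine = 117.15, trehalose = 342.30),
                       nonfreezing = 0.27, skin_alpha_factor = 0.60),
    "GLYCEROL"  = list(solutes = c(glycerol = 0.15), mw = c(glycerol = 92.09),
                       nonfreezing = 0.15, skin_alpha_factor = 1.0),
    "GLY"       = NULL,  # alias, filled below
    "DMSO"      = list(solutes = c(dmso = 0.15), mw = c(dmso = 78.13),
                       nonfreezing = 0.15, skin_alpha_factor = 1.0)
  )
  tab[["GLY"]] <- tab[["GLYCEROL"]]
  if (is.null(tab[[key]])) stop("unknown CPA preset: ", name)
  p <- tab[[key]]
  p$name <- key
  # colligative freezing-point depression; PBS background ~0.29 osmol/kg
  wf_water <- 1 - sum(p$solutes)
  molality <- if (length(p$solutes)) sum(p$solutes * 1000 / p$mw) / wf_water else 0
  p$water_mass_fraction <- wf_water
  p$freezing_point_depression <- .KF_WATER * (molality + 0.29)
  p
}

#' Literature-default materials for the cryopreservation scenario
#'
#' Bundled stand-ins for the unavailable instrument-calibrated parameter set:
#' per-phase thermophysical and mechanical constants for the CPA solution
#' (liquid vs. ice-rich frozen mixture) and skin (fresh vs. frozen), with the
#' melt point depressed colligatively by the chosen CPA preset and the latent
#' heat reduced by the preset's nonfreezing-water fraction.  The liquid
#' phases use a soft, fast-relaxing elastic surrogate (small E, small Maxwell
#' viscosity) so fluid cells carry negligible deviatoric stress within the
#' linear-elastic constitutive family.
#'
#' @param cpa CPA preset name passed to [cpa_preset()] (default `"BT-2"`)
#' @return for `solution_material()`/`skin_material()` a
#'   [phase_change_material()]; for `default_materials()` a named list with
#'   elements `solution` and `skin`
#' @export
solution_material <- function(cpa = "BT-2") {
  p <- cpa_preset(cpa)
  wf_w <- p$water_mass_fraction
  # frozen mixture: ice crystals + unfrozen residual brine/solute (~1150 kg/m3)
  w_ice <- wf_w * (1 - p$nonfreezing)
  w_res <- 1 - w_ice
  rho_frozen <- 1 / (w_ice / 917 + w_res / 1150)
  rho_liquid <- 1000 + 320 * sum(p$solutes)   # ~1048 at 15 wt%
  k_frozen <- 2.25 * w_ice + 0.5 * w_res
  frozen <- phase_properties(
    density = rho_frozen, heat_capacity = 2050 + 1800 * w_res,
    conductivity = k_frozen,
    young_modulus = 9e9, poisson = 0.33, expansion = 5.1e-5,
    maxwell_viscosity = 1e13)
  liquid <- phase_properties(
    density = rho_liquid, heat_capacity = 4180 - 2000 * sum(p$solutes),
    conductivity = 0.56,
    young_modulus = 1e5, poisson = 0.45, expansion = 2.0e-4,
    maxwell_viscosity = 1e3)
  phase_change_material(
    frozen, liquid,
    melt_temperature = celsius_to_kelvin(0) - p$freezing_point_depression,
    transition_half_width = 0.5,
    latent_heat = .L_WATER * wf_w * (1 - p$nonfreezing),
    name = paste0("solution[", p$name, "]"))
}

#' @rdname solution_material
#' @export
skin_material <- function(cpa = "BT-2") {
  p <- cpa_preset(cpa)
  wf_w <- 0.70                       # tissue water mass fraction
  frozen <- phase_properties(
    density = 1090, heat_capacity = 2000, conductivity = 1.9,
    young_modulus = 1.0e9, poisson = 0.30,
    expansion = 1.0e-4 * p$skin_alpha_factor,
    maxwell_viscosity = 1e13)
  fresh <- phase_properties(
    density = 1100, heat_capacity = 3500, conductivity = 0.45,
    young_modulus = 5e5, poisson = 0.45, expansion = 1.5e-4,
    maxwell_viscosity = 1e5)
  phase_change_material(
    frozen, fresh,
    # interstitial fluid equilibrated with the loading bath after 2 h at 4 degC
    melt_temperature = celsius_to_kelvin(0) - p$freezing_point_depression,
    transition_half_width = 0.5,
    latent_heat = .L_WATER * wf_w * (1 - max(p$nonfreezing, 0.10)),
    name = paste0("skin[", p$name, "]"))
}

#' @rdname solution_material
#' @export
default_materials <- function(cpa = "BT-2") {
  list(solution = solution_material(cpa), skin = skin_material(cpa))
}
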