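#' Named generator presets encoding the study conditions
#'
#' Read-only parameter bundles for the synthetic generators, encoding the
#' headline quantities of the emulated physiology:
#'
#' * `growth_wt_minimal` — wild type in glucose minimal medium,
#'   lambda = 0.95 /h, OD0 = 0.02, 10-min sampling over 4 h, noiseless.
#' * `growth_relA_OE_30uM` — moderate (p)ppGpp induction (constitutive
#'   synthetase, 30 uM IPTG), lambda = 0.45 /h (a > 50% decrease), same
#'   sampling.
#' * `viability_hyperosmotic_wt` — wild-type survival under hyperosmotic
#'   shock (extra 2 M NaCl): death rate 0.666 /h, i.e. 95% viability loss
#'   by 4.5 h; sampled every 0.5 h to 6 h.
#' * `viability_hyperosmotic_relA_OE` — induced strain, viability largely
#'   maintained (death rate 0.04 /h).
#' * `downshift_<scenario>_<strain>` — paired nutrient-downshift curves for
#'   scenarios `NH4Cl_to_alanine`, `NH4Cl_to_arginine` (nitrogen downshifts)
#'   and `glucose_to_alanine` (carbon downshift), strains `wt` and
#'   `relA_OE`. Curves start at the transition (OD_ini = 0.1, the usual
#'   post-filtration inoculum), sampled every 0.1 h for 8 h, noiseless.
#'   Induction shortens the lag 2.5-2.7x (within the observed 2-3x band)
#'   and slightly lowers the post-shift rate.
#' * `proteome_induction` — [proteome_spec()] with baseline and induced
#'   conditions in both wild-type and rpoS-null backgrounds, 3 replicates,
#'   CV 10%; rpoS pinned at an observed 5-fold induction. The measured
#'   (p)ppGpp pool increase at this induction level (4- to 5-fold) is
#'   carried as metadata.
#'
#' @param name Preset name; see [preset_names()].
#' @return A `curve_spec`, `proteome_spec`, or (for viability presets) a
#'   list of [gen_viability()] arguments.
#' @export
preset <- function(name) {
  downshift <- function(scenario, strain) {
    p <- switch(scenario,
      NH4Cl_to_alanine = list(wt = c(post = 0.40, lag = 2.5),
                              relA_OE = c(post = 0.36, lag = 1.0)),
      NH4Cl_to_arginine = list(wt = c(post = 0.35, lag = 3.0),
                               relA_OE = c(post = 0.33, lag = 1.2)),
      glucose_to_alanine = list(wt = c(post = 0.30, lag = 4.0),
                                relA_OE = c(post = 0.28, lag = 1.5)),
      stop("unknown downshift scenario: ", scenario))[[strain]]
    pre <- if (strain == "wt") 0.95 else 0.45
    curve_spec(lambda_pre = pre, lambda_post = p[["post"]], od0 = 0.1,
               lag_h = p[["lag"]], t_transition = 0, dt = 0.1, horizon = 8,
               cv = 0, strain = strain, condition = scenario)
  }
  switch(name,
    growth_wt_minimal = curve_spec(
      lambda_pre = 0.95, od0 = 0.02, dt = 1 / 6, horizon = 4, cv = 0,
      strain = "wild_type", condition = "glucose_minimal"),
    growth_relA_OE_30uM = curve_spec(
      lambda_pre = 0.45, od0 = 0.02, dt = 1 / 6, horizon = 4, cv = 0,
      strain = "relA_OE", condition = "glucose_minimal_30uM_IPTG"),
    viability_hyperosmotic_wt = list(
      rate = 0.666, t_grid = seq(0, 6, by = 0.5), cv = 0,
      stressor = "hyperosmotic_2M_NaCl", strain = "wild_type"),
    viability_hyperosmotic_relA_OE = list(
      rate = 0.04, t_grid = seq(0, 6, by = 0.5), cv = 0,
      stressor = "hyperosmotic_2M_NaCl", strain = "relA_OE"),
    downshift_NH4Cl_to_alanine_wt = downshift("NH4Cl_to_alanine", "wt"),
    downshift_NH4Cl_to_alanine_relA_OE = downshift("NH4Cl_to_alanine", "relA_OE"),
    downshift_NH4Cl_to_arginine_wt = downshift("NH4Cl_to_arginine", "wt"),
    downshift_NH4Cl_to_arginine_relA_OE = downshift("NH4Cl_to_arginine", "relA_OE"),
    downshift_glucose_to_alanine_wt = downshift("glucose_to_alanine", "wt"),
    downshift_glucose_to_alanine_relA_OE = downshift("glucose_to_alanine", "relA_OE"),
    proteome_induction = {
      sp <- proteome_spec(strains = c("wild_type", "rpoS_null"))
      attr(sp, "metadata") <- list(ppGpp_fold_at_30uM_IPTG = "4-5")
      sp
    },
    stop("unknown preset: ", name)
  )
}

#' @rdname preset
#' @export
preset_names <- function() {
  c("growth_wt_minimal", "growth_relA_OE_30uM",
    "viability_hyperosmotic_wt", "viability_hyperosmotic_relA_OE",
    "downshift_NH4Cl_to_alanine_wt", "downshift_NH4Cl_to_alanine_relA_OE",
    "downshift_NH4Cl_to_arginine_wt", "downshift_NH4Cl_to_arginine_relA_OE",
    "downshift_glucose_to_alanine_wt", "downshift_glucose_to_alanine_relA_OE",
    "proteome_induction")
}
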