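# The six experimental light steps (0-100% of 260 umol photons m-2 s-1)
light_steps <- c(0, 10, 33, 60, 80, 100) / 100 * 260

# Build a chamber record whose true states are carbonate-consistent:
# initial state from (dic_i, ta), final state after removing ddic_l umol/L
# of DIC at constant TA. No measurement noise.
make_chamber <- function(chamber_id = "c1", species = "S_latissima",
                         pco2_level = 400, dic_i = 2100, ta = 2150,
                         ddic_l = 30, ddo_l = 20, biomass_dw = 2,
                         duration_h = 1.5, temp = 15, sal = 31,
                         do_i = 250) {
  ini <- carb_from_dic_ta(dic_i, ta, temp, sal)
  fin <- carb_from_dic_ta(dic_i - umol_l_to_kg(ddic_l), ta, temp, sal)
  data.frame(chamber_id = chamber_id, species = species,
             pco2_level = pco2_level,
             ph_initial = ini$pH_total, ph_final = fin$pH_total,
             ta_initial = ta, ta_final = ta,
             do_initial = do_i, do_final = do_i + ddo_l,
             temp_C = temp, sal = sal, biomass_dw = biomass_dw,
             volume_L = 1, duration_h = duration_h)
}

# Noise-free generator configuration for exact-recovery checks
noiseless_exp2 <- function(seed = 1, ...) {
  generator_config(seed = seed, exp2 = list(
    sigma_ph = 0, sigma_ta = 0, sigma_do = 0,
    replicate_cv_scale = 0, biomass_fw_sd = 0,
    dark_offset_mean = c(do = 0, dic = 0), dark_offset_sd = 0, ...))
}
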