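#' Configuration for the synthetic experiment generators
#'
#' Assembles (and validates) the parameters that define the two emulated
#' experimental designs. Defaults reproduce the study conditions: a
#' chamber comparison of four macrophyte species across six pCO2 levels
#' (280-1120 uatm, 1 L chambers, 1.5 h incubations), and a flow-through
#' kelp experiment with two scenarios (ambient ~500 uatm / 11 C, future
#' ~1600 uatm / 13 C), two flows (0.5 / 1.4 L min-1), five replicate 30 L
#' tanks plus one kelp-free control, and six light steps (0-100% of
#' 260 umol photons m-2 s-1). Noise defaults are the instrument precisions
#' of the measurements being emulated (0.01 pH, 5 umol/kg TA, 2 umol/L DO).
#'
#' The chamber truth table carries per-species intercepts and per-uatm
#' slopes for the biomass- and time-normalized DO release and DIC uptake;
#' the generator applies these to DO and DIC (TA held constant) and lets
#' the pH and saturation-state responses emerge through the carbonate
#' system. Tank truth defaults to the treatment-mean light-curve parameter
#' table ([default_treatment_fits()]), with replicate-tank parameters drawn
#' log-normally around the treatment mean at the CV implied by the reported
#' standard errors (`CV = SE * sqrt(n) / mean`).
#'
#' @param seed integer seed; the same (seed, config) pair reproduces the
#'   generated tables exactly.
#' @param exp1,exp2 named lists overriding individual defaults (see the
#'   returned object for the full set of fields).
#' @return Object of class `generator_config`.
#' @examples
#' cfg <- generator_config(seed = 42, exp1 = list(n_reps = 4))
#' @export
generator_config <- function(seed = 1, exp1 = list(), exp2 = list()) {
  e1 <- list(
    species = c("S_latissima", "U_lactuca", "Z_marina", "F_vesiculosus"),
    truth = data.frame(
      species = c("S_latissima", "U_lactuca", "Z_marina", "F_vesiculosus"),
      int_do = c(25, 22, 8, 6),
      slope_do = c(0.03, 0.02, 0.01, 0.005),
      int_dic = c(20, 18, 6, 8),
      # per-uatm DIC-uptake slopes as published (umol L-1 g-1 h-1 per uatm)
      slope_dic = c(0.30, 0.02, 0.05, -0.01)
    ),
    pco2_levels = c(280, 400, 520, 640, 880, 1120),
    n_reps = 5, n_controls = 1,
    sigma_ph = 0.01, sigma_ta = 5, sigma_do = 2,
    ta_mean = 2150, ta_sd = 3,
    temp_range = c(14, 16), sal = 31,
    do_init_mean = 250, do_init_sd = 5,
    volume_L = 1, duration_h = 1.5,
    biomass_range = c(0.3, 0.8)
  )
  e2 <- list(
    scenarios = c("ambient", "future"),
    pco2 = c(ambient = 500, future = 1600),
    temp = c(ambient = 11, future = 13),
    sal = 31,
    flows = c(0.5, 1.4),
    n_tanks = 5, n_controls = 1,
    light_pct = c(0, 10, 33, 60, 80, 100), e_max = 260,
    volume_L = 30, biomass_fw_mean = 150, biomass_fw_sd = 10,
    ta_in = 2150,
    do_in = c(ambient = 280, future = 260),
    truth = NULL,              # NULL -> default_treatment_fits() (do, dic)
    replicate_cv_scale = 1,
    dark_offset_mean = c(do = 3, dic = 3),
    dark_offset_sd = 1,
    sigma_ph = 0.01, sigma_ta = 5, sigma_do = 2
  )
  e1[names(exp1)] <- exp1
  e2[names(exp2)] <- exp2
  if (any(diff(e2$light_pct) <= 0))
    stop("light levels must be strictly ascending", call. = FALSE)
  sds <- c(e1$sigma_ph, e1$sigma_ta, e1$sigma_do, e1$ta_sd,
           e2$sigma_ph, e2$sigma_ta, e2$sigma_do, e2$dark_offset_sd,
           e2$biomass_fw_sd, e2$replicate_cv_scale)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (e1$n_reps < 1 || e2$n_tanks < 1)
    stop("replicate counts must be >= 1", call. = FALSE)
  out <- list(seed = as.integer(seed), exp1 = e1, exp2 = e2)
  class(out) <- "generator_config"
  out
}

#' Generate a synthetic chamber experiment
#'
#' Emulates the closed-chamber species comparison. For each species x pCO2
#' level x replicate: an initial carbonate state is solved from the
#' (jittered) target pCO2 and alkalinity, the true biomass- and
#' time-normalized DO/DIC response from the truth table is applied to the
#' chamber (DIC removal at constant TA; the final pH follows from the
#' carbonate system), and Gaussian measurement noise is added to the
#' recorded pH, TA and DO at both time points. Control chambers carry no
#' macrophyte and zero true change.
#'
#' @param cfg a [generator_config()].
#' @return data.frame in the input layout of [chamber_deltas()], with a
#'   `truth` attribute (the truth table and per-chamber true normalized
#'   deltas).
#' @examples
#' ch <- generate_chamber_experiment(generator_config(seed = 7))
#' head(ch)
#' @export
generate_chamber_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  e <- cfg$exp1
  set.seed(cfg$seed)
  rows <- list(); truths <- list(); id <- 0L
  for (lev in e$pco2_levels) {
    for (sp in c(e$species, rep("control", e$n_controls))) {
      n <- if (sp == "control") 1L else e$n_reps
      for (r in seq_len(n)) {
        id <- id + 1L
        temp <- stats::runif(1, e$temp_range[1], e$temp_range[2])
        ta <- e$ta_mean + stats::rnorm(1, 0, e$ta_sd)
        state <- NULL
        for (try in 1:10) {   # bounded retries on infeasible draws
          pco2_actual <- lev * (1 + stats::rnorm(1, 0, 0.02))
          ph_i <- tryCatch(.ph_from_pco2_ta(pco2_actual, ta, temp, e$sal),
                           error = function(err) NULL)
          if (!is.null(ph_i)) { state <- ph_i; break }
        }
        if (is.null(state))
          stop("could not generate a feasible initial state", call. = FALSE)
        ini <- carb_from_ph_ta(state, ta, temp, e$sal)
        B <- if (sp == "control") 0 else
          stats::runif(1, e$biomass_range[1], e$biomass_range[2])
        tr <- e$truth[e$truth$species == sp, ]
        rate_do <- if (sp == "control") 0 else tr$int_do + tr$slope_do * lev
        rate_dic <- if (sp == "control") 0 else tr$int_dic + tr$slope_dic * lev
        raw_do <- rate_do * B * e$duration_h        # umol/L per chamber
        raw_dic <- rate_dic * B * e$duration_h
        dic_f <- ini$DIC_umol_kg - umol_l_to_kg(raw_dic)
        fin <- carb_from_dic_ta(dic_f, ta, temp, e$sal)
        do_i <- e$do_init_mean + stats::rnorm(1, 0, e$do_init_sd)
        rows[[id]] <- data.frame(
          chamber_id = sprintf("ch%03d", id), species = sp,
          pco2_level = lev,
          ph_initial = ini$pH_total + stats::rnorm(1, 0, e$sigma_ph),
          ph_final = fin$pH_total + stats::rnorm(1, 0, e$sigma_ph),
          ta_initial = ta + stats::rnorm(1, 0, e$sigma_ta),
          ta_final = ta + stats::rnorm(1, 0, e$sigma_ta),
          do_initial = do_i + stats::rnorm(1, 0, e$sigma_do),
          do_final = do_i + raw_do + stats::rnorm(1, 0, e$sigma_do),
          temp_C = temp, sal = e$sal, biomass_dw = B,
          volume_L = e$volume_L, duration_h = e$duration_h
        )
        truths[[id]] <- data.frame(
          chamber_id = rows[[id]]$chamber_id, species = sp,
          pco2_level = lev, rate_do = rate_do, rate_dic = rate_dic,
          raw_d_do = raw_do, raw_d_dic = raw_dic
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(table = e$truth,
                             chambers = do.call(rbind, truths))
  out
}

#' Generate a synthetic flow-through tank experiment
#'
#' Emulates the kelp residence-time experiment. Per treatment (scenario x
#' flow) the inflow carbonate state is solved from the target pCO2 and
#' alkalinity; each replicate tank draws its own Jassby-Platt parameters
#' log-normally around the treatment truth and a dark respiration offset;
#' at each light step the steady-state outflow carries the gross light
#' response minus the dark offset, with the DIC-linked pH computed through
#' the carbonate solver so that all four response variables are mutually
#' consistent. Measurement noise is added to the recorded inflow and
#' outflow pH, TA and DO. Control tanks carry no kelp and zero signal.
#'
#' @param cfg a [generator_config()]; `cfg$exp2$replicate_cv_scale = 0` and
#'   zero noise/dark-offset settings produce noiseless tanks whose fitted
#'   parameters recover the truth exactly.
#' @return data.frame in the input layout of [tank_deltas()], with a
#'   `truth` attribute (treatment truth and per-tank drawn parameters).
#' @examples
#' tk <- generate_tank_experiment(generator_config(seed = 7))
#' head(tk)
#' @export
generate_tank_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  e <- cfg$exp2
  set.seed(cfg$seed + 1L)
  truth <- e$truth
  if (is.null(truth)) {
    tf <- default_treatment_fits()
    truth <- tf[tf$variable %in% c("do", "dic"), ]
  }
  E <- e$light_pct / 100 * e$e_max
  rows <- list(); tank_truths <- list(); id <- 0L

  draw_param <- function(mean, se, n) {
    cv <- e$replicate_cv_scale * se * sqrt(n) / mean
    if (cv == 0) return(mean)
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(1, log(mean) - sdlog^2 / 2, sdlog)
  }

  for (sc in e$scenarios) {
    temp <- e$temp[[sc]]
    ph_in_true <- .ph_from_pco2_ta(e$pco2[[sc]], e$ta_in, temp, e$sal)
    in_state <- carb_from_ph_ta(ph_in_true, e$ta_in, temp, e$sal)
    for (fl in e$flows) {
      tr_do <- truth[truth$scenario == sc & truth$flow_L_min == fl &
                       truth$variable == "do", ]
      tr_dic <- truth[truth$scenario == sc & truth$flow_L_min == fl &
                        truth$variable == "dic", ]
      if (nrow(tr_do) != 1 || nrow(tr_dic) != 1)
        stop("truth table must have one do and one dic row per treatment",
             call. = FALSE)
      for (tk in seq_len(e$n_tanks + e$n_controls)) {
        id <- id + 1L
        control <- tk > e$n_tanks
        if (control) {
          pm_do <- al_do <- pm_dic <- al_dic <- rd_do <- rd_dic <- 0
          bio <- 0
        } else {
          pm_do <- draw_param(tr_do$pmax, tr_do$pmax_se, tr_do$n)
          al_do <- draw_param(tr_do$alpha, tr_do$alpha_se, tr_do$n)
          pm_dic <- draw_param(tr_dic$pmax, tr_dic$pmax_se, tr_dic$n)
          al_dic <- draw_param(tr_dic$alpha, tr_dic$alpha_se, tr_dic$n)
          rd_do <- max(0, stats::rnorm(1, e$dark_offset_mean[["do"]],
                                       e$dark_offset_sd))
          rd_dic <- max(0, stats::rnorm(1, e$dark_offset_mean[["dic"]],
                                        e$dark_offset_sd))
          bio <- max(1, e$biomass_fw_mean +
                       stats::rnorm(1, 0, e$biomass_fw_sd))
        }
        tank_id <- sprintf("%s_f%s_t%d", sc, fl, tk)
        ddo <- if (control) rep(0, length(E)) else
          jassby_platt(pmax(E, 0), max(pm_do, 1e-9), al_do) - rd_do
        ddic <- if (control) rep(0, length(E)) else
          jassby_platt(pmax(E, 0), max(pm_dic, 1e-9), al_dic) - rd_dic
        dic_out <- in_state$DIC_umol_kg - umol_l_to_kg(ddic)
        out_state <- carb_from_dic_ta(dic_out, e$ta_in, temp, e$sal)
        do_in_true <- e$do_in[[sc]]
        m <- length(E)
        rows[[id]] <- data.frame(
          tank_id = tank_id, scenario = sc, flow_L_min = fl,
          control = control, light_pct = e$light_pct,
          light_umol_m2_s = E,
          ph_in = ph_in_true + stats::rnorm(m, 0, e$sigma_ph),
          ph_out = out_state$pH_total + stats::rnorm(m, 0, e$sigma_ph),
          ta_in = e$ta_in + stats::rnorm(m, 0, e$sigma_ta),
          ta_out = e$ta_in + stats::rnorm(m, 0, e$sigma_ta),
          do_in = do_in_true + stats::rnorm(m, 0, e$sigma_do),
          do_out = do_in_true + ddo + stats::rnorm(m, 0, e$sigma_do),
          temp_C = temp, sal = e$sal, biomass_fw = bio,
          volume_L = e$volume_L
        )
        tank_truths[[id]] <- data.frame(
          tank_id = tank_id, scenario = sc, flow_L_min = fl,
          control = control, pmax_do = pm_do, alpha_do = al_do,
          pmax_dic = pm_dic, alpha_dic = al_dic,
          rd_do = rd_do, rd_dic = rd_dic, biomass_fw = bio
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(table = truth,
                             tanks = do.call(rbind, tank_truths))
  out
}

#' Per-record tank amelioration responses
#'
#' Computes the inflow-outflow response of each tank x light-step record:
#' DIC and aragonite saturation state at inflow and outflow are derived
#' from measured pH and TA via [carb_from_ph_ta()]. `d_do` and `d_ph` and
#' `d_omega` are outflow minus inflow (release/increase positive); `d_dic`
#' is inflow minus outflow in umol L-1 (uptake positive).
#'
#' @param tanks data.frame in the layout produced by
#'   [generate_tank_experiment()] (or equivalent measured data).
#' @return data.frame of class `tank_deltas`, one row per record, ready for
#'   [fit_tank_curves()].
#' @export
tank_deltas <- function(tanks) {
  req <- c("tank_id", "scenario", "flow_L_min", "light_umol_m2_s",
           "ph_in", "ph_out", "ta_in", "ta_out", "do_in", "do_out",
           "temp_C", "sal")
  miss <- setdiff(req, names(tanks))
  if (length(miss))
    stop("missing tank columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  inn <- carb_from_ph_ta(tanks$ph_in, tanks$ta_in, tanks$temp_C, tanks$sal)
  out <- carb_from_ph_ta(tanks$ph_out, tanks$ta_out, tanks$temp_C,
                         tanks$sal)
  d <- data.frame(
    tank_id = tanks$tank_id, scenario = tanks$scenario,
    flow_L_min = tanks$flow_L_min,
    control = if ("control" %in% names(tanks)) tanks$control else FALSE,
    light_pct = if ("light_pct" %in% names(tanks)) tanks$light_pct else NA,
    light_umol_m2_s = tanks$light_umol_m2_s,
    d_do = tanks$do_out - tanks$do_in,
    d_dic = umol_kg_to_l(inn$DIC_umol_kg - out$DIC_umol_kg),
    d_ph = tanks$ph_out - tanks$ph_in,
    d_omega = out$omega_ar - inn$omega_ar
  )
  class(d) <- c("tank_deltas", "data.frame")
  d
}
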