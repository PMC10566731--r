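#' Biomass- and time-normalized chamber incubation responses
#'
#' Computes the amelioration response of each closed-chamber incubation:
#' DIC and aragonite saturation state at both time points are derived from
#' measured pH and TA through [carb_from_ph_ta()], and the change over the
#' incubation is normalized by macrophyte dry-weight biomass and duration.
#'
#' Sign conventions (stated in the output): `d_do`, `d_ph`, `d_omega` are
#' final minus initial (release/increase positive); `d_dic` is initial
#' minus final, so positive values mean DIC removal (uptake). Control
#' chambers (no macrophyte) are normalized per litre and hour only.
#'
#' @param chambers data.frame with columns `chamber_id`, `species`
#'   (`"control"` for blank chambers), `pco2_level` (uatm treatment label),
#'   `ph_initial`, `ph_final` (total scale), `ta_initial`, `ta_final`
#'   (umol kg-1; may be `NA` if supplied via `species_ta`), `do_initial`,
#'   `do_final` (umol L-1), `temp_C`, `sal`, `biomass_dw` (g; 0 for
#'   controls), `volume_L`, `duration_h`.
#' @param species_ta optional species-level alkalinity table (columns
#'   `species`, `pco2_level`, `ta_initial`, `ta_final`) joined onto
#'   chambers whose own TA columns are missing; measured per-chamber TA
#'   always takes precedence.
#' @return data.frame of class `chamber_deltas`: identifiers plus `d_do`,
#'   `d_dic` (umol L-1 g-1 h-1; per L and h only for controls), `d_ph`
#'   (pH g-1 h-1), `d_omega` (g-1 h-1), and the raw per-litre changes
#'   (`raw_` columns, umol L-1 or plain units per incubation).
#' @seealso [fit_species_pco2_model()], [generate_chamber_experiment()]
#' @export
chamber_deltas <- function(chambers, species_ta = NULL) {
  req <- c("chamber_id", "species", "pco2_level", "ph_initial", "ph_final",
           "do_initial", "do_final", "temp_C", "sal", "biomass_dw",
           "volume_L", "duration_h")
  miss <- setdiff(req, names(chambers))
  if (length(miss))
    stop("missing chamber columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ch <- chambers
  if (!"ta_initial" %in% names(ch)) ch$ta_initial <- NA_real_
  if (!"ta_final" %in% names(ch)) ch$ta_final <- NA_real_
  if (!is.null(species_ta)) {
    idx <- match(interaction(ch$species, ch$pco2_level),
                 interaction(species_ta$species, species_ta$pco2_level))
    fill_i <- is.na(ch$ta_initial) & !is.na(idx)
    fill_f <- is.na(ch$ta_final) & !is.na(idx)
    ch$ta_initial[fill_i] <- species_ta$ta_initial[idx[fill_i]]
    ch$ta_final[fill_f] <- species_ta$ta_final[idx[fill_f]]
  }
  if (any(is.na(ch$ta_initial) | is.na(ch$ta_final)))
    stop("alkalinity missing for chamber(s): ",
         paste(ch$chamber_id[is.na(ch$ta_initial) | is.na(ch$ta_final)],
               collapse = ", "), call. = FALSE)
  if (any(ch$duration_h <= 0))
    stop("`duration_h` must be positive", call. = FALSE)
  is_ctl <- ch$species == "control"
  if (any(!is_ctl & ch$biomass_dw <= 0))
    stop("`biomass_dw` must be positive for macrophyte chambers",
         call. = FALSE)

  ini <- tryCatch(
    carb_from_ph_ta(ch$ph_initial, ch$ta_initial, ch$temp_C, ch$sal),
    error = function(e) stop("initial carbonate state infeasible (",
                             conditionMessage(e), ")", call. = FALSE))
  fin <- tryCatch(
    carb_from_ph_ta(ch$ph_final, ch$ta_final, ch$temp_C, ch$sal),
    error = function(e) stop("final carbonate state infeasible (",
                             conditionMessage(e), ")", call. = FALSE))

  raw_do <- ch$do_final - ch$do_initial                      # umol/L
  raw_dic <- umol_kg_to_l(ini$DIC_umol_kg - fin$DIC_umol_kg) # uptake, umol/L
  raw_ph <- ch$ph_final - ch$ph_initial
  raw_omega <- fin$omega_ar - ini$omega_ar

  # per gram dry weight per hour; controls per litre per hour only
  norm <- ifelse(is_ctl, ch$duration_h, ch$biomass_dw * ch$duration_h)
  out <- data.frame(
    chamber_id = ch$chamber_id, species = ch$species,
    pco2_level = ch$pco2_level, control = is_ctl,
    biomass_dw = ch$biomass_dw, duration_h = ch$duration_h,
    d_do = raw_do / norm, d_dic = raw_dic / norm,
    d_ph = raw_ph / norm, d_omega = raw_omega / norm,
    raw_d_do = raw_do, raw_d_dic = raw_dic,
    raw_d_ph = raw_ph, raw_d_omega = raw_omega
  )
  class(out) <- c("chamber_deltas", "data.frame")
  out
}

#' Species-by-pCO2 linear response model
#'
#' Ordinary least squares of a normalized chamber response on species
#' (categorical), pCO2 level (continuous, uatm) and their interaction,
#' with the sequential (Type-I) ANOVA in the fixed order species, pCO2,
#' species:pCO2. Per-species slopes (response change per uatm) are
#' assembled from the pCO2 coefficient and the interaction contrasts.
#'
#' @param deltas a [chamber_deltas()] data.frame (controls are dropped).
#' @param response one of `"do"`, `"dic"`, `"ph"`, `"omega"`.
#' @return Object of class `species_pco2_fit`: the underlying `lm` fit
#'   (`fit`), the sequential `anova` table, named per-species `slopes` and
#'   `intercepts`, and `response`.
#' @examples
#' cfg <- generator_config(seed = 1)
#' d <- chamber_deltas(generate_chamber_experiment(cfg))
#' m <- fit_species_pco2_model(d, "ph")
#' coef(m)   # per-species slopes per uatm
#' @export
fit_species_pco2_model <- function(deltas,
                                   response = c("do", "dic", "ph", "omega")) {
  response <- match.arg(response)
  col <- paste0("d_", response)
  d <- deltas[!deltas$control, , drop = FALSE]
  d$species <- factor(as.character(d$species))
  d$pco2 <- as.numeric(d$pco2_level)
  if (nlevels(d$species) < 2)
    stop("need >= 2 species", call. = FALSE)
  if (length(unique(d$pco2)) < 2)
    stop("need >= 2 pCO2 levels", call. = FALSE)
  d$y <- d[[col]]
  fit <- stats::lm(y ~ species * pco2, data = d)
  if (fit$rank < length(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  aov_tab <- stats::anova(fit)

  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  sp <- levels(d$species)
  slope_contrast <- function(s) {
    v <- stats::setNames(rep(0, length(cf)), names(cf))
    v["pco2"] <- 1
    term <- paste0("species", s, ":pco2")
    if (term %in% names(cf)) v[term] <- 1
    v
  }
  slopes <- vapply(sp, function(s) sum(slope_contrast(s) * cf), numeric(1))
  slopes_se <- vapply(sp, function(s) {
    v <- slope_contrast(s)
    sqrt(drop(t(v) %*% V %*% v))
  }, numeric(1))
  intercepts <- vapply(sp, function(s) {
    b <- cf[["(Intercept)"]]
    term <- paste0("species", s)
    if (term %in% names(cf)) b <- b + cf[[term]]
    b
  }, numeric(1))

  out <- list(fit = fit, anova = aov_tab, slopes = slopes,
              slopes_se = slopes_se, intercepts = intercepts,
              response = response)
  class(out) <- "species_pco2_fit"
  out
}

#' @export
confint.species_pco2_fit <- function(object, parm, level = 0.95, ...) {
  q <- stats::qt(1 - (1 - level) / 2, stats::df.residual(object$fit))
  out <- cbind(object$slopes - q * object$slopes_se,
               object$slopes + q * object$slopes_se)
  colnames(out) <- paste(100 * c((1 - level) / 2, 1 - (1 - level) / 2), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
print.species_pco2_fit <- function(x, ...) {
  cat(sprintf("Species x pCO2 linear response model for d_%s\n", x$response))
  cat("Sequential (Type-I) ANOVA:\n")
  print(x$anova)
  cat("\nPer-species slopes (response per uatm pCO2):\n")
  print(signif(x$slopes, 4))
  invisible(x)
}

#' @export
coef.species_pco2_fit <- function(object, ...) object$slopes

#' @export
summary.species_pco2_fit <- function(object, ...) summary(object$fit, ...)
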