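#' Jassby-Platt photosynthesis-irradiance curve
#'
#' The saturating hyperbolic-tangent light response
#' \eqn{P = P_{max} \tanh(\alpha E / P_{max})}: linear with initial slope
#' `alpha` at low irradiance, plateauing at `pmax` above the saturation
#' irradiance \eqn{E_k = P_{max}/\alpha}. No photoinhibition term.
#'
#' @param E irradiance, umol photons m-2 s-1, >= 0.
#' @param pmax maximum rate at saturating irradiance (response units), > 0.
#' @param alpha initial light-limited slope (response units per unit
#'   irradiance), >= 0.
#' @return Predicted rate in the units of `pmax`.
#' @examples
#' jassby_platt(210.97, pmax = 32.44, alpha = 0.1538)  # ~ pmax * tanh(1)
#' @export
jassby_platt <- function(E, pmax, alpha) {
  if (any(E < 0)) stop("`E` must be non-negative", call. = FALSE)
  if (any(pmax <= 0)) stop("`pmax` must be positive", call. = FALSE)
  if (any(alpha < 0)) stop("`alpha` must be non-negative", call. = FALSE)
  pmax * tanh(alpha * E / pmax)
}

#' Saturation irradiance Ek
#'
#' \eqn{E_k = P_{max}/\alpha}, the irradiance at which the initial slope
#' reaches the plateau; the response at `Ek` is `pmax * tanh(1)`, about 76%
#' of the plateau.
#'
#' @param object a `light_fit` from [fit_light_curve()], or `pmax` directly.
#' @param alpha initial slope, required when `object` is numeric.
#' @return Ek in umol photons m-2 s-1.
#' @examples
#' saturation_irradiance(32.44, 0.1538)
#' @export
saturation_irradiance <- function(object, alpha = NULL) {
  if (inherits(object, "light_fit")) {
    pmax <- object$coefficients[["pmax"]]
    alpha <- object$coefficients[["alpha"]]
  } else {
    pmax <- object
    if (is.null(alpha)) stop("`alpha` required", call. = FALSE)
  }
  if (any(alpha == 0))
    stop("saturation irradiance undefined for alpha = 0", call. = FALSE)
  pmax / alpha
}

#' Fit a Jassby-Platt light curve by Nelder-Mead least squares
#'
#' Minimizes the residual sum of squares of [jassby_platt()] over
#' `(pmax, alpha)` with a derivative-free simplex search, restarted once
#' from the first optimum (standard practice to tighten Nelder-Mead
#' termination). Starting values are `pmax0 = max(P)` and `alpha0` from the
#' slope of the two lowest non-zero-irradiance points, robust for
#' saturating curves.
#'
#' The dark step (`E == 0`) is excluded by default: the model forces
#' `P(0) = 0` while the observed dark response reflects respiration. Set
#' `dark_offset = TRUE` to fit the net model `P = JP(E) - Rd` with a dark
#' respiration offset `rd`, keeping the dark step in.
#'
#' @param E irradiance levels, umol photons m-2 s-1 (>= 3 distinct values
#'   spanning sub- and supra-saturating irradiance).
#' @param P observed response at each level (delta-units; umol/L for
#'   DO/DIC, pH units or dimensionless for pH/Omega responses).
#' @param exclude_dark drop `E == 0` observations (default `TRUE`; ignored
#'   when `dark_offset = TRUE`).
#' @param dark_offset fit a dark respiration offset `rd` (default `FALSE`).
#' @param maxit maximum simplex iterations per start.
#' @return Object of class `light_fit` with components `coefficients`
#'   (`pmax`, `alpha`, optionally `rd`), `e_k`, `rss`, `converged`,
#'   `n_points`, `fitted.values`, `residuals` and the data used.
#' @examples
#' E <- c(26, 85.8, 156, 208, 260)
#' P <- jassby_platt(E, 32.44, 0.16)
#' fit <- fit_light_curve(E, P)
#' coef(fit)
#' @seealso [jassby_platt()], [saturation_irradiance()], [welch_from_summary()]
#' @export
fit_light_curve <- function(E, P, exclude_dark = TRUE, dark_offset = FALSE,
                            maxit = 2000) {
  stopifnot(length(E) == length(P))
  ok <- is.finite(E) & is.finite(P)
  E <- E[ok]; P <- P[ok]
  if (any(E < 0)) stop("`E` must be non-negative", call. = FALSE)
  if (exclude_dark && !dark_offset) {
    keep <- E > 0
    E <- E[keep]; P <- P[keep]
  }
  if (length(unique(E)) < 3)
    stop("need >= 3 distinct irradiance levels", call. = FALSE)
  if (all(P == 0))
    stop("degenerate response: all observations zero", call. = FALSE)

  pmax0 <- max(P, max(abs(P)) * 0.1)
  nz <- order(E[E > 0])[1:2]
  Enz <- E[E > 0][nz]; Pnz <- P[E > 0][nz]
  alpha0 <- if (diff(Enz) != 0) abs(diff(Pnz) / diff(Enz)) else NA_real_
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- pmax0 / stats::median(E[E > 0])

  obj <- if (dark_offset) {
    function(par) {
      if (par[1] <= 0 || par[2] <= 0) return(1e30)
      sum((P - (par[1] * tanh(par[2] * E / par[1]) - par[3]))^2)
    }
  } else {
    function(par) {
      if (par[1] <= 0 || par[2] <= 0) return(1e30)
      sum((P - par[1] * tanh(par[2] * E / par[1]))^2)
    }
  }
  par0 <- if (dark_offset) c(pmax0, alpha0, max(0, -min(P))) else c(pmax0, alpha0)
  ctl <- list(maxit = maxit, reltol = 1e-14)
  opt <- stats::optim(par0, obj, method = "Nelder-Mead", control = ctl)
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = ctl)
  if (opt2$value <= opt$value) opt <- opt2

  coefs <- c(pmax = opt$par[1], alpha = opt$par[2])
  if (dark_offset) coefs <- c(coefs, rd = opt$par[3])
  fitted <- coefs[["pmax"]] * tanh(coefs[["alpha"]] * E / coefs[["pmax"]])
  if (dark_offset) fitted <- fitted - coefs[["rd"]]

  e_k <- coefs[["pmax"]] / coefs[["alpha"]]
  out <- list(
    coefficients = coefs,
    e_k = e_k,
    rss = opt$value,
    converged = opt$convergence == 0 && coefs[["pmax"]] > 0 &&
      coefs[["alpha"]] > 0,
    # plateau identified only if the fitted saturation irradiance falls
    # near the measured range: far above it the fit degenerates to a line
    # (pmax, Ek unbounded); far below the lowest light level the initial
    # slope is unconstrained (alpha unbounded)
    saturating = e_k <= 3 * max(E) && e_k >= min(E[E > 0]) / 3 &&
      coefs[["pmax"]] <= 5 * max(abs(P)),
    n_points = length(E),
    E = E, P = P,
    fitted.values = fitted,
    residuals = P - fitted,
    dark_offset = dark_offset,
    call = match.call()
  )
  class(out) <- "light_fit"
  out
}

#' @export
print.light_fit <- function(x, digits = 4, ...) {
  cat("Jassby-Platt light-response fit (Nelder-Mead least squares)\n")
  cat(sprintf("  Pmax = %.*g, alpha = %.*g, Ek = %.*g\n",
              digits, x$coefficients[["pmax"]],
              digits, x$coefficients[["alpha"]], digits, x$e_k))
  if (x$dark_offset)
    cat(sprintf("  dark offset Rd = %.*g\n", digits, x$coefficients[["rd"]]))
  cat(sprintf("  n = %d, RSS = %.*g, converged: %s, plateau identified: %s\n",
              x$n_points, digits, x$rss, x$converged, x$saturating))
  invisible(x)
}

#' @export
coef.light_fit <- function(object, ...) object$coefficients

#' @export
fitted.light_fit <- function(object, ...) object$fitted.values

#' @export
residuals.light_fit <- function(object, ...) object$residuals

#' @export
predict.light_fit <- function(object, newdata = NULL, ...) {
  E <- if (is.null(newdata)) object$E
       else if (is.list(newdata)) newdata$E else newdata
  p <- jassby_platt(E, object$coefficients[["pmax"]],
                    object$coefficients[["alpha"]])
  if (object$dark_offset) p <- p - object$coefficients[["rd"]]
  p
}

#' @export
summary.light_fit <- function(object, ...) {
  sigma <- sqrt(object$rss / max(1, object$n_points -
                                   length(object$coefficients)))
  structure(list(fit = object, sigma = sigma), class = "summary.light_fit")
}

#' @export
print.summary.light_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SD = %.4g\n", x$sigma))
  invisible(x)
}

#' @export
simulate.light_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- summary(object)$sigma
  out <- as.data.frame(replicate(
    nsim, object$fitted.values + stats::rnorm(object$n_points, 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.light_fit <- function(x, xlab = "Irradiance (umol photons m-2 s-1)",
                           ylab = "Response", ...) {
  graphics::plot(x$E, x$P, xlab = xlab, ylab = ylab, ...)
  Egrid <- seq(0, max(x$E), length.out = 200)
  graphics::lines(Egrid, predict(x, Egrid))
  graphics::abline(v = x$e_k, lty = 3)
  invisible(x)
}

#' Welch two-sample t-test from summary statistics
#'
#' Welch's unequal-variance t statistic with Satterthwaite fractional
#' degrees of freedom, computed from group means, standard errors of the
#' mean and sample sizes -- the form needed to compare fitted light-curve
#' parameters reported as treatment mean +/- SE.
#'
#' @param mean1,se1,n1 first group: mean, standard error of the mean, n.
#' @param mean2,se2,n2 second group.
#' @return Object of class `welch_test` (and `htest`): statistic `t`,
#'   fractional `df`, two-sided `p.value`.
#' @examples
#' # compare Pmax 32.44 +/- 3.58 (n = 5) against 20.54 +/- 1.96 (n = 5)
#' welch_from_summary(32.44, 3.58, 5, 20.54, 1.96, 5)
#' @export
welch_from_summary <- function(mean1, se1, n1, mean2, se2, n2) {
  if (se1 < 0 || se2 < 0) stop("SEs must be >= 0", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in each group", call. = FALSE)
  v <- se1^2 + se2^2
  if (v == 0) stop("both groups have zero variance", call. = FALSE)
  t <- (mean2 - mean1) / sqrt(v)
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  out <- list(statistic = c(t = t), parameter = c(df = df), p.value = p,
              estimate = c(mean1 = mean1, mean2 = mean2),
              method = "Welch two-sample t-test (from summaries)",
              data.name = "summary statistics")
  class(out) <- c("welch_test", "htest")
  out
}

#' Welch two-sample t-test from raw samples
#'
#' Computes each sample's mean, SE and n and delegates to
#' [welch_from_summary()], so the two entry points agree exactly.
#'
#' @param x1,x2 numeric samples, each of length >= 2.
#' @return A `welch_test` object (see [welch_from_summary()]).
#' @examples
#' welch_from_samples(rnorm(5, 32), rnorm(5, 21))
#' @export
welch_from_samples <- function(x1, x2) {
  if (length(x1) < 2 || length(x2) < 2)
    stop("need >= 2 observations per sample", call. = FALSE)
  if (stats::var(x1) == 0 && stats::var(x2) == 0)
    stop("both samples have zero variance", call. = FALSE)
  welch_from_summary(mean(x1), stats::sd(x1) / sqrt(length(x1)), length(x1),
                     mean(x2), stats::sd(x2) / sqrt(length(x2)), length(x2))
}

#' Per-tank light-curve fits and treatment summaries
#'
#' Fits one Jassby-Platt curve per tank for one response variable and
#' aggregates the fitted parameters to treatment level (mean, SE, n per
#' scenario x flow), the form in which treatment light responses are
#' reported and the input expected by [amelioration_model()].
#'
#' @param deltas a data.frame of per-record tank responses as produced by
#'   [tank_deltas()] (columns `tank_id`, `scenario`, `flow_L_min`,
#'   `control`, `light_umol_m2_s`, and `d_<variable>`).
#' @param variable one of `"do"`, `"dic"`, `"ph"`, `"omega"`.
#' @param drop_unidentified exclude per-tank fits whose plateau is not
#'   identified (runaway `pmax`/`Ek`, see `saturating` in
#'   [fit_light_curve()]) from the treatment summary, the usual practice
#'   when a replicate curve never approaches saturation. The per-tank table
#'   keeps every fit with its flags.
#' @param ... passed to [fit_light_curve()].
#' @return list with `fits` (per-tank parameter data.frame) and `summary`
#'   (per scenario x flow: `pmax`, `pmax_se`, `alpha`, `alpha_se`, `ek`,
#'   `ek_se`, `n`).
#' @export
fit_tank_curves <- function(deltas, variable = c("do", "dic", "ph", "omega"),
                            drop_unidentified = TRUE, ...) {
  variable <- match.arg(variable)
  col <- paste0("d_", variable)
  if (!col %in% names(deltas)) stop("column ", col, " not found", call. = FALSE)
  d <- deltas[!deltas$control, , drop = FALSE]
  key <- interaction(d$tank_id, d$scenario, d$flow_L_min, drop = TRUE)
  rows <- lapply(split(d, key), function(g) {
    fit <- fit_light_curve(g$light_umol_m2_s, g[[col]], ...)
    data.frame(tank_id = g$tank_id[1], scenario = g$scenario[1],
               flow_L_min = g$flow_L_min[1],
               pmax = coef(fit)[["pmax"]], alpha = coef(fit)[["alpha"]],
               ek = fit$e_k, rss = fit$rss, converged = fit$converged,
               saturating = fit$saturating)
  })
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  keep <- if (drop_unidentified) fits$converged & fits$saturating
          else rep(TRUE, nrow(fits))
  if (!any(keep)) stop("no identifiable per-tank fits", call. = FALSE)
  grp <- interaction(fits$scenario[keep], fits$flow_L_min[keep], drop = TRUE)
  summ <- do.call(rbind, lapply(split(fits[keep, ], grp), function(g) {
    n <- nrow(g)
    data.frame(scenario = g$scenario[1], flow_L_min = g$flow_L_min[1],
               variable = variable,
               pmax = mean(g$pmax), pmax_se = stats::sd(g$pmax) / sqrt(n),
               alpha = mean(g$alpha), alpha_se = stats::sd(g$alpha) / sqrt(n),
               ek = mean(g$ek), ek_se = stats::sd(g$ek) / sqrt(n),
               n = n)
  }))
  rownames(summ) <- NULL
  list(fits = fits, summary = summ)
}
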