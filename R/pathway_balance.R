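#' Enzyme abundance profile of a whole-cell catalyst
#'
#' Copies per cell of the three pathway enzymes plus a dimensionless
#' endogenous-reductase activity scale (1 = wild-type E. coli background).
#'
#' @param p450 Cytochrome P450 limonene-6-hydroxylase copies per cell.
#' @param cpr Cytochrome P450 reductase copies per cell.
#' @param cdh Carveol dehydrogenase copies per cell.
#' @param endogenous Endogenous carbonyl/ene-reductase activity scale.
#' @param strain Strain label.
#' @return A list of class `enzyme_profile`.
#' @export
enzyme_profile <- function(p450 = 0, cpr = 0, cdh = 0, endogenous = 1,
                           strain = "") {
  stopifnot(p450 >= 0, cpr >= 0, cdh >= 0, endogenous >= 0)
  structure(list(p450 = p450, cpr = cpr, cdh = cdh,
                 endogenous = endogenous, strain = strain),
            class = "enzyme_profile")
}

#' Whole-cell bioconversion reaction conditions
#'
#' @param od600 Cell density of the reaction (OD600 units).
#' @param duration_h Reaction time in hours.
#' @param substrate Starting substrate, `"limonene"` or `"carveol"`.
#' @param substrate_mg_per_l Initial substrate concentration (mg/L).
#' @param temperature_c Reaction temperature, informational only (the rate
#'   coefficients are calibrated at this temperature).
#' @return A list of class `reaction_conditions`.
#' @export
reaction_conditions <- function(od600 = 20, duration_h = 16,
                                substrate = c("limonene", "carveol"),
                                substrate_mg_per_l = 100,
                                temperature_c = 14) {
  substrate <- match.arg(substrate)
  stopifnot(od600 > 0, duration_h > 0, substrate_mg_per_l >= 0)
  structure(list(od600 = od600, duration_h = duration_h,
                 substrate = substrate,
                 substrate_mg_per_l = substrate_mg_per_l,
                 temperature_c = temperature_c),
            class = "reaction_conditions")
}

#' Second-order rate coefficients of the bioconversion network
#'
#' Mass-action coefficients in units of per (copies per cell) per OD600
#' per hour, for the five reactions of the network:
#' limonene -> trans-carveol (P450/CPR, flux limited by the scarcer of the
#' two), trans-carveol -> carvone (CDH), trans-carveol -> dihydrocarveol
#' (CDH side reaction), trans-carveol -> dihydrocarvone (endogenous) and
#' carvone -> dihydrocarvone (endogenous).
#'
#' @param k_p450 limonene -> carveol coefficient.
#' @param k_cdh_carvone carveol -> carvone coefficient.
#' @param k_cdh_branch carveol -> dihydrocarveol coefficient.
#' @param k_endo_carveol carveol -> dihydrocarvone coefficient.
#' @param k_endo_carvone carvone -> dihydrocarvone coefficient.
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(k_p450, k_cdh_carvone, k_cdh_branch,
                           k_endo_carveol, k_endo_carvone) {
  ks <- c(k_p450 = k_p450, k_cdh_carvone = k_cdh_carvone,
          k_cdh_branch = k_cdh_branch, k_endo_carveol = k_endo_carveol,
          k_endo_carvone = k_endo_carvone)
  if (any(ks < 0)) stop("rate coefficients must be non-negative")
  structure(as.list(ks), class = "kinetic_params")
}

# Shipped coefficients. k_endo_* are fixed modeling constants (small
# background activities of the E. coli host); the three enzyme
# coefficients were calibrated with calibrate_rate_constants() against the
# reference endpoints (carveol/carvone activity assays, 24 and 49 mg/L,
# and the 16-h carvone titers 44 and 2.9 mg/L). See the package vignette.
DEFAULT_KINETIC_PARAMS <- list(
  k_p450 = 7.24129752e-07,
  k_cdh_carvone = 4.01540096e-05,
  k_cdh_branch = 3.98361e-05,
  k_endo_carveol = 1e-4,
  k_endo_carvone = 9e-4
)

#' Default calibrated rate coefficients
#'
#' The shipped coefficients reproduce the reference whole-cell endpoints:
#' carveol and carvone activity assays of the single-enzyme strains and
#' the 16-h carvone titers of the single-strain pathway variants.
#'
#' @return A [kinetic_params()] object.
#' @export
default_kinetic_params <- function() {
  do.call(kinetic_params, DEFAULT_KINETIC_PARAMS)
}

#' Population P450/CDH ratio of a two-strain mixture
#'
#' OD-weighted per-cell abundances, assuming equal cells per OD unit
#' across strains.
#'
#' @param profile_a,profile_b [enzyme_profile()]s of the two strains.
#' @param od_a,od_b Mixing proportions in OD600 units.
#' @return The pooled P450/CDH ratio; `Inf` (with no error) if the pooled
#'   CDH is zero.
#' @export
mixture_ratio <- function(profile_a, profile_b, od_a, od_b) {
  stopifnot(od_a >= 0, od_b >= 0, od_a + od_b > 0)
  p450 <- profile_a$p450 * od_a + profile_b$p450 * od_b
  cdh <- profile_a$cdh * od_a + profile_b$cdh * od_b
  if (cdh == 0) return(Inf)
  p450 / cdh
}

#' Pool two strains into an effective per-cell profile
#'
#' OD-weighted average of per-cell abundances, the profile "seen" by the
#' quantification pipeline when the mixed culture is digested as one
#' population.
#'
#' @inheritParams mixture_ratio
#' @param strain Label for the pooled profile.
#' @return An [enzyme_profile()].
#' @export
pool_profiles <- function(profile_a, profile_b, od_a, od_b, strain = "mix") {
  fa <- od_a / (od_a + od_b)
  fb <- 1 - fa
  enzyme_profile(
    p450 = profile_a$p450 * fa + profile_b$p450 * fb,
    cpr = profile_a$cpr * fa + profile_b$cpr * fb,
    cdh = profile_a$cdh * fa + profile_b$cdh * fb,
    endogenous = profile_a$endogenous * fa + profile_b$endogenous * fb,
    strain = strain
  )
}

#' Simulate whole-cell bioconversion of limonene to carvone
#'
#' Integrates the mass-action network in molar units with a fixed-step
#' 4th-order Runge-Kutta scheme and converts to mg/L. Reaction rates are
#' `k x enzyme copies per cell x OD600 x [substrate]`; the P450 step uses
#' the smaller of the P450 and CPR copy numbers, since hydroxylation
#' requires electron transfer from CPR.
#'
#' @param profile An [enzyme_profile()].
#' @param conditions A [reaction_conditions()].
#' @param params A [kinetic_params()]; defaults to the shipped calibrated
#'   coefficients.
#' @param step Integration step in hours (must be <= 0.01).
#' @return A tibble of class `timecourse` with columns `time_h` and one
#'   column per species in mg/L.
#' @export
simulate_bioconversion <- function(profile, conditions = reaction_conditions(),
                                   params = default_kinetic_params(),
                                   step = 0.0025) {
  stopifnot(inherits(profile, "enzyme_profile"),
            inherits(conditions, "reaction_conditions"),
            inherits(params, "kinetic_params"))
  if (step > 0.01) stop("integration step must be <= 0.01 h")
  mw <- SPECIES_MOLAR_MASS
  y0 <- c(limonene = 0, carveol = 0, carvone = 0, dihydrocarveol = 0,
          dihydrocarvone = 0)
  y0[conditions$substrate] <-
    conditions$substrate_mg_per_l / mw[[conditions$substrate]]
  od <- conditions$od600
  eff_p450 <- min(profile$p450, profile$cpr)
  rate <- c(
    r1 = params$k_p450 * eff_p450 * od,
    r2 = params$k_cdh_carvone * profile$cdh * od,
    r3 = params$k_cdh_branch * profile$cdh * od,
    r4 = params$k_endo_carveol * profile$endogenous * od,
    r5 = params$k_endo_carvone * profile$endogenous * od
  )
  rhs <- function(t, y, p) {
    f1 <- p[["r1"]] * y[["limonene"]]
    f2 <- p[["r2"]] * y[["carveol"]]
    f3 <- p[["r3"]] * y[["carveol"]]
    f4 <- p[["r4"]] * y[["carveol"]]
    f5 <- p[["r5"]] * y[["carvone"]]
    list(c(-f1, f1 - f2 - f3 - f4, f2 - f5, f3, f4 + f5))
  }
  times <- seq(0, conditions$duration_h, by = step)
  out <- deSolve::ode(y0, times, rhs, rate, method = "rk4")
  res <- tibble::as_tibble(as.data.frame(out))
  names(res)[1] <- "time_h"
  for (sp in names(mw)) res[[sp]] <- res[[sp]] * mw[[sp]]
  class(res) <- c("timecourse", class(res))
  res
}

#' Whole-cell activity from a simulated or measured time course
#'
#' Final product concentration per hour per OD600 unit, the standard
#' strain-level activity metric for whole-cell biocatalysts.
#'
#' @param timecourse A [simulate_bioconversion()] result (or any tibble
#'   with `time_h` and species columns in mg/L).
#' @param product Species name, e.g. `"carveol"` or `"carvone"`.
#' @param conditions The [reaction_conditions()] of the assay.
#' @return Activity in mg L^-1 h^-1 OD600^-1.
#' @export
whole_cell_activity <- function(timecourse, product, conditions) {
  if (!product %in% names(timecourse)) {
    stop("species not in timecourse: ", product)
  }
  if (conditions$duration_h <= 0) stop("duration must be positive")
  final <- timecourse[[product]][nrow(timecourse)]
  final / (conditions$duration_h * conditions$od600)
}

#' Calibrate rate coefficients against observed reaction endpoints
#'
#' Derivative-free least-squares fit (Nelder-Mead on log-coefficients) of
#' selected coefficients to observed endpoint concentrations. Each
#' scenario supplies an enzyme profile, reaction conditions and one or
#' more observed endpoint concentrations by species; the objective is the
#' sum of squared relative endpoint errors.
#'
#' @param scenarios List of lists with elements `profile`, `conditions`
#'   and `observed` (named vector, mg/L at the end of the reaction).
#' @param start A [kinetic_params()] starting point.
#' @param free Character vector of coefficient names to fit; the others
#'   are held at their `start` values. The number of observations must be
#'   at least the number of free coefficients.
#' @param step Integration step during fitting.
#' @param maxit,reltol Optimizer control.
#' @return List with `params` (fitted [kinetic_params()]), `residuals`
#'   (named relative endpoint errors) and `value` (objective).
#' @export
calibrate_rate_constants <- function(scenarios, start,
                                     free = c("k_p450", "k_cdh_carvone",
                                              "k_cdh_branch"),
                                     step = 0.005, maxit = 3000,
                                     reltol = 1e-13) {
  stopifnot(inherits(start, "kinetic_params"))
  n_obs <- sum(vapply(scenarios, function(s) length(s$observed), integer(1)))
  if (n_obs < length(free)) {
    stop("need at least as many observations (", n_obs,
         ") as free coefficients (", length(free), ")")
  }
  base <- unclass(start)
  endpoint_errors <- function(params, st) {
    unlist(lapply(scenarios, function(s) {
      tc <- simulate_bioconversion(s$profile, s$conditions, params, step = st)
      fin <- tc[nrow(tc), ]
      vapply(names(s$observed), function(sp)
        (fin[[sp]] - s$observed[[sp]]) / s$observed[[sp]], numeric(1))
    }))
  }
  obj <- function(x) {
    p <- base
    p[free] <- as.list(exp(x))
    sum(endpoint_errors(do.call(kinetic_params, p), step)^2)
  }
  fit <- stats::optim(log(unlist(base[free])), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  p <- base
  p[free] <- as.list(exp(fit$par))
  params <- do.call(kinetic_params, p)
  resid <- endpoint_errors(params, 0.0025)
  # convergence code 10 (simplex degeneracy at the optimum) is acceptable;
  # 1 means the iteration budget ran out
  if (fit$convergence == 1) {
    stop("calibration did not converge; residuals: ",
         paste(sprintf("%s=%.3g", names(resid), resid), collapse = ", "))
  }
  list(params = params, residuals = resid, value = fit$value)
}

#' Optimal P450/CDH ratio from a ratio-titer series
#'
#' Returns the ratio with the maximal product titer; ties break toward the
#' larger ratio, since excess CDH drives by-product formation.
#'
#' @param points Tibble or data.frame with columns `ratio` and `titer`.
#' @return List with `optimal_ratio`, `optimal_titer` and `table` (the
#'   input ranked by decreasing titer).
#' @export
optimum_ratio_analysis <- function(points) {
  if (is.null(nrow(points)) || nrow(points) == 0L) stop("empty input")
  stopifnot(all(c("ratio", "titer") %in% names(points)))
  ord <- order(-points$titer, -points$ratio)
  best <- points[ord[1], ]
  list(optimal_ratio = best$ratio, optimal_titer = best$titer,
       table = tibble::as_tibble(points[ord, ]))
}
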