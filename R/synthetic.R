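# Synthetic-data generators emulating the spheroid experiments: logistic /
# Lotka-Volterra growth with multiplicative lognormal measurement noise, the
# full 8-dose ribociclib panel, censored estradiol measurements, and
# (cells, area, fluorescence) calibration tables. Every generator is a pure
# function of its parameters and seed.

#' Measurement-noise specification
#'
#' Spheroid cell counts are strictly positive with roughly constant
#' coefficient of variation, so noise is multiplicative lognormal on the
#' latent model counts.
#'
#' @param sigma log-scale standard deviation (default 0.15).
#' @param seed integer seed; each generator call seeds its own stream.
#' @export
noise_spec <- function(sigma = 0.15, seed = 1L) {
  if (!is.numeric(sigma) || sigma < 0) stop_("sigma must be >= 0")
  structure(list(family = "lognormal", sigma = sigma,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

apply_lognormal <- function(x, sigma, seed, stream) {
  if (sigma == 0) return(x)
  set.seed(stream_seed(seed, stream))
  x * rlnorm(length(x), meanlog = 0, sdlog = sigma)
}

growth_rows <- function(cell_line, composition, lineage, replicate, day,
                        dose, count, modifier = "none", modifier_dose = 0) {
  data.frame(cell_line = cell_line, composition = composition,
             lineage = lineage, replicate = replicate, day = day,
             dose_nM = dose, modifier = modifier,
             modifier_dose_nM = modifier_dose, count = count,
             stringsAsFactors = FALSE)
}

#' Generate logistic monoculture growth trajectories
#'
#' Counts are the closed-form logistic solution times lognormal noise.
#'
#' @param r growth rate (1/day).
#' @param K carrying capacity (cells).
#' @param n0 abundance at the first day of the grid.
#' @param days sampling days.
#' @param reps number of replicates.
#' @param noise a [noise_spec()].
#' @param lineage lineage label of the monoculture.
#' @param dose recorded dose (the trajectory itself is governed by `r`).
#' @param cell_line cell-line label.
#' @param modifier,modifier_dose optional modifier annotation.
#' @return a validated growth table.
#' @export
gen_logistic <- function(r, K, n0, days, reps = 3,
                         noise = noise_spec(),
                         lineage = "sensitive", dose = 0,
                         cell_line = "synthetic",
                         modifier = "none", modifier_dose = 0) {
  if (n0 <= 0) stop_("n0 must be positive")
  if (K <= 0) stop_("carrying capacity must be positive")
  days <- sort(unique(days))
  latent <- logistic_growth(days - days[1], n0, r, K)
  composition <- if (lineage == "sensitive") 1 else 0
  out <- do.call(rbind, lapply(seq_len(reps), function(rep) {
    counts <- apply_lognormal(latent, noise$sigma, noise$seed,
                              sprintf("logistic/%s/%d/%g", lineage, rep, dose))
    growth_rows(cell_line, composition, lineage, rep, days, dose, counts,
                modifier, modifier_dose)
  }))
  validate_rows(out, "growth")
}

#' Generate Lotka-Volterra coculture trajectories
#'
#' Numerically integrates the two-species competition system and applies
#' lognormal noise per lineage and replicate.
#'
#' @param params a [competition_params()] object.
#' @param init length-2 vector `(S0, R0)` at the first day of the grid.
#' @param days sampling days.
#' @param reps replicates.
#' @param noise a [noise_spec()].
#' @param dose recorded dose.
#' @param cell_line cell-line label.
#' @return a validated growth table with both lineages.
#' @export
gen_lv_coculture <- function(params, init, days, reps = 3,
                             noise = noise_spec(), dose = 0,
                             cell_line = "synthetic") {
  stopifnot(inherits(params, "competition_params"))
  days <- sort(unique(days))
  tr <- lv_integrate(unclass(params), c(init[[1]], init[[2]]),
                     days[1], days, rtol = 1e-10, atol = 1e-10)
  composition <- init[[1]] / (init[[1]] + init[[2]])
  out <- do.call(rbind, lapply(seq_len(reps), function(rep) {
    cs <- apply_lognormal(tr$S, noise$sigma, noise$seed,
                          sprintf("lv/S/%d/%g", rep, dose))
    cr <- apply_lognormal(tr$R, noise$sigma, noise$seed,
                          sprintf("lv/R/%d/%g", rep, dose))
    rbind(growth_rows(cell_line, composition, "sensitive", rep, days, dose, cs),
          growth_rows(cell_line, composition, "resistant", rep, days, dose, cr))
  }))
  validate_rows(out, "growth")
}

#' Experimental design of the dose panel
#'
#' Defaults reproduce the study conditions: eight ribociclib doses in the
#' EC20-50 range, three compositions (pure sensitive, pure resistant,
#' 50:50), three replicates, 2000 plated cells, and imaging at 3- to 4-day
#' intervals over 21 days.
#'
#' @param doses dose grid (nM).
#' @param compositions initial sensitive fractions.
#' @param reps replicates per condition.
#' @param days sampling days (the fits use day 4 onward).
#' @param n0 total plated cells.
#' @export
panel_design <- function(doses = c(0, 100, 200, 400, 600, 800, 1000, 2000),
                         compositions = c(1, 0, 0.5), reps = 3,
                         days = c(4, 7, 11, 14, 18, 21), n0 = 2000) {
  if (length(doses) == 0) stop_("empty dose list")
  if (any(doses < 0)) stop_("doses must be >= 0")
  list(doses = doses, compositions = compositions, reps = reps,
       days = sort(unique(days)), n0 = n0)
}

#' Generate a full dose-panel from the mechanistic model
#'
#' Simulates the stage-structured consumer-resource model for every
#' dose x composition condition, observes `P + Z + X` per lineage at the
#' design days under lognormal noise, and records exact day-0 plating
#' counts (plating numbers are known, not measured).
#'
#' @param params a [mech_params()] object.
#' @param design a [panel_design()].
#' @param noise a [noise_spec()].
#' @param variant model variant to simulate from.
#' @return a validated growth table.
#' @export
gen_mechanistic_panel <- function(params, design = panel_design(),
                                  noise = noise_spec(),
                                  variant = "facilitation") {
  if (length(design$doses) == 0) stop_("empty dose list")
  rows <- list()
  for (dose in design$doses) {
    for (comp in design$compositions) {
      S0 <- design$n0 * comp
      R0 <- design$n0 * (1 - comp)
      tr <- simulate_spheroid(params, spheroid_state(S0, R0), dose,
                              c(0, design$days), variant = variant)
      tr <- tr[tr$day %in% design$days, , drop = FALSE]
      for (rep in seq_len(design$reps)) {
        if (S0 > 0) {
          cs <- apply_lognormal(tr$N_S, noise$sigma, noise$seed,
                                sprintf("panel/S/%g/%g/%d", dose, comp, rep))
          rows[[length(rows) + 1]] <- rbind(
            growth_rows("synthetic", comp, "sensitive", rep, 0, dose, S0),
            growth_rows("synthetic", comp, "sensitive", rep, tr$day, dose, cs))
        }
        if (R0 > 0) {
          cr <- apply_lognormal(tr$N_R, noise$sigma, noise$seed,
                                sprintf("panel/R/%g/%g/%d", dose, comp, rep))
          rows[[length(rows) + 1]] <- rbind(
            growth_rows("synthetic", comp, "resistant", rep, 0, dose, R0),
            growth_rows("synthetic", comp, "resistant", rep, tr$day, dose, cr))
        }
      }
    }
  }
  validate_rows(do.call(rbind, rows), "growth")
}

#' Generate censored estradiol measurements
#'
#' Concentrations follow the reduced production/uptake model
#' `f2 = (rho_R R + rho_S S) / (R + a_S S)` plus additive Gaussian assay
#' noise truncated at zero; readings below the detection limit are recorded
#' as 0 and flagged. Defaults are the fitted per-cell rates of the reduced
#' model.
#'
#' @param cultures `data.frame` with columns `s_cells`, `r_cells` and
#'   optionally `dose_nM` (default 0).
#' @param rho_R,rho_S per-cell production rates (pg/mL scale).
#' @param a_S uptake by sensitive cells relative to resistant cells.
#' @param noise_sd assay noise SD (pg/mL).
#' @param llod lower limit of detection (pg/mL).
#' @param seed RNG seed.
#' @return a validated estradiol table.
#' @export
gen_estradiol <- function(cultures, rho_R = 96.79, rho_S = 11.71,
                          a_S = 0.400, noise_sd = 15, llod = 62.5,
                          seed = 1L) {
  if (llod <= 0) stop_("llod must be positive")
  if (any(c(rho_R, rho_S, a_S) < 0)) stop_("rates must be >= 0")
  S <- cultures$s_cells; R <- cultures$r_cells
  if (any(R + a_S * S <= 0))
    stop_("culture with zero effective cells: f2 undefined")
  mu <- (rho_R * R + rho_S * S) / (R + a_S * S)
  set.seed(stream_seed(seed, "estradiol"))
  conc <- pmax(mu + rnorm(length(mu), 0, noise_sd), 0)
  conc[conc < llod] <- 0
  out <- data.frame(
    sample_id = sprintf("SYN%03d", seq_along(conc)),
    s_cells = S, r_cells = R,
    dose_nM = cultures$dose_nM %||% rep(0, length(conc)),
    estradiol_pg_ml = conc, stringsAsFactors = FALSE)
  validate_rows(out, "estradiol")
}

#' Generate a calibration table
#'
#' Spheroid area follows the supplied standard curve at the total cell
#' number; each channel's fluorescence is linear in its lineage's cell
#' number. Lognormal noise is applied to area and fluorescence; a noiseless
#' table is exactly invertible by the calibration module.
#'
#' @param curve an [area_curve()].
#' @param fluor_slopes length-2 vector `(slope_S, slope_R)`, intensity per
#'   cell.
#' @param grid `data.frame` with columns `n_sensitive`, `n_resistant`.
#' @param noise a [noise_spec()] (`sigma = 0` for a noiseless table).
#' @return a validated calibration table.
#' @export
gen_calibration <- function(curve, fluor_slopes, grid,
                            noise = noise_spec(sigma = 0)) {
  if (any(grid$n_sensitive < 0 | grid$n_resistant < 0))
    stop_("cell-number grid must be non-negative")
  if (any(fluor_slopes <= 0)) stop_("fluorescence slopes must be positive")
  N <- grid$n_sensitive + grid$n_resistant
  area <- predict(curve, N)
  fs <- fluor_slopes[[1]] * grid$n_sensitive
  fr <- fluor_slopes[[2]] * grid$n_resistant
  out <- data.frame(
    n_sensitive = grid$n_sensitive, n_resistant = grid$n_resistant,
    area = apply_lognormal(area, noise$sigma, noise$seed, "calib/area"),
    fluor_s = apply_lognormal(fs, noise$sigma, noise$seed, "calib/fs"),
    fluor_r = apply_lognormal(fr, noise$sigma, noise$seed, "calib/fr"))
  validate_rows(out, "calibration")
}
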