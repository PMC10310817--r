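# Stage-structured consumer-resource model of spheroid coculture.
#
# Proliferative (P), quiescent (Z) and senescent (X) cells of each lineage
# compete through a shared carrying-capacity term and the sensitive lineage
# is facilitated by extracellular estradiol (E_E) secreted mostly by
# resistant cells. CDK4/6 inhibition (ribociclib, dose x) diverts cells
# entering the G1/S checkpoint into quiescence with saturating dose response
# x / (k_i + x).

.mech_order <- c("r_S", "r_R", "lambda_S", "lambda_R", "phi_S", "phi_R",
                 "delta_S", "delta_R", "k_S", "k_R", "K_S", "K_R",
                 "gamma_S", "gamma_R", "rho_S", "rho_R", "mu_S", "mu_R",
                 "eta", "c", "sigma_E", "delta_E", "nu", "k_nu")

.mech_variants <- c(facilitation = 1L, competition_only = 2L,
                    plasticity_induced = 3L, plasticity_random = 4L)

#' Parameters of the stage-structured consumer-resource model
#'
#' Returns the full parameter set with defaults describing the regime the
#' experiments operate in: sensitive cells divide faster but are far more
#' drug-sensitive, resistant cells are less competitive, quiesce less, and
#' secrete several-fold more estradiol. All rates are per day; doses in nM;
#' capacities in cells.
#'
#' @param r_S,r_R baseline G1/S entry rates (1/day).
#' @param lambda_S,lambda_R baseline quiescence rates (1/day).
#' @param phi_S,phi_R quiescent-to-senescent transition rates (1/day).
#' @param delta_S,delta_R senescent death rates (1/day).
#' @param k_S,k_R ribociclib dose of half-maximal cell-cycle arrest (nM).
#' @param K_S,K_R competitive carrying capacities (cells).
#' @param gamma_S,gamma_R net estradiol secretion per (P + Z) cell
#'   (concentration/day).
#' @param rho_S,rho_R intracellular estradiol production rates.
#' @param mu_S,mu_R receptor binding (utilisation) rates.
#' @param eta cell/medium diffusion rate of the facilitation factor.
#' @param c saturation constant of the facilitation benefit.
#' @param sigma_E external estradiol influx (only enters the fast
#'   intracellular/extracellular flux subsystem).
#' @param delta_E extracellular decay rate (1/day).
#' @param nu,k_nu sensitive-to-resistant switching rate and half-max dose of
#'   the phenotypic-plasticity model variants.
#' @return an object of class `mech_params` (a validated named list).
#' @export
mech_params <- function(r_S = 0.5, r_R = 0.25,
                        lambda_S = 0.12, lambda_R = 0.05,
                        phi_S = 0.1, phi_R = 0.1,
                        delta_S = 0.1, delta_R = 0.1,
                        k_S = 200, k_R = 1000,
                        K_S = 2e4, K_R = 1.2e4,
                        gamma_S = 5e-4, gamma_R = 1e-3,
                        rho_S = 0.1, rho_R = 0.2,
                        mu_S = 0.5, mu_R = 0.1,
                        eta = 1, c = 1,
                        sigma_E = 0, delta_E = 1,
                        nu = 0.05, k_nu = 500) {
  p <- as.list(environment())[.mech_order]
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_("all mechanistic parameters must be finite and >= 0")
  if (p$k_S <= 0 || p$k_R <= 0) stop_("half-max doses k_i must be > 0")
  if (p$K_S <= 0 || p$K_R <= 0) stop_("carrying capacities K_i must be > 0")
  structure(p, class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("Consumer-resource model parameters (S = sensitive, R = resistant)\n")
  v <- unlist(x)
  print(signif(v, 4))
  invisible(x)
}

as_param_vector <- function(params) {
  stopifnot(inherits(params, "mech_params"))
  unlist(params)[.mech_order]
}

#' Initial spheroid state
#'
#' All plated cells start proliferative, with no extracellular estradiol
#' (fresh medium).
#'
#' @param S0,R0 plated sensitive and resistant cell counts.
#' @return named numeric state vector (P_S, Z_S, X_S, P_R, Z_R, X_R, E_E).
#' @export
spheroid_state <- function(S0, R0) {
  if (S0 < 0 || R0 < 0) stop_("initial counts must be >= 0")
  c(P_S = S0, Z_S = 0, X_S = 0, P_R = R0, Z_R = 0, X_R = 0, E_E = 0)
}

#' Dose response of drug-induced quiescence
#'
#' Fraction of G1/S-entering cells diverted into quiescence at ribociclib
#' dose `x`: `q = x / (k + x)`. Zero without treatment, half-maximal at
#' `x = k`, saturating at complete arrest.
#'
#' @param x dose (nM), non-negative.
#' @param k half-maximal dose (nM), positive.
#' @export
quiescence_fraction <- function(x, k) {
  if (any(x < 0)) stop_("dose must be non-negative")
  if (any(k <= 0)) stop_("half-max dose must be positive")
  x / (k + x)
}

#' Shared competition term
#'
#' `alpha = 1 - N_S/K_S - N_R/K_R` where `N_i = P_i + Z_i + X_i`. All stages
#' occupy space; competitive ability is set by the capacity parameters.
#'
#' @param state spheroid state vector (see [spheroid_state()]).
#' @param K_S,K_R carrying capacities.
#' @export
competition_term <- function(state, K_S, K_R) {
  N_S <- state[["P_S"]] + state[["Z_S"]] + state[["X_S"]]
  N_R <- state[["P_R"]] + state[["Z_R"]] + state[["X_R"]]
  1 - N_S / K_S - N_R / K_R
}

#' Quasi-steady-state intracellular estradiol
#'
#' Intracellular concentration given the (slowly varying) extracellular pool:
#' `E_i = (rho_i + eta * E_E) / (eta + mu_i)`. The fast intracellular
#' dynamics are assumed equilibrated relative to population growth.
#'
#' @param params a [mech_params()] object.
#' @param E_E extracellular concentration.
#' @param lineage `"sensitive"` or `"resistant"`.
#' @export
intracellular_qss <- function(params, E_E, lineage = c("sensitive", "resistant")) {
  lineage <- match.arg(lineage)
  sfx <- if (lineage == "sensitive") "S" else "R"
  eta <- params$eta
  mu <- params[[paste0("mu_", sfx)]]
  rho <- params[[paste0("rho_", sfx)]]
  if (eta + mu <= 0) stop_("eta + mu must be positive")
  (rho + eta * E_E) / (eta + mu)
}

#' Equilibrium of the estradiol flux subsystem
#'
#' Closed-form fixed point of the intracellular/extracellular flux equations
#' at fixed cell numbers `S` and `R`: production (`rho_i`, influx `sigma_E`)
#' balanced against receptor binding (`mu_i`) and extracellular decay
#' (`delta_E`), with diffusive exchange at rate `eta`.
#'
#' @param params a [mech_params()] object.
#' @param S,R fixed sensitive and resistant cell numbers.
#' @return named vector `(E_E, E_S, E_R)`.
#' @export
estradiol_equilibrium <- function(params, S, R) {
  eta <- params$eta
  wS <- eta / (eta + params$mu_S)
  wR <- eta / (eta + params$mu_R)
  num <- params$sigma_E + params$rho_S * S * wS + params$rho_R * R * wR
  den <- eta * S * params$mu_S / (eta + params$mu_S) +
    eta * R * params$mu_R / (eta + params$mu_R) + params$delta_E
  if (den <= 0) stop_("flux subsystem has no finite equilibrium (zero sinks)")
  E_E <- num / den
  c(E_E = E_E,
    E_S = intracellular_qss(params, E_E, "sensitive"),
    E_R = intracellular_qss(params, E_E, "resistant"))
}

#' G1/S checkpoint entry rate
#'
#' `G_i = r_i * (1 + mu_i E_i / (1 + c mu_i E_i)) * alpha(P, Z, X)`, with
#' `E_i` at quasi-steady state given the extracellular concentration in
#' `state`, and the competition term clamped at zero (checkpoint entry
#' cannot be negative when the spheroid transiently overshoots capacity).
#'
#' @inheritParams intracellular_qss
#' @param state spheroid state vector including `E_E`.
#' @export
g1s_entry_rate <- function(params, state, lineage = c("sensitive", "resistant")) {
  lineage <- match.arg(lineage)
  sfx <- if (lineage == "sensitive") "S" else "R"
  E_i <- intracellular_qss(params, state[["E_E"]], lineage)
  mu <- params[[paste0("mu_", sfx)]]
  r <- params[[paste0("r_", sfx)]]
  me <- mu * E_i
  alpha <- max(competition_term(state, params$K_S, params$K_R), 0)
  r * (1 + me / (1 + params$c * me)) * alpha
}

#' Simulate spheroid growth
#'
#' Integrates the 7-state system (P/Z/X per lineage plus extracellular
#' estradiol) with an adaptive Dormand-Prince RK45 integrator at relative
#' tolerance `rtol`. States are clipped at zero (clip events are counted in
#' the `n_clipped` attribute).
#'
#' @param params a [mech_params()] object.
#' @param init initial state from [spheroid_state()].
#' @param dose constant ribociclib dose (nM).
#' @param days output time grid (days); integration starts at `t0`.
#' @param variant one of `"facilitation"` (full model),
#'   `"competition_only"` (secretion and binding off),
#'   `"plasticity_induced"` / `"plasticity_random"` (facilitation off,
#'   sensitive-to-resistant switching on).
#' @param t0 start time of the integration.
#' @param rtol,atol integrator tolerances.
#' @return a `data.frame` of class `spheroid_sim` with columns `day`, the
#'   seven states, and totals `N_S`, `N_R`.
#' @export
simulate_spheroid <- function(params, init, dose, days,
                              variant = "facilitation",
                              t0 = 0, rtol = 1e-8, atol = 1e-8) {
  if (!variant %in% names(.mech_variants))
    stop_("unknown model variant '%s'", variant)
  if (length(days) == 0) stop_("empty output time grid")
  if (dose < 0) stop_("dose must be non-negative")
  days <- sort(unique(as.numeric(days)))
  m <- cpp_simulate(as_param_vector(params), .mech_variants[[variant]],
                    as.numeric(init), dose, t0, days, rtol, atol)
  out <- data.frame(day = days, m)
  names(out) <- c("day", "P_S", "Z_S", "X_S", "P_R", "Z_R", "X_R", "E_E")
  out$N_S <- out$P_S + out$Z_S + out$X_S
  out$N_R <- out$P_R + out$Z_R + out$X_R
  attr(out, "n_clipped") <- attr(m, "n_clipped")
  attr(out, "variant") <- variant
  attr(out, "dose") <- dose
  class(out) <- c("spheroid_sim", "data.frame")
  out
}

#' @rdname simulate_spheroid
#' @export
simulate_variant <- function(variant, params, init, dose, days, ...) {
  simulate_spheroid(params, init, dose, days, variant = variant, ...)
}

#' Decompose G1/S entry into facilitation and competition components
#'
#' For each dose, simulates the coculture and evaluates, along the
#' trajectory, the facilitation component `F = mu E /(1 + c mu E)` and the
#' competition term `alpha` of the focal lineage's checkpoint-entry rate.
#' The normalised share `F / (F + (1 - alpha))` is bright exactly when the
#' facilitation benefit is large while crowding is not yet limiting - the
#' facilitation window.
#'
#' @param params a [mech_params()] object.
#' @param init initial state.
#' @param doses dose grid (nM).
#' @param days time grid (days).
#' @param lineage focal lineage (default sensitive).
#' @return `data.frame` with columns `dose`, `day`, `facilitation`,
#'   `competition` (alpha), `ratio` and `share`.
#' @export
decompose_g1s <- function(params, init, doses, days,
                          lineage = c("sensitive", "resistant")) {
  lineage <- match.arg(lineage)
  sfx <- if (lineage == "sensitive") "S" else "R"
  mu <- params[[paste0("mu_", sfx)]]
  out <- lapply(doses, function(x) {
    tr <- simulate_spheroid(params, init, x, days)
    E_i <- (params[[paste0("rho_", sfx)]] + params$eta * tr$E_E) /
      (params$eta + mu)
    me <- mu * E_i
    fac <- me / (1 + params$c * me)
    alpha <- 1 - tr$N_S / params$K_S - tr$N_R / params$K_R
    data.frame(dose = x, day = tr$day, facilitation = fac,
               competition = alpha,
               ratio = fac / pmax(1 - alpha, .Machine$double.eps),
               share = fac / (fac + pmax(1 - alpha, 0)))
  })
  do.call(rbind, out)
}

#' Predicted effect of facilitation-blocking therapy
#'
#' Reduces the receptor binding rates of both lineages by a factor `zeta`
#' (mimicking ER-antagonist exposure held constant over the run) and reports
#' final abundances after `horizon` days for every (dose, zeta) pair.
#'
#' @param params a [mech_params()] object.
#' @param init initial state.
#' @param doses dose grid (nM).
#' @param zeta blocking factors in `[0, 1]` (the experiments explore 0-0.8).
#' @param horizon final day (default 21).
#' @return `data.frame` with columns `dose`, `zeta`, `N_S`, `N_R`, `total`.
#' @export
blocking_prediction <- function(params, init, doses, zeta, horizon = 21) {
  if (any(zeta < 0 | zeta > 1)) stop_("zeta must lie in [0, 1]")
  grid <- expand.grid(dose = doses, zeta = zeta)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$mu_S <- params$mu_S * (1 - grid$zeta[i])
    p$mu_R <- params$mu_R * (1 - grid$zeta[i])
    tr <- simulate_spheroid(p, init, grid$dose[i], c(0, horizon))
    tail_row <- tr[nrow(tr), ]
    data.frame(dose = grid$dose[i], zeta = grid$zeta[i],
               N_S = tail_row$N_S, N_R = tail_row$N_R,
               total = tail_row$N_S + tail_row$N_R)
  })
  do.call(rbind, res)
}

#' @export
plot.spheroid_sim <- function(x, ...) {
  graphics::matplot(x$day, cbind(x$N_S, x$N_R), type = "l", lty = 1,
                    col = c("forestgreen", "steelblue"),
                    xlab = "day", ylab = "cells", ...)
  graphics::legend("topleft", c("sensitive", "resistant"), lty = 1,
                   col = c("forestgreen", "steelblue"), bty = "n")
  invisible(x)
}
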