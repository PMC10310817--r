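# Shared fixtures, built in code.

quiet_noise <- function(seed = 1L) noise_spec(sigma = 0, seed = seed)

# small coculture LV parameter set in the regime the experiments describe:
# sensitive faster and dominant, resistant barely affecting sensitive cells
lv_fixture <- function(alpha_SR = 0.1, alpha_RS = 1.5) {
  competition_params(r_S = 0.35, K_S = 2e4, r_R = 0.2, K_R = 1.2e4,
                     alpha_SR = alpha_SR, alpha_RS = alpha_RS)
}

# independent LV integration with a different integrator (oracle)
lv_oracle <- function(params, init, t0, days, method = "ode45") {
  rhs <- function(t, y, p) {
    S <- y[1]; R <- y[2]
    list(c(p$r_S * (1 - (S + p$alpha_SR * R) / p$K_S) * S,
           p$r_R * (1 - (p$alpha_RS * S + R) / p$K_R) * R))
  }
  times <- sort(unique(c(t0, days)))
  sol <- deSolve::ode(y = c(S = init[[1]], R = init[[2]]), times = times,
                      func = rhs, parms = unclass(params), method = method,
                      rtol = 1e-11, atol = 1e-11)
  as.data.frame(sol)[match(days, times), ]
}

# independent integration of the full 7-state consumer-resource system
# (deSolve, written directly from the model equations)
mech_oracle <- function(params, init, dose, days, variant = "facilitation") {
  p <- params
  rhs <- function(t, y, parms) {
    P_S <- y[1]; Z_S <- y[2]; X_S <- y[3]
    P_R <- y[4]; Z_R <- y[5]; X_R <- y[6]; E_E <- y[7]
    alpha <- max(1 - (P_S + Z_S + X_S) / p$K_S - (P_R + Z_R + X_R) / p$K_R, 0)
    fac <- function(rho, mu) {
      if (variant != "facilitation") return(0)
      me <- mu * (rho + p$eta * E_E) / (p$eta + mu)
      me / (1 + p$c * me)
    }
    G_S <- p$r_S * (1 + fac(p$rho_S, p$mu_S)) * alpha
    G_R <- p$r_R * (1 + fac(p$rho_R, p$mu_R)) * alpha
    q_S <- dose / (p$k_S + dose); q_R <- dose / (p$k_R + dose)
    dP_S <- (G_S * (1 - 2 * q_S) - p$lambda_S) * P_S
    dP_R <- (G_R * (1 - 2 * q_R) - p$lambda_R) * P_R
    sw <- if (variant == "plasticity_random") p$nu else
      if (variant == "plasticity_induced") p$nu * dose / (p$k_nu + dose) else 0
    dP_S <- dP_S - sw * P_S; dP_R <- dP_R + sw * P_S
    dE <- if (variant == "facilitation")
      p$gamma_S * (P_S + Z_S) + p$gamma_R * (P_R + Z_R) - p$delta_E * E_E
    else -p$delta_E * E_E
    list(c(dP_S,
           (G_S * q_S + p$lambda_S) * P_S - p$phi_S * Z_S,
           p$phi_S * Z_S - p$delta_S * X_S,
           dP_R,
           (G_R * q_R + p$lambda_R) * P_R - p$phi_R * Z_R,
           p$phi_R * Z_R - p$delta_R * X_R,
           dE))
  }
  times <- sort(unique(c(0, days)))
  sol <- deSolve::ode(y = as.numeric(init), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  out <- as.data.frame(sol)[match(days, times), ]
  names(out) <- c("day", "P_S", "Z_S", "X_S", "P_R", "Z_R", "X_R", "E_E")
  out
}
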