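test_that("dose response of quiescence is saturating with half-max at k", {
  expect_equal(quiescence_fraction(0, 200), 0)
  expect_equal(quiescence_fraction(200, 200), 0.5)
  expect_equal(quiescence_fraction(9 * 200, 200), 0.9)
  expect_error(quiescence_fraction(-1, 200), "non-negative")
})

test_that("the shared competition term counts all stages against capacity", {
  expect_equal(competition_term(spheroid_state(0, 0), 2e4, 1.2e4), 1)
  st <- c(P_S = 1e4, Z_S = 5e3, X_S = 5e3, P_R = 0, Z_R = 0, X_R = 0, E_E = 0)
  expect_equal(competition_term(st, 2e4, 1.2e4), 0)
  st2 <- c(P_S = 1e4, Z_S = 0, X_S = 0, P_R = 6e3, Z_R = 0, X_R = 0, E_E = 0)
  expect_equal(competition_term(st2, 2e4, 1.2e4), 0)
})

test_that("quasi-steady-state intracellular estradiol has the stated limits", {
  p <- mech_params(rho_S = 2, mu_S = 0.5, eta = 0)
  expect_equal(intracellular_qss(p, E_E = 10, "sensitive"), 2 / 0.5)
  p2 <- mech_params(rho_S = 0, mu_S = 1e-9, eta = 1e6)
  expect_equal(intracellular_qss(p2, E_E = 3.7, "sensitive"), 3.7,
               tolerance = 1e-6)
})

test_that("flux equilibrium matches long-time integration of the full subsystem", {
  set.seed(14)
  for (i in 1:100) {
    p <- mech_params(rho_S = runif(1, 0, 5), rho_R = runif(1, 0, 5),
                     mu_S = runif(1, 0.05, 2), mu_R = runif(1, 0.05, 2),
                     eta = runif(1, 0.2, 3), sigma_E = runif(1, 0, 2),
                     delta_E = runif(1, 0.2, 2))
    S <- runif(1, 10, 5000); R <- runif(1, 10, 5000)
    eq <- estradiol_equilibrium(p, S, R)
    rhs <- function(t, y, parms) {
      list(c(p$rho_S + p$eta * (y[3] - y[1]) - p$mu_S * y[1],
             p$rho_R + p$eta * (y[3] - y[2]) - p$mu_R * y[2],
             p$sigma_E + p$eta * S * (y[1] - y[3]) +
               p$eta * R * (y[2] - y[3]) - p$delta_E * y[3]))
    }
    sol <- deSolve::lsoda(c(0, 0, 0), times = c(0, 2000), func = rhs,
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    final <- sol[2, 2:4]
    expect_equal(unname(final[3]), unname(eq[["E_E"]]), tolerance = 1e-6)
    expect_equal(unname(final[1]), unname(eq[["E_S"]]), tolerance = 1e-6)
    expect_equal(unname(final[2]), unname(eq[["E_R"]]), tolerance = 1e-6)
  }
})

test_that("checkpoint entry rate matches direct evaluation on random draws", {
  set.seed(6)
  for (i in 1:100) {
    p <- mech_params(r_S = runif(1, 0.1, 1), mu_S = runif(1, 0.05, 2),
                     rho_S = runif(1, 0, 3), eta = runif(1, 0.2, 3),
                     c = runif(1, 0.2, 3))
    st <- c(P_S = runif(1, 0, 1e4), Z_S = runif(1, 0, 5e3),
            X_S = runif(1, 0, 5e3), P_R = runif(1, 0, 1e4),
            Z_R = runif(1, 0, 5e3), X_R = runif(1, 0, 5e3),
            E_E = runif(1, 0, 20))
    Ei <- (p$rho_S + p$eta * st[["E_E"]]) / (p$eta + p$mu_S)
    alpha <- max(1 - sum(st[1:3]) / p$K_S - sum(st[4:6]) / p$K_R, 0)
    direct <- p$r_S * (1 + p$mu_S * Ei / (1 + p$c * p$mu_S * Ei)) * alpha
    expect_equal(g1s_entry_rate(p, st, "sensitive"), direct,
                 tolerance = 1e-12)
  }
  # saturation limit: E -> Inf gives r (1 + 1/c) alpha
  p <- mech_params(c = 2)
  st <- spheroid_state(0, 0); st[["E_E"]] <- 1e12
  expect_equal(g1s_entry_rate(p, st, "sensitive"),
               p$r_S * (1 + 1 / p$c), tolerance = 1e-6)
  st0 <- spheroid_state(0, 0)
  p0 <- mech_params(rho_S = 0)
  expect_equal(g1s_entry_rate(p0, st0, "sensitive"), p0$r_S)
})

test_that("the compiled integrator agrees with an independent reference solution", {
  p <- mech_params()
  init <- spheroid_state(1000, 1000)
  days <- c(4, 7, 11, 14, 18, 21)
  for (dose in c(0, 400, 2000)) {
    tr <- simulate_spheroid(p, init, dose, days, rtol = 1e-10, atol = 1e-10)
    orc <- mech_oracle(p, init, dose, days)
    for (col in c("P_S", "Z_S", "X_S", "P_R", "Z_R", "X_R", "E_E"))
      expect_equal(tr[[col]], orc[[col]], tolerance = 1e-6)
  }
})

test_that("integrator tolerances are converged at day 21", {
  p <- mech_params()
  init <- spheroid_state(1000, 1000)
  a <- simulate_spheroid(p, init, 400, c(0, 21), rtol = 1e-8, atol = 1e-8)
  b <- simulate_spheroid(p, init, 400, c(0, 21), rtol = 5e-9, atol = 5e-9)
  expect_equal(a$N_S[2] / b$N_S[2], 1, tolerance = 1e-6)
  expect_equal(a$N_R[2] / b$N_R[2], 1, tolerance = 1e-6)
})

test_that("variant nesting holds: facilitation with secretion/binding off equals competition-only", {
  p <- mech_params(gamma_S = 0, gamma_R = 0, mu_S = 0, mu_R = 0, rho_S = 0,
                   rho_R = 0)
  init <- spheroid_state(1000, 1000)
  days <- c(4, 11, 21)
  a <- simulate_spheroid(p, init, 400, days, variant = "facilitation")
  b <- simulate_spheroid(p, init, 400, days, variant = "competition_only")
  expect_identical(a$N_S, b$N_S)
  expect_identical(a$N_R, b$N_R)
  # plasticity with zero switching also reduces to competition-only
  p2 <- mech_params(nu = 0)
  c1 <- simulate_spheroid(p2, init, 400, days, variant = "plasticity_random")
  c2 <- simulate_spheroid(p2, init, 400, days, variant = "competition_only")
  expect_identical(c1$N_S, c2$N_S)
  # induced switching at dose zero equals random switching with nu = 0
  p3 <- mech_params(nu = 0.2)
  d1 <- simulate_spheroid(p3, init, 0, days, variant = "plasticity_induced")
  d2 <- simulate_spheroid(p2, init, 0, days, variant = "plasticity_random")
  expect_equal(d1$N_S, d2$N_S, tolerance = 1e-10)
  expect_equal(d1$N_R, d2$N_R, tolerance = 1e-10)
  expect_error(simulate_spheroid(p, init, 400, days, variant = "nope"),
               "unknown")
})

test_that("all states stay non-negative along trajectories", {
  p <- mech_params()
  init <- spheroid_state(1500, 500)
  for (dose in c(0, 600, 2000)) {
    tr <- simulate_spheroid(p, init, dose, seq(0, 21, by = 0.5))
    expect_true(all(as.matrix(tr[, 2:8]) >= 0))
  }
  z <- simulate_spheroid(mech_params(), spheroid_state(0, 0), 100, c(0, 5, 10))
  expect_true(all(z$N_S == 0 & z$N_R == 0))
})

test_that("monoculture day-21 abundance is non-increasing in dose", {
  p <- mech_params()
  doses <- c(0, 100, 200, 400, 600, 800, 1000, 2000)
  for (comp in c(1, 0)) {
    init <- spheroid_state(2000 * comp, 2000 * (1 - comp))
    final <- vapply(doses, function(x) {
      tr <- simulate_spheroid(p, init, x, c(0, 21))
      tr$N_S[2] + tr$N_R[2]
    }, numeric(1))
    expect_true(all(diff(final) <= 1e-6 * final[-length(final)]))
  }
})

test_that("high-dose coculture grows first and then shrinks", {
  p <- mech_params()
  tr <- simulate_spheroid(p, spheroid_state(1000, 1000), 2000, 0:21)
  tot <- tr$N_S + tr$N_R
  peak <- which.max(tot)
  expect_gt(tot[peak], tot[1] * 1.05)        # initial growth phase
  expect_true(peak > 1 && peak < length(tot)) # interior maximum
  expect_lt(tot[length(tot)], 0.75 * tot[peak]) # delayed shrinkage
})

test_that("the facilitation window sits below 600 nM and closes at high dose", {
  p <- mech_params()
  init <- spheroid_state(1000, 1000)
  doses <- c(0, 100, 200, 400, 600, 800, 1000, 2000)
  dec <- decompose_g1s(p, init, doses, seq(0, 21, 0.5))
  expect_true(all(dec$facilitation >= 0 & dec$facilitation <= 1))
  # window: facilitation benefit while crowding is not yet limiting
  dec$band <- dec$facilitation * (dec$competition > 0.15)
  peak_day <- vapply(doses, function(x) {
    d <- dec[dec$dose == x, ]
    d$day[which.max(d$band)]
  }, numeric(1))
  peak_val <- vapply(doses, function(x) max(dec$band[dec$dose == x]),
                     numeric(1))
  # at moderate doses the window opens late and stays open; it shifts later
  # as dose increases from 0
  expect_true(all(peak_day[doses %in% c(100, 200, 400, 600)] >= 15))
  expect_gt(peak_day[2], peak_day[1])
  # above 600 nM the late window is gone: the residual peak is early and weak
  expect_true(all(peak_day[doses >= 800] <= 10))
  expect_true(all(peak_val[doses >= 800] < 0.62 * peak_val[doses == 200]))
  # no estradiol signal anywhere: the facilitation component vanishes
  p0 <- mech_params(gamma_S = 0, gamma_R = 0, rho_S = 0, rho_R = 0)
  dec0 <- decompose_g1s(p0, init, c(0, 400), c(0, 10, 21))
  expect_true(all(dec0$facilitation == 0))
})

test_that("facilitation blocking only bites beyond 50% receptor inhibition", {
  p <- mech_params()
  init <- spheroid_state(1000, 1000)
  bl <- blocking_prediction(p, init, doses = c(100, 200, 400, 600),
                            zeta = c(0, 0.3, 0.5, 0.8))
  base <- bl[bl$zeta == 0, ]
  rel <- function(z) bl$total[bl$zeta == z] / base$total
  expect_equal(rel(0), rep(1, 4))
  # moderate blocking: under 10% size reduction everywhere
  expect_true(all(rel(0.3) > 0.9))
  expect_true(all(rel(0.5) > 0.9))
  # strong blocking: substantial reduction at facilitation-dependent doses
  expect_true(any(rel(0.8) < 0.9))
  # saturation: the marginal effect grows with zeta
  expect_true(all(1 - rel(0.8) > 1.5 * (1 - rel(0.5))))
  # at low dose, sensitive cells lose proportionally more than resistant
  b100 <- bl[bl$dose == 100, ]
  relS <- b100$N_S[b100$zeta == 0.8] / b100$N_S[b100$zeta == 0]
  relR <- b100$N_R[b100$zeta == 0.8] / b100$N_R[b100$zeta == 0]
  expect_lt(relS, relR)
  expect_error(blocking_prediction(p, init, 100, zeta = 1.2), "zeta")
})
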