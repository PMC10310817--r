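days6 <- c(4, 7, 11, 14, 18, 21)

test_that("logistic fits recover noiseless generating parameters exactly", {
  tab <- gen_logistic(r = 0.2, K = 2e4, n0 = 600, days = days6, reps = 3,
                      noise = quiet_noise())
  fit <- fit_logistic(tab, "sensitive")
  expect_equal(fit$r, 0.2, tolerance = 1e-6)
  expect_equal(fit$K, 2e4, tolerance = 1e-5)
  expect_equal(fit$n0, 600)
  expect_equal(fit$t0, 4)

  flat <- gen_logistic(r = 0, K = 2e4, n0 = 600, days = days6, reps = 2,
                       noise = quiet_noise())
  expect_equal(fit_logistic(flat, "sensitive")$r, 0)
  expect_error(fit_logistic(tab[tab$day <= 7, ], "sensitive"), "3 time points")
})

test_that("logistic fit is at least as good as a brute-force grid optimum", {
  tab <- gen_logistic(r = 0.25, K = 1.5e4, n0 = 500, days = days6, reps = 3,
                      noise = noise_spec(0.1, seed = 21))
  d <- tab[tab$day >= 4, ]
  n0 <- mean(d$count[d$day == 4])
  rss <- function(r, K) sum((d$count - logistic_growth(d$day - 4, n0, r, K))^2)
  grid <- expand.grid(r = seq(0.05, 0.6, by = 0.01),
                      K = seq(5e3, 4e4, by = 500))
  grid_best <- min(mapply(rss, grid$r, grid$K))
  fit <- fit_logistic(tab, "sensitive")
  expect_lte(fit$rss, grid_best + 1e-8)
})

test_that("treated growth rate is recovered with K inherited from the untreated fit", {
  K <- 2e4
  treated <- gen_logistic(r = 0.05, K = K, n0 = 700, days = days6, reps = 3,
                          noise = quiet_noise(), dose = 400)
  fit <- fit_treated_growth(treated, "sensitive", K_fixed = K)
  expect_equal(fit$rate, 0.05, tolerance = 1e-6)
  expect_equal(fit$K_fixed, K)

  # a null treatment returns the untreated rate
  untr <- gen_logistic(r = 0.3, K = K, n0 = 700, days = days6, reps = 3,
                       noise = quiet_noise())
  expect_equal(fit_treated_growth(untr, "sensitive", K)$rate, 0.3,
               tolerance = 1e-6)

  # declining series under strong treatment: negative rate allowed
  decl <- gen_logistic(r = -0.1, K = K, n0 = 700, days = days6, reps = 2,
                       noise = quiet_noise(), dose = 2000)
  expect_equal(fit_treated_growth(decl, "sensitive", K)$rate, -0.1,
               tolerance = 1e-6)
})

test_that("drug effect ordering matches the biology: sensitive hit much harder", {
  # growth-rate reduction factors: sensitive ~7.8x, resistant ~1.25x
  base <- list(S = 0.39, R = 0.25)
  treatedS <- gen_logistic(base$S / 7.8, 2e4, 700, days6, 3, quiet_noise(),
                           lineage = "sensitive", dose = 400)
  treatedR <- gen_logistic(base$R / 1.25, 1.2e4, 700, days6, 3, quiet_noise(),
                           lineage = "resistant", dose = 400)
  fS <- fit_treated_growth(treatedS, "sensitive", 2e4)
  fR <- fit_treated_growth(treatedR, "resistant", 1.2e4)
  expect_equal(base$S / fS$rate, 7.8, tolerance = 1e-4)
  expect_equal(base$R / fR$rate, 1.25, tolerance = 1e-4)
  expect_gt(base$S / fS$rate, base$R / fR$rate)
})

test_that("synergy null composes multiplicatively", {
  s <- synergy_score(0.2, 0.1, 0.15, r_TM_observed = 0.075)
  expect_equal(s$null, 0.075)
  expect_equal(s$deviation, 0)
  expect_equal(s$log_ratio, 0)
  expect_equal(synergy_score(0.2, 0.1, 0.15, 0.15)$log_ratio, log(2))
  expect_error(synergy_score(0, 0.1, 0.15, 0.1), "zero")
})

test_that("competition coefficients are recovered from coculture data", {
  p <- lv_fixture(alpha_SR = 0.1, alpha_RS = 1.5)
  mono <- list(S = structure(list(r = p$r_S, K = p$K_S), class = "logistic_fit"),
               R = structure(list(r = p$r_R, K = p$K_R), class = "logistic_fit"))
  co <- gen_lv_coculture(p, c(500, 500), days6, reps = 3,
                         noise = noise_spec(0.05, seed = 31))
  fit <- fit_competition(co, mono)
  a <- coef(fit)
  expect_equal(unname(a[["alpha_RS"]]), 1.5, tolerance = 0.05)
  # the effect of the strongly suppressed resistant lineage on sensitive
  # cells is near zero and only weakly identified under noise: require the
  # fit to recognise it as small rather than to pin it precisely
  expect_lt(abs(a[["alpha_SR"]] - 0.1), 0.25)

  # coculture identical to independent logistics implies both alphas zero
  co0 <- gen_lv_coculture(lv_fixture(0, 0), c(500, 500), days6, reps = 2,
                          noise = quiet_noise())
  a0 <- coef(fit_competition(co0, mono))
  expect_lt(max(abs(a0)), 1e-3)
  expect_error(fit_competition(co0[co0$lineage == "sensitive", ], mono),
               "resistant")
})

test_that("alpha recovery error shrinks to zero as noise vanishes", {
  mono <- list(S = structure(list(r = 0.35, K = 2e4), class = "logistic_fit"),
               R = structure(list(r = 0.2, K = 1.2e4), class = "logistic_fit"))
  errs <- sapply(c(0, 0.05, 0.15), function(sig) {
    es <- sapply(c(0, 0.5, 1, 1.5), function(alpha) {
      p <- lv_fixture(alpha_SR = alpha, alpha_RS = alpha)
      co <- gen_lv_coculture(p, c(500, 500), days6, reps = 3,
                             noise = noise_spec(sig, seed = 7 + alpha * 10))
      max(abs(coef(fit_competition(co, mono)) - alpha))
    })
    median(es)
  })
  expect_lt(errs[1], 1e-3)
  expect_lt(errs[1], errs[2])
  expect_lt(errs[1], errs[3])
})

test_that("expected coculture trajectories match an independent integrator", {
  p <- lv_fixture(alpha_SR = 0.3, alpha_RS = 1.2)
  expd <- expected_coculture(p, c(S = 500, R = 400), days6, t0 = 4)
  orc <- lv_oracle(p, c(500, 400), 4, days6)
  expect_equal(expd$S, orc$S, tolerance = 1e-8)
  expect_equal(expd$R, orc$R, tolerance = 1e-8)
  # alphas zero: independent treated logistics
  p0 <- lv_fixture(0, 0)
  expd0 <- expected_coculture(p0, c(S = 500, R = 400), days6, t0 = 4)
  expect_equal(expd0$S, logistic_growth(days6 - 4, 500, p0$r_S, p0$K_S),
               tolerance = 1e-8)
})

test_that("facilitation scores measure log deviation from the null trajectory", {
  p <- lv_fixture()
  expd <- expected_coculture(p, c(S = 500, R = 500), days6, t0 = 4)
  obs <- do.call(rbind, lapply(1:3, function(rep)
    data.frame(cell_line = "synthetic", composition = 0.5,
               lineage = "sensitive", replicate = rep, day = expd$day,
               dose_nM = 200, modifier = "none", modifier_dose_nM = 0,
               count = expd$S)))
  f0 <- facilitation_score(obs, expd, days = c(11, 14, 18), "sensitive")
  expect_equal(f0$summary, 0, tolerance = 1e-12)
  obs2 <- transform(obs, count = 2 * count)
  f2 <- facilitation_score(obs2, expd, days = c(11, 14, 18), "sensitive")
  expect_equal(f2$summary, log(2), tolerance = 1e-12)
  expect_equal(f2$per_day$score, rep(log(2), 3), tolerance = 1e-12)
  obs3 <- obs; obs3$count[obs3$day == 11] <- 0
  expect_warning(facilitation_score(obs3, expd, c(11, 14, 18), "sensitive"),
                 "excluding")
})

test_that("facilitation of null-generated coculture data is zero in expectation", {
  p <- lv_fixture()
  expd <- expected_coculture(p, c(S = 500, R = 500), days6, t0 = 4)
  set.seed(99)
  sigma <- 0.15
  scores <- replicate(200, {
    obs <- data.frame(cell_line = "synthetic", composition = 0.5,
                      lineage = "sensitive", replicate = 1, day = expd$day,
                      dose_nM = 200, modifier = "none", modifier_dose_nM = 0,
                      count = expd$S * rlnorm(nrow(expd), 0, sigma))
    facilitation_score(obs, expd, c(11, 14, 18), "sensitive")$summary
  })
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 3 * se)
})

test_that("modifier combinations generated from the composed null score zero", {
  base_tab <- rbind(
    gen_logistic(0.35, 2e4, 600, days6, 3, quiet_noise(), "sensitive"),
    gen_logistic(0.20, 1.2e4, 600, days6, 3, quiet_noise(), "resistant"))
  ribo_tab <- rbind(
    gen_logistic(0.05, 2e4, 600, days6, 3, quiet_noise(), "sensitive", dose = 400),
    gen_logistic(0.16, 1.2e4, 600, days6, 3, quiet_noise(), "resistant", dose = 400))
  mod_tab <- rbind(
    gen_logistic(0.30, 2e4, 600, days6, 3, quiet_noise(), "sensitive"),
    gen_logistic(0.18, 1.2e4, 600, days6, 3, quiet_noise(), "resistant"))
  base <- list(S = fit_logistic(base_tab, "sensitive"),
               R = fit_logistic(base_tab, "resistant"))
  ribo <- list(S = fit_treated_growth(ribo_tab, "sensitive", base$S$K),
               R = fit_treated_growth(ribo_tab, "resistant", base$R$K))
  modf <- list(S = fit_treated_growth(mod_tab, "sensitive", base$S$K),
               R = fit_treated_growth(mod_tab, "resistant", base$R$K))
  cp <- lv_fixture()
  comp <- list(params = competition_params(base$S$r, base$S$K, base$R$r,
                                           base$R$K, cp$alpha_SR, cp$alpha_RS))
  null_params <- competition_params(ribo$S$rate * modf$S$rate / base$S$r,
                                    base$S$K,
                                    ribo$R$rate * modf$R$rate / base$R$r,
                                    base$R$K, cp$alpha_SR, cp$alpha_RS)
  expd <- expected_coculture(null_params, c(S = 500, R = 500),
                             c(4, days6[-1]), t0 = 4)
  combo_obs <- do.call(rbind, lapply(c("sensitive", "resistant"), function(ln)
    data.frame(cell_line = "synthetic", composition = 0.5, lineage = ln,
               replicate = 1, day = expd$day, dose_nM = 400,
               modifier = "estradiol", modifier_dose_nM = 0.1,
               count = if (ln == "sensitive") expd$S else expd$R)))
  res <- facilitation_modification(combo_obs, ribo, modf, comp, base)
  expect_equal(res$summary, 0, tolerance = 1e-4)
  expect_error(facilitation_modification(combo_obs, ribo, list(S = NULL),
                                         comp, base), "missing")
})

test_that("the pipeline runs end to end and records step provenance", {
  p <- lv_fixture()
  mono_un <- rbind(
    gen_logistic(p$r_S, p$K_S, 600, days6, 3, noise_spec(0.05, 1), "sensitive"),
    gen_logistic(p$r_R, p$K_R, 600, days6, 3, noise_spec(0.05, 2), "resistant"))
  mono_tr <- rbind(
    gen_logistic(0.06, p$K_S, 600, days6, 3, noise_spec(0.05, 3), "sensitive", dose = 400),
    gen_logistic(0.16, p$K_R, 600, days6, 3, noise_spec(0.05, 4), "resistant", dose = 400))
  co_un <- gen_lv_coculture(p, c(500, 500), days6, 3, noise_spec(0.05, 5))
  co_tr <- gen_lv_coculture(competition_params(0.06, p$K_S, 0.16, p$K_R,
                                               p$alpha_SR, p$alpha_RS),
                            c(500, 500), days6, 3, noise_spec(0.05, 6),
                            dose = 400)
  out <- fact_pipeline(mono_un, mono_tr, co_un, co_tr)
  expect_length(out$provenance, 5)
  expect_true(grepl("step1", out$provenance[1]))
  # data were generated from the null itself, so facilitation is near zero
  expect_lt(abs(out$facilitation$sensitive$summary), 0.1)
  expect_s3_class(out$competition$params, "competition_params")
})

test_that("group statistics match their sampling-theory behaviour", {
  d <- data.frame(value = rep(c(1, 2), each = 3),
                  group = rep(c("a", "b"), each = 3))
  d$value <- c(1, 2, 3, 1, 2, 3)
  eq <- group_stats(d, "ttest_two_sided")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)

  set.seed(12)
  delta <- 0.7
  big <- data.frame(value = c(rnorm(1e4), rnorm(1e4, delta)),
                    group = rep(c("a", "b"), each = 1e4))
  est <- group_stats(big, "ttest_two_sided")
  expect_equal(abs(est$estimate), delta, tolerance = 0.05)
  expect_lt(est$p, 1e-10)

  one <- group_stats(data.frame(value = rnorm(50, 0.5, 0.1)), "ttest_vs_zero")
  expect_equal(one$estimate, 0.5, tolerance = 0.06)

  set.seed(2)
  n <- 2000
  df <- data.frame(x = rnorm(n), g = rep(0:1, length.out = n))
  df$y <- 1 + 0.5 * df$x + 2 * df$g - 0.8 * df$x * df$g + rnorm(n, 0, 0.1)
  li <- group_stats(df, "lm_interaction", formula = y ~ x * g, term = "x:g")
  expect_equal(li$estimate, -0.8, tolerance = 0.02)
  expect_true(li$ci[1] < -0.8 && -0.8 < li$ci[2])
})
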