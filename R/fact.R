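# FACT: facilitation analysis through combination therapy.
#
# Six steps, each consuming only upstream outputs:
#   1. logistic growth (r, K) per lineage, untreated monoculture
#   2. treated growth rate with K fixed from step 1
#   3. synergy of combined treatments against a multiplicative null
#   4. Lotka-Volterra competition coefficients from untreated coculture
#   5. facilitation = log(observed / expected) against the treated LV null
#   6. facilitation under a modifier, composing steps 2 and 5
#
# All fits are least squares on untransformed counts over pooled replicates,
# start at day 4 (earlier points show a lag), and fix the initial condition
# to the observed day-4 mean.

#' Closed-form logistic trajectory
#'
#' @param t time (days), relative to the time of the initial condition.
#' @param n0 initial abundance.
#' @param r growth rate (1/day); a zero rate gives a constant trajectory.
#' @param K carrying capacity (> 0).
#' @export
logistic_growth <- function(t, n0, r, K) {
  if (K <= 0) stop_("carrying capacity must be positive")
  if (n0 < 0) stop_("initial abundance must be non-negative")
  if (r == 0) return(rep(n0, length(t)))
  K * n0 * exp(r * t) / (K + n0 * (exp(r * t) - 1))
}

fact_subset <- function(ts, lineage, min_day = 4) {
  d <- ts[ts$lineage == lineage & ts$day >= min_day, , drop = FALSE]
  if (nrow(d) == 0) stop_("no rows for lineage '%s' from day %g", lineage, min_day)
  d
}

#' Step 1: fit logistic growth to untreated monoculture
#'
#' Fits `(r, K)` by least squares over all replicates jointly, with the
#' initial condition fixed to the observed mean on the first usable day
#' (day 4; earlier measurements are excluded because spheroids lag before
#' growing).
#'
#' @param ts growth table (monoculture, untreated) containing the lineage.
#' @param lineage `"sensitive"` or `"resistant"`.
#' @param min_day first day used in the fit.
#' @return object of class `logistic_fit` with elements `r`, `K`, `n0`,
#'   `t0`, `rss`, `lineage`.
#' @export
fit_logistic <- function(ts, lineage, min_day = 4) {
  d <- fact_subset(ts, lineage, min_day)
  if (length(unique(d$day)) < 3)
    stop_("need >= 3 time points from day %g to fit (r, K)", min_day)
  t0 <- min(d$day)
  n0 <- mean(d$count[d$day == t0])
  obj <- function(p) {
    pred <- logistic_growth(d$day - t0, n0, p[["r"]], p[["K"]])
    sum((d$count - pred)^2)
  }
  # flat series: r = 0 regardless of K
  if (sd(d$count) < 1e-10 * max(1, mean(d$count))) {
    fit <- list(par = c(r = 0, K = max(n0, 1)), value = obj(c(r = 0, K = max(n0, 1))))
  } else {
    start <- c(r = 0.3, K = max(d$count) * 1.2)
    fit <- multistart_optim(function(p) obj(c(r = p[[1]], K = p[[2]])),
                            start = start)
    fit$par <- setNames(fit$par, c("r", "K"))
  }
  structure(list(r = unname(fit$par[["r"]]), K = unname(fit$par[["K"]]),
                 n0 = n0, t0 = t0, rss = fit$value, lineage = lineage,
                 n_obs = nrow(d)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (%s): r = %.4g /day, K = %.4g cells (n0 = %.4g at day %g, RSS = %.4g)\n",
              x$lineage, x$r, x$K, x$n0, x$t0, x$rss))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) c(r = object$r, K = object$K)

#' @export
predict.logistic_fit <- function(object, days, ...) {
  logistic_growth(days - object$t0, object$n0, object$r, object$K)
}

#' Step 2: fit the treated growth rate with carrying capacity fixed
#'
#' A single free rate is fitted by least squares; the untreated carrying
#' capacity is inherited, on the premise that treatment acts primarily on
#' growth. Negative rates (net decline under treatment) are allowed.
#'
#' @param ts growth table of a treated monoculture.
#' @param lineage lineage label.
#' @param K_fixed carrying capacity from [fit_logistic()] of the same lineage.
#' @param treatment label recorded in the result.
#' @param min_day first day used.
#' @return object of class `treated_growth` (`rate`, `K_fixed`, `rss`, ...).
#' @export
fit_treated_growth <- function(ts, lineage, K_fixed, treatment = "treated",
                               min_day = 4) {
  d <- fact_subset(ts, lineage, min_day)
  if (length(unique(d$day)) < 3)
    stop_("need >= 3 time points from day %g to fit the treated rate", min_day)
  t0 <- min(d$day)
  n0 <- mean(d$count[d$day == t0])
  obj <- function(r) sum((d$count - logistic_growth(d$day - t0, n0, r, K_fixed))^2)
  opt <- optimize(obj, interval = c(-3, 3), tol = 1e-12)
  # refine once on a shrinking bracket for high-accuracy recovery
  w <- 0.05
  opt2 <- optimize(obj, interval = opt$minimum + c(-w, w), tol = 1e-14)
  if (opt2$objective < opt$objective) opt <- opt2
  structure(list(rate = opt$minimum, K_fixed = K_fixed, n0 = n0, t0 = t0,
                 rss = opt$objective, lineage = lineage,
                 treatment = treatment),
            class = "treated_growth")
}

#' @export
print.treated_growth <- function(x, ...) {
  cat(sprintf("Treated growth (%s, %s): rate = %.4g /day (K fixed at %.4g, RSS = %.4g)\n",
              x$lineage, x$treatment, x$rate, x$K_fixed, x$rss))
  invisible(x)
}

#' Step 3: synergy of combined treatments
#'
#' The null model for the combined rate multiplies the relative effects of
#' the two single treatments: `r_null = r_base (r_T/r_base)(r_M/r_base)`.
#' Deviation is reported on the rate scale and, when both rates are
#' positive, as `log(observed / null)`.
#'
#' @param r_base untreated rate; must be nonzero.
#' @param r_T,r_M single-treatment rates.
#' @param r_TM_observed observed rate under the combination.
#' @return list with `null`, `deviation`, `log_ratio` (NA if undefined).
#' @export
synergy_score <- function(r_base, r_T, r_M, r_TM_observed) {
  if (r_base == 0) stop_("undefined null model: untreated rate is zero")
  null <- r_T * r_M / r_base
  list(null = null,
       deviation = r_TM_observed - null,
       log_ratio = if (r_TM_observed > 0 && null > 0)
         log(r_TM_observed / null) else NA_real_)
}

#' Bundle of Lotka-Volterra competition parameters
#'
#' Self-effects are scaled to 1; `alpha_SR` is the per-capita effect of
#' resistant on sensitive cells and `alpha_RS` the reverse.
#'
#' @param r_S,K_S,r_R,K_R monoculture logistic parameters.
#' @param alpha_SR,alpha_RS interaction coefficients.
#' @export
competition_params <- function(r_S, K_S, r_R, K_R, alpha_SR, alpha_RS) {
  if (K_S <= 0 || K_R <= 0) stop_("carrying capacities must be positive")
  vals <- c(r_S, K_S, r_R, K_R, alpha_SR, alpha_RS)
  if (any(!is.finite(vals))) stop_("all parameters must be finite")
  structure(list(r_S = r_S, K_S = K_S, r_R = r_R, K_R = K_R,
                 alpha_SR = alpha_SR, alpha_RS = alpha_RS),
            class = "competition_params")
}

#' @export
print.competition_params <- function(x, ...) {
  cat(sprintf("LV competition: r_S = %.4g, K_S = %.4g, r_R = %.4g, K_R = %.4g\n",
              x$r_S, x$K_S, x$r_R, x$K_R))
  cat(sprintf("  alpha_SR (R on S) = %.4g, alpha_RS (S on R) = %.4g\n",
              x$alpha_SR, x$alpha_RS))
  invisible(x)
}

lv_integrate <- function(params, init, t0, days, rtol = 1e-10, atol = 1e-10) {
  rhs <- function(t, y, p) {
    S <- y[1]; R <- y[2]
    list(c(p$r_S * (1 - (S + p$alpha_SR * R) / p$K_S) * S,
           p$r_R * (1 - (p$alpha_RS * S + R) / p$K_R) * R))
  }
  times <- sort(unique(c(t0, days)))
  sol <- deSolve::lsoda(y = c(S = init[[1]], R = init[[2]]), times = times,
                        func = rhs, parms = params, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop_("LV integration failed (lsoda istate %d)", attr(sol, "istate")[1])
  as.data.frame(sol)[match(days, times), , drop = FALSE]
}

#' Step 4: fit competition coefficients from untreated coculture
#'
#' Holds the monoculture rates and capacities fixed and fits `alpha_SR`,
#' `alpha_RS` by least squares against the numerically integrated LV system,
#' pooling both lineages and all replicates; the initial condition is the
#' observed day-4 mean of each lineage.
#'
#' @param ts coculture growth table containing both lineages.
#' @param mono_params named list with `S` and `R` entries, each a
#'   [fit_logistic()] result.
#' @param min_day first day used.
#' @return object of class `competition_fit`; its `params` element is a
#'   [competition_params()] object.
#' @export
fit_competition <- function(ts, mono_params, min_day = 4) {
  for (ln in c("sensitive", "resistant"))
    if (!any(ts$lineage == ln & ts$day >= min_day))
      stop_("coculture table lacks lineage '%s'", ln)
  dS <- fact_subset(ts, "sensitive", min_day)
  dR <- fact_subset(ts, "resistant", min_day)
  t0 <- min(c(dS$day, dR$day))
  init <- c(S = mean(dS$count[dS$day == t0]),
            R = mean(dR$count[dR$day == t0]))
  days <- sort(unique(c(dS$day, dR$day)))
  fS <- mono_params$S; fR <- mono_params$R
  obj <- function(a) {
    p <- list(r_S = fS$r, K_S = fS$K, r_R = fR$r, K_R = fR$K,
              alpha_SR = a[1], alpha_RS = a[2])
    tr <- tryCatch(lv_integrate(p, init, t0, days), error = function(e) NULL)
    if (is.null(tr)) return(1e300)
    predS <- tr$S[match(dS$day, days)]
    predR <- tr$R[match(dR$day, days)]
    sum((dS$count - predS)^2) + sum((dR$count - predR)^2)
  }
  # alphas may legitimately be 0; optimise unconstrained, multi-start
  best <- NULL
  for (s in 1:6) {
    set.seed(2000 + s)
    a0 <- if (s == 1) c(0.5, 0.5) else runif(2, 0, 2)
    res <- optim(a0, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
    if (is.null(best) || res$value < best$value) best <- res
  }
  pol <- tryCatch(optim(best$par, obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 300)),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) best <- pol
  a <- best$par
  structure(list(
    params = competition_params(fS$r, fS$K, fR$r, fR$K, a[1], a[2]),
    init = init, t0 = t0, rss = best$value),
    class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  fitted from day %g, init S = %.4g, R = %.4g, RSS = %.4g\n",
              x$t0, x$init[["S"]], x$init[["R"]], x$rss))
  invisible(x)
}

#' @export
coef.competition_fit <- function(object, ...) {
  with(object$params, c(alpha_SR = alpha_SR, alpha_RS = alpha_RS))
}

#' Step 5 null model: expected treated coculture trajectories
#'
#' Integrates the LV system with the treated monoculture rates substituted
#' for the untreated ones, untreated carrying capacities and the untreated
#' competition coefficients - the expectation if coculture does not change
#' either lineage's drug tolerance.
#'
#' @param params a [competition_params()] object whose rates are the rates
#'   to simulate under (substitute treated rates for a treated null).
#' @param init named vector `c(S = , R = )` at `t0`.
#' @param days output days (absolute).
#' @param t0 day of the initial condition.
#' @return `data.frame` with columns `day`, `S`, `R`.
#' @export
expected_coculture <- function(params, init, days, t0 = min(days)) {
  stopifnot(inherits(params, "competition_params"))
  days <- sort(unique(days))
  tr <- lv_integrate(unclass(params), c(init[["S"]], init[["R"]]), t0, days)
  data.frame(day = days, S = tr$S, R = tr$R)
}

#' Step 5: facilitation score
#'
#' Per replicate and evaluation day, `log(observed / expected)` for the
#' focal lineage; the summary is the mean over days and replicates.
#' Nonpositive observed or expected counts are excluded with a warning
#' (the log ratio is undefined there).
#'
#' @param observed coculture growth table (focal lineage rows are used).
#' @param expected output of [expected_coculture()].
#' @param days evaluation days (default 11, 14, 18).
#' @param lineage focal lineage.
#' @param treatment label carried into the result.
#' @return object of class `facilitation_result` with per-observation
#'   scores, per-day means, `summary` (grand mean), `se`, and Student-t 95%
#'   confidence bounds.
#' @export
facilitation_score <- function(observed, expected, days = c(11, 14, 18),
                               lineage = c("sensitive", "resistant"),
                               treatment = "ribociclib") {
  lineage <- match.arg(lineage)
  col <- if (lineage == "sensitive") "S" else "R"
  obs <- observed[observed$lineage == lineage & observed$day %in% days, ,
                  drop = FALSE]
  if (nrow(obs) == 0) stop_("no observations at the evaluation days")
  missing_days <- setdiff(days, expected$day)
  if (length(missing_days) > 0)
    stop_("expected trajectory lacks evaluation day(s): %s",
          paste(missing_days, collapse = ", "))
  exp_val <- expected[[col]][match(obs$day, expected$day)]
  ok <- obs$count > 0 & exp_val > 0
  if (any(!ok))
    warn_("excluding %d observation(s) with nonpositive observed or expected counts",
          sum(!ok))
  if (!any(ok)) stop_("all observations excluded; facilitation undefined")
  score <- log(obs$count[ok] / exp_val[ok])
  per_obs <- data.frame(replicate = obs$replicate[ok], day = obs$day[ok],
                        score = score)
  per_day <- aggregate(score ~ day, data = per_obs, FUN = mean)
  n <- length(score)
  se <- sd(score) / sqrt(n)
  ci <- mean(score) + qt(c(0.025, 0.975), df = max(n - 1, 1)) * se
  structure(list(per_obs = per_obs, per_day = per_day,
                 summary = mean(score), se = se, ci = ci, n = n,
                 treatment = treatment, lineage = lineage,
                 days = sort(unique(per_obs$day))),
            class = "facilitation_result")
}

#' @export
print.facilitation_result <- function(x, ...) {
  cat(sprintf("Facilitation of %s cells under %s\n", x$lineage, x$treatment))
  cat(sprintf("  mean log(obs/expected) = %.4g (SE %.3g, 95%% CI %.3g..%.3g, n = %d)\n",
              x$summary, x$se, x$ci[1], x$ci[2], x$n))
  cat("  per-day means:",
      paste(sprintf("day %g: %.3g", x$per_day$day, x$per_day$score),
            collapse = ", "), "\n")
  invisible(x)
}

#' Step 6: facilitation under a ribociclib + modifier combination
#'
#' Builds the combination null by composing the treated-coculture
#' expectation (step 5) with the modifier's direct monoculture effect
#' (step 2): each lineage's null rate is
#' `r_i (r_iT/r_i)(r_iM/r_i) = r_iT r_iM / r_i`. The score quantifies
#' whether the modifier enhances or cancels the facilitation seen under
#' ribociclib alone.
#'
#' @param ts coculture growth table under ribociclib + modifier.
#' @param ribo_rates named list `S`/`R` of [fit_treated_growth()] results
#'   under ribociclib alone.
#' @param modifier_rates named list `S`/`R` of [fit_treated_growth()]
#'   results under the modifier alone.
#' @param comp_fit untreated [fit_competition()] result.
#' @param base named list `S`/`R` of untreated [fit_logistic()] fits.
#' @param days evaluation days.
#' @param lineage focal lineage.
#' @return a [facilitation_score()] result for the combination.
#' @export
facilitation_modification <- function(ts, ribo_rates, modifier_rates,
                                      comp_fit, base,
                                      days = c(11, 14, 18),
                                      lineage = "sensitive") {
  for (nm in c("S", "R")) {
    if (is.null(ribo_rates[[nm]]) || is.null(modifier_rates[[nm]]))
      stop_("missing monoculture fit for lineage '%s'", nm)
    if (base[[nm]]$r == 0)
      stop_("untreated rate of lineage '%s' is zero; null undefined", nm)
  }
  null_rate <- function(nm)
    ribo_rates[[nm]]$rate * modifier_rates[[nm]]$rate / base[[nm]]$r
  cp <- comp_fit$params
  null_params <- competition_params(null_rate("S"), cp$K_S,
                                    null_rate("R"), cp$K_R,
                                    cp$alpha_SR, cp$alpha_RS)
  dS <- fact_subset(ts, "sensitive")
  dR <- fact_subset(ts, "resistant")
  t0 <- min(c(dS$day, dR$day))
  init <- c(S = mean(dS$count[dS$day == t0]),
            R = mean(dR$count[dR$day == t0]))
  expd <- expected_coculture(null_params, init,
                             sort(unique(c(t0, days))), t0 = t0)
  facilitation_score(ts, expd, days = days, lineage = lineage,
                     treatment = "ribociclib+modifier")
}

#' Group statistics used in the figure-level analyses
#'
#' Thin wrappers around the standard tests: a two-sample two-tailed t-test,
#' a one-sample t-test against zero (deviation of facilitation scores from
#' the null line), and an ordinary-least-squares interaction coefficient.
#'
#' @param data a `data.frame`.
#' @param test `"ttest_two_sided"`, `"ttest_vs_zero"`, or `"lm_interaction"`.
#' @param value name of the response column.
#' @param group name of the two-level grouping column (two-sample test).
#' @param formula model formula for `lm_interaction`.
#' @param term name of the interaction coefficient to report; defaults to
#'   the last coefficient of the model.
#' @return list with `statistic`, `p`, `estimate`, `ci` (95%), and `se`
#'   where applicable.
#' @export
group_stats <- function(data, test = c("ttest_two_sided", "ttest_vs_zero",
                                       "lm_interaction"),
                        value = "value", group = "group",
                        formula = NULL, term = NULL) {
  test <- match.arg(test)
  if (test == "ttest_two_sided") {
    g <- factor(data[[group]])
    if (nlevels(g) != 2) stop_("two-sample test needs exactly 2 groups")
    if (min(table(g)) < 2) stop_("each group needs >= 2 observations")
    tt <- t.test(data[[value]] ~ g)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         estimate = unname(diff(rev(tt$estimate))), ci = unname(tt$conf.int))
  } else if (test == "ttest_vs_zero") {
    v <- data[[value]]
    if (length(v) < 2) stop_("need >= 2 observations")
    tt <- t.test(v, mu = 0)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         estimate = unname(tt$estimate), ci = unname(tt$conf.int))
  } else {
    if (is.null(formula)) stop_("lm_interaction requires a formula")
    fit <- lm(formula, data = data)
    cf <- summary(fit)$coefficients
    if (is.null(term)) term <- rownames(cf)[nrow(cf)]
    if (!term %in% rownames(cf)) stop_("term '%s' not in the model", term)
    est <- cf[term, "Estimate"]; se <- cf[term, "Std. Error"]
    dfree <- fit$df.residual
    list(statistic = cf[term, "t value"], p = cf[term, "Pr(>|t|)"],
         estimate = est, se = se,
         ci = est + qt(c(0.025, 0.975), dfree) * se, term = term)
  }
}

#' Run the FACT pipeline on a set of growth tables
#'
#' Convenience driver for steps 1-5 that records provenance (which step
#' produced which estimate, in order).
#'
#' @param mono_untreated monoculture untreated growth table (both lineages).
#' @param mono_treated monoculture treated growth table (both lineages).
#' @param cocult_untreated untreated coculture table.
#' @param cocult_treated treated coculture table.
#' @param days facilitation evaluation days.
#' @param treatment label of the treatment.
#' @return list of step outputs plus a `provenance` character vector.
#' @export
fact_pipeline <- function(mono_untreated, mono_treated, cocult_untreated,
                          cocult_treated, days = c(11, 14, 18),
                          treatment = "ribociclib") {
  prov <- character()
  base <- list(S = fit_logistic(mono_untreated, "sensitive"),
               R = fit_logistic(mono_untreated, "resistant"))
  prov <- c(prov, "step1: logistic (r, K) per lineage, untreated monoculture")
  treated <- list(
    S = fit_treated_growth(mono_treated, "sensitive", base$S$K, treatment),
    R = fit_treated_growth(mono_treated, "resistant", base$R$K, treatment))
  prov <- c(prov, "step2: treated rates with K fixed from step 1")
  comp <- fit_competition(cocult_untreated, base)
  prov <- c(prov, "step4: LV competition coefficients, untreated coculture")
  cp <- comp$params
  null_params <- competition_params(treated$S$rate, cp$K_S,
                                    treated$R$rate, cp$K_R,
                                    cp$alpha_SR, cp$alpha_RS)
  dS <- fact_subset(cocult_treated, "sensitive")
  dR <- fact_subset(cocult_treated, "resistant")
  t0 <- min(c(dS$day, dR$day))
  init <- c(S = mean(dS$count[dS$day == t0]),
            R = mean(dR$count[dR$day == t0]))
  expd <- expected_coculture(null_params, init,
                             sort(unique(c(t0, days))), t0 = t0)
  prov <- c(prov, "step5: treated LV null trajectory")
  fac <- list(
    sensitive = facilitation_score(cocult_treated, expd, days,
                                   "sensitive", treatment),
    resistant = facilitation_score(cocult_treated, expd, days,
                                   "resistant", treatment))
  prov <- c(prov, "step5: facilitation scores per lineage")
  list(base = base, treated = treated, competition = comp,
       expected = expd, facilitation = fac, provenance = prov)
}
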