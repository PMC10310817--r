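# Michaelis-Menten estradiol production/uptake models fitted to medium
# concentrations across cultures of varying composition:
#   f4 = (rho_R R + rho_S S) / (1 + a_R R + a_S S)   full model
#   f3 = (rho_R R)           / (1 + a_R R + a_S S)   no sensitive production
#   f2 = (rho_R R + rho_S S) / (R + a_S S)           background usage dropped,
#                                                    a_R scaled to 1
# Zero readings are censored at the assay's lower limit of detection and
# replaced by LLOD/2 before fitting; skipping that replacement biases fits.

.flux_pars <- list(f4 = c("rho_R", "rho_S", "a_R", "a_S"),
                   f3 = c("rho_R", "a_R", "a_S"),
                   f2 = c("rho_R", "rho_S", "a_S"))

#' Preprocess raw estradiol measurements
#'
#' Replaces zero (non-detect) readings by `llod / 2` while keeping the
#' `below_llod` flag, and drops listed outlier samples. All other values
#' pass through unchanged.
#'
#' @param raw estradiol table (see [read_table()]).
#' @param llod lower limit of detection in pg/mL (assay default 62.5).
#' @param exclude character vector of `sample_id`s to drop.
#' @return the processed table.
#' @export
preprocess_estradiol <- function(raw, llod = 62.5, exclude = character()) {
  if (llod <= 0) stop_("llod must be positive")
  out <- as.data.frame(raw)
  if (is.null(out$below_llod)) out$below_llod <- out$estradiol_pg_ml == 0
  missing <- setdiff(exclude, out$sample_id)
  if (length(missing) > 0)
    warn_("exclusion id(s) not present: %s", paste(missing, collapse = ", "))
  out <- out[!out$sample_id %in% exclude, , drop = FALSE]
  zero <- out$estradiol_pg_ml == 0
  out$below_llod[zero] <- TRUE
  out$estradiol_pg_ml[zero] <- llod / 2
  attr(out, "llod") <- llod
  attr(out, "schema") <- "estradiol"
  out
}

#' Evaluate a production/uptake model
#'
#' @param variant `"f4"`, `"f3"` or `"f2"`.
#' @param params named vector/list with the variant's parameters
#'   (`rho_R`, `rho_S`, `a_R`, `a_S` as applicable).
#' @param S,R sensitive and resistant cell numbers.
#' @return predicted concentration (pg/mL).
#' @export
predict_flux <- function(variant = c("f2", "f3", "f4"), params, S, R) {
  variant <- match.arg(variant)
  p <- as.list(params)
  if (variant == "f4") {
    (p$rho_R * R + p$rho_S * S) / (1 + p$a_R * R + p$a_S * S)
  } else if (variant == "f3") {
    (p$rho_R * R) / (1 + p$a_R * R + p$a_S * S)
  } else {
    den <- R + p$a_S * S
    if (any(den <= 0)) stop_("f2 undefined: R + a_S S must be positive")
    (p$rho_R * R + p$rho_S * S) / den
  }
}

#' Fit a production/uptake model by least squares
#'
#' Minimises the sum of squared concentration residuals with parameters
#' constrained non-negative (optimised on the log scale from multiple
#' dispersed starts, then polished by Levenberg-Marquardt).
#'
#' @param data preprocessed estradiol table (see [preprocess_estradiol()]).
#' @param variant model variant.
#' @return object of class `flux_fit`: estimates, `rss`, `n_obs`,
#'   `sigma2_hat = rss / n_obs`.
#' @export
fit_flux <- function(data, variant = c("f2", "f3", "f4")) {
  variant <- match.arg(variant)
  pnames <- .flux_pars[[variant]]
  S <- data$s_cells; R <- data$r_cells; y <- data$estradiol_pg_ml
  if (length(y) < length(pnames) + 1)
    stop_("need at least %d observations to fit %s",
          length(pnames) + 1, variant)
  obj <- function(p) {
    pred <- predict_flux(variant, setNames(p, pnames), S, R)
    sum((y - pred)^2)
  }
  start <- setNames(c(rho_R = max(y), rho_S = max(y) / 5, a_R = 0.5,
                      a_S = 0.5)[pnames], pnames)
  ms <- multistart_optim(obj, start, n_starts = 10, spread = 1.5)
  # Levenberg-Marquardt polish on the log scale
  resid_fn <- function(lp) {
    pred <- predict_flux(variant, setNames(exp(lp), pnames), S, R)
    y - pred
  }
  lm_fit <- tryCatch(
    minpack.lm::nls.lm(par = log(ms$par), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  par <- ms$par; rss <- ms$value
  if (!is.null(lm_fit)) {
    rss_lm <- sum(lm_fit$fvec^2)
    if (rss_lm <= rss) { par <- setNames(exp(lm_fit$par), pnames); rss <- rss_lm }
  }
  structure(list(variant = variant, par = par, rss = rss,
                 n_obs = length(y), sigma2_hat = rss / length(y),
                 data = data.frame(s_cells = S, r_cells = R,
                                   estradiol_pg_ml = y)),
            class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("Estradiol flux model %s (n = %d)\n", x$variant, x$n_obs))
  print(signif(x$par, 4))
  cat(sprintf("  RSS = %.4g, sigma2_hat = %.4g\n", x$rss, x$sigma2_hat))
  invisible(x)
}

#' @export
coef.flux_fit <- function(object, ...) object$par

#' @export
predict.flux_fit <- function(object, S, R, ...) {
  predict_flux(object$variant, object$par, S, R)
}

flux_loglik <- function(rss, n, sigma2) {
  -n / 2 * log(2 * pi * sigma2) - rss / (2 * sigma2)
}

#' Profile-likelihood confidence interval for a flux parameter
#'
#' The residual variance at the optimum converts least squares into a
#' Gaussian likelihood (`sigma2 = rss/n`, held fixed). The focal parameter
#' is profiled on a 401-point grid spanning the MLE scaled by 0.25 to 4 (re-optimising
#' the remaining parameters at each point) and the interval is the set of
#' values whose log likelihood is within 2 of the maximum, with the
#' threshold crossings refined by bisection.
#'
#' @param fit a [fit_flux()] result.
#' @param data the table the fit used (defaults to the data stored in the
#'   fit).
#' @param parameter parameter name to profile.
#' @param span multiplicative span of the grid around the MLE.
#' @param n_grid grid size.
#' @return object of class `profile_ci`: `lower`, `upper`, `mle`, and
#'   boundary flags set when the interval touches the search range.
#' @export
profile_ci <- function(fit, data = NULL, parameter, span = c(0.25, 4),
                       n_grid = 401) {
  pnames <- names(fit$par)
  if (!parameter %in% pnames) stop_("unknown parameter '%s'", parameter)
  if (is.null(data)) data <- fit$data
  S <- data$s_cells; R <- data$r_cells; y <- data$estradiol_pg_ml
  sigma2 <- fit$sigma2_hat
  n <- fit$n_obs
  others <- setdiff(pnames, parameter)
  prof_rss <- function(val) {
    if (length(others) == 0) {
      pred <- predict_flux(fit$variant, setNames(val, parameter), S, R)
      return(sum((y - pred)^2))
    }
    resid_fn <- function(lp) {
      p <- setNames(numeric(length(pnames)), pnames)
      p[others] <- exp(lp); p[parameter] <- val
      y - predict_flux(fit$variant, p, S, R)
    }
    r <- tryCatch(minpack.lm::nls.lm(
      par = log(pmax(fit$par[others], 1e-8)), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(r)) Inf else sum(r$fvec^2)
  }
  dev <- function(val) (flux_loglik(fit$rss, n, sigma2) -
                          flux_loglik(prof_rss(val), n, sigma2))
  mle <- fit$par[[parameter]]
  grid <- seq(mle * span[1], mle * span[2], length.out = n_grid)
  dv <- vapply(grid, dev, numeric(1))
  inside <- dv <= 2
  if (all(inside)) {
    return(structure(list(parameter = parameter, lower = grid[1],
                          upper = grid[n_grid], mle = mle,
                          lower_at_bound = TRUE, upper_at_bound = TRUE,
                          unbounded = TRUE),
                     class = "profile_ci"))
  }
  bisect <- function(lo, hi) {
    # dev(lo) and dev(hi) straddle 2
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if ((dev(lo) - 2) * (dev(mid) - 2) <= 0) hi <- mid else lo <- mid
      if (abs(hi - lo) < 1e-10 * max(1, abs(mle))) break
    }
    (lo + hi) / 2
  }
  idx <- which(inside)
  lower_at_bound <- idx[1] == 1
  upper_at_bound <- idx[length(idx)] == n_grid
  lower <- if (lower_at_bound) grid[1] else bisect(grid[idx[1] - 1], grid[idx[1]])
  upper <- if (upper_at_bound) grid[n_grid] else
    bisect(grid[idx[length(idx)]], grid[idx[length(idx)] + 1])
  structure(list(parameter = parameter, lower = lower, upper = upper,
                 mle = mle, lower_at_bound = lower_at_bound,
                 upper_at_bound = upper_at_bound, unbounded = FALSE),
            class = "profile_ci")
}

#' @export
print.profile_ci <- function(x, ...) {
  cat(sprintf("Profile CI for %s: [%.4g, %.4g] (MLE %.4g)%s\n",
              x$parameter, x$lower, x$upper, x$mle,
              if (x$lower_at_bound || x$upper_at_bound)
                " [hits search bound]" else ""))
  invisible(x)
}

#' Production and use ratios of resistant relative to sensitive cells
#'
#' From the reduced model's fit: production ratio `rho_R / rho_S`, use
#' ratio `1 / a_S` (uptake of R relative to S, since `a_R` is scaled to 1),
#' and their quotient, the production-per-use composite.
#'
#' @param fit a [fit_flux()] result with `variant = "f2"`.
#' @return list with `production_ratio`, `use_ratio`, `production_use`.
#' @export
production_use_ratios <- function(fit) {
  if (fit$variant != "f2") stop_("ratios are defined for the f2 variant")
  p <- fit$par
  if (p[["rho_S"]] <= 0) stop_("rho_S = 0: production ratio undefined")
  if (p[["a_S"]] <= 0) stop_("a_S = 0: use ratio undefined")
  production <- p[["rho_R"]] / p[["rho_S"]]
  use <- 1 / p[["a_S"]]
  list(production_ratio = production, use_ratio = use,
       production_use = production / use)
}
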