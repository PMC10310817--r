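# Bayesian fitting of the consumer-resource model to dose-panel growth
# data. The sampler is Hamiltonian Monte Carlo on the log-parameter scale:
# leapfrog dynamics with a jittered number of steps, dual-averaging step
# size adaptation and diagonal mass-matrix estimation during warmup.
# Gradients of the ODE log likelihood are obtained by batched forward
# finite differences evaluated in compiled code; the Metropolis correction
# uses the exact log posterior, so small gradient errors cost acceptance
# rate, not correctness.

#' Lognormal measurement log-likelihood
#'
#' Log density of each observed count under a lognormal distribution with
#' log-mean `log(predicted)` and log-scale SD `sigma_obs`.
#'
#' @param predicted,observed positive counts.
#' @param sigma_obs log-scale SD.
#' @return per-observation log-likelihood vector.
#' @export
lognormal_loglik <- function(predicted, observed, sigma_obs) {
  if (any(predicted <= 0) || any(observed <= 0))
    stop_("lognormal likelihood needs positive counts")
  if (sigma_obs <= 0) stop_("sigma_obs must be positive")
  dnorm(log(observed), log(predicted), sigma_obs, log = TRUE) - log(observed)
}

#' Weakly informative prior specification
#'
#' Lognormal priors centred at the supplied parameter values (log-scale SD
#' `sd`) for the positive model rates, and a half-normal prior on the
#' measurement SD.
#'
#' @param params a [mech_params()] object giving the prior locations.
#' @param free names of the parameters being sampled.
#' @param sd log-scale SD of the lognormal priors.
#' @param sigma_scale scale of the half-normal prior on `sigma_obs`.
#' @return `data.frame` with columns `name`, `family`, `location`, `scale`.
#' @export
prior_spec <- function(params = mech_params(), free = default_free(),
                       sd = 1, sigma_scale = 1) {
  pv <- as_param_vector(params)
  bad <- setdiff(free, names(pv))
  if (length(bad) > 0) stop_("unknown parameter(s): %s", paste(bad, collapse = ", "))
  rbind(
    data.frame(name = free, family = "lognormal",
               location = log(pv[free]), scale = sd,
               stringsAsFactors = FALSE),
    data.frame(name = "sigma_obs", family = "half-normal",
               location = 0, scale = sigma_scale, stringsAsFactors = FALSE))
}

#' @rdname prior_spec
#' @export
default_free <- function() {
  c("r_S", "r_R", "lambda_S", "lambda_R", "k_S", "k_R", "K_S", "K_R")
}

# log prior and its gradient on the unconstrained scale u = log(theta)
# (the last entry is log sigma_obs with a half-normal prior + Jacobian)
log_prior_u <- function(u, priors) {
  d <- length(u)
  lp <- 0
  for (j in seq_len(d)) {
    if (priors$family[j] == "lognormal") {
      lp <- lp - 0.5 * ((u[j] - priors$location[j]) / priors$scale[j])^2
    } else { # half-normal on theta = exp(u), plus Jacobian u
      s <- exp(u[j])
      lp <- lp - 0.5 * (s / priors$scale[j])^2 + u[j]
    }
  }
  lp
}

grad_log_prior_u <- function(u, priors) {
  d <- length(u)
  g <- numeric(d)
  for (j in seq_len(d)) {
    if (priors$family[j] == "lognormal") {
      g[j] <- -(u[j] - priors$location[j]) / priors$scale[j]^2
    } else {
      s <- exp(u[j])
      g[j] <- -(s / priors$scale[j])^2 + 1
    }
  }
  g
}

# Assemble condition and observation arrays from a growth panel.
# Day-0 rows give exact initial states; later rows are the likelihood data.
panel_data <- function(panel, n0 = NULL) {
  d0 <- panel[panel$day == 0, , drop = FALSE]
  obs <- panel[panel$day > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop_("panel has no observations after day 0")
  key <- paste(obs$dose_nM, obs$composition, sep = "|")
  ckeys <- unique(key)
  conds <- t(vapply(ckeys, function(k) {
    parts <- as.numeric(strsplit(k, "|", fixed = TRUE)[[1]])
    dose <- parts[1]; comp <- parts[2]
    sel0 <- d0$dose_nM == dose & d0$composition == comp
    if (any(sel0)) {
      S0 <- mean(d0$count[sel0 & d0$lineage == "sensitive"])
      R0 <- mean(d0$count[sel0 & d0$lineage == "resistant"])
      if (!is.finite(S0)) S0 <- 0
      if (!is.finite(R0)) R0 <- 0
    } else {
      if (is.null(n0))
        stop_("no day-0 rows and no plated total `n0` supplied")
      S0 <- n0 * comp; R0 <- n0 * (1 - comp)
    }
    c(dose, S0, R0)
  }, numeric(3)))
  list(conds = unname(conds),
       obs_cond = match(key, ckeys),
       obs_day = obs$day,
       obs_lineage = ifelse(obs$lineage == "resistant", 1L, 0L),
       obs_count = obs$count,
       n_obs = nrow(obs))
}

#' Fit the consumer-resource model by Hamiltonian Monte Carlo
#'
#' Samples the posterior of a chosen subset of model parameters (plus the
#' lognormal measurement SD) given a dose-panel growth table. Per-draw
#' pointwise log-likelihoods are stored for WAIC.
#'
#' @param panel growth table from [gen_mechanistic_panel()] or
#'   [read_table()]; day-0 rows set the initial states.
#' @param variant model variant to fit.
#' @param params a [mech_params()] object supplying values of the
#'   parameters that are held fixed and the prior centres of the free ones.
#' @param free names of the sampled parameters (default [default_free()]).
#' @param priors a [prior_spec()] table; defaults to weakly informative
#'   priors centred at `params`.
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iter_warmup,iter_sampling warmup and post-warmup iterations per
#'   chain.
#' @param seed integer seed; chains use derived substreams.
#' @param n0 plated total used only if the panel lacks day-0 rows.
#' @param leapfrog range of leapfrog steps (jittered per iteration).
#' @param target_accept dual-averaging acceptance target.
#' @param likelihood_weight tempering weight on the log likelihood; 0 turns
#'   the data off entirely, so the sampler targets the prior (used to
#'   validate the sampler against known prior moments).
#' @param rtol,atol ODE tolerances of the likelihood solves. Looser than
#'   the [simulate_spheroid()] default: inside the sampler the integration
#'   error (well below the measurement noise) trades off against the cost
#'   of hundreds of thousands of solves.
#' @return object of class `posterior_draws`: `draws` (iterations x chains
#'   x parameters, positive scale), `pointwise_loglik`, `diagnostics`
#'   (split R-hat, effective sample size, divergences), `accept_rate`.
#' @export
fit_posterior <- function(panel, variant = "facilitation",
                          params = mech_params(), free = default_free(),
                          priors = NULL, chains = 2,
                          iter_warmup = 300, iter_sampling = 500,
                          seed = 1, n0 = NULL, leapfrog = c(3, 6),
                          target_accept = 0.8, rtol = 1e-6, atol = 1e-3,
                          likelihood_weight = 1) {
  if (chains < 2)
    warn_("fewer than 2 chains: convergence diagnostics are unreliable")
  if (!variant %in% names(.mech_variants))
    stop_("unknown model variant '%s'", variant)
  pd <- panel_data(panel, n0 = n0)
  if (is.null(priors)) priors <- prior_spec(params, free)
  stopifnot(identical(priors$name, c(free, "sigma_obs")))
  base_theta <- as_param_vector(params)
  free_idx <- match(free, .mech_order)
  vcode <- .mech_variants[[variant]]
  d <- length(free) + 1L

  theta_of_u <- function(u) {
    th <- c(base_theta, 0)
    th[free_idx] <- exp(u[seq_along(free)])
    th[25] <- exp(u[d])
    th
  }
  loglik_batch <- function(U) { # rows of U are u-vectors
    if (likelihood_weight == 0) return(rep(0, nrow(U)))
    TH <- t(apply(U, 1, theta_of_u))
    likelihood_weight *
      cpp_panel_loglik_mat(TH, vcode, pd$conds, pd$obs_cond, pd$obs_day,
                           pd$obs_lineage, pd$obs_count, rtol, atol)
  }
  h_fd <- 3e-5
  logpost_and_grad <- function(u) {
    U <- matrix(rep(u, d + 1), nrow = d + 1, byrow = TRUE)
    for (j in seq_len(d)) U[j + 1, j] <- U[j + 1, j] + h_fd
    ll <- loglik_batch(U)
    lp0 <- ll[1] + log_prior_u(u, priors)
    gll <- (ll[-1] - ll[1]) / h_fd
    list(lp = lp0, grad = gll + grad_log_prior_u(u, priors))
  }
  logpost <- function(u) {
    ll <- loglik_batch(matrix(u, nrow = 1))
    ll[1] + log_prior_u(u, priors)
  }

  loc <- c(priors$location[seq_along(free)], log(0.5 * priors$scale[d]))
  run_chain <- function(chain_id) {
    set.seed(stream_seed(seed, paste0("hmc-chain-", chain_id)))
    u <- loc + 0.2 * rnorm(d)
    minv <- rep(1, d)         # inverse mass (posterior variance estimate)
    eps <- 0.05
    mu_da <- log(10 * eps); log_eps_bar <- log(eps); H_bar <- 0
    gamma_da <- 0.05; t0_da <- 10; kappa_da <- 0.75
    n_iter <- iter_warmup + iter_sampling
    draws <- matrix(NA_real_, iter_sampling, d)
    lp_store <- numeric(iter_sampling)
    warm_buf <- matrix(NA_real_, iter_warmup, d)
    divergences <- 0L; accepts <- 0L
    cur <- logpost_and_grad(u)
    da_count <- 0
    for (it in seq_len(n_iter)) {
      p0 <- rnorm(d) / sqrt(minv)
      L <- sample(seq(leapfrog[1], leapfrog[2]), 1)
      uu <- u; pp <- p0; gr <- cur$grad
      H0 <- -cur$lp + 0.5 * sum(pp^2 * minv)
      diverged <- FALSE
      prop <- NULL
      for (l in seq_len(L)) {
        pp <- pp + 0.5 * eps * gr
        uu <- uu + eps * minv * pp
        if (any(!is.finite(uu)) || any(abs(uu) > 50)) { diverged <- TRUE; break }
        prop <- logpost_and_grad(uu)
        if (!is.finite(prop$lp)) { diverged <- TRUE; break }
        gr <- prop$grad
        pp <- pp + 0.5 * eps * gr
      }
      if (!diverged) {
        H1 <- -prop$lp + 0.5 * sum(pp^2 * minv)
        dH <- H1 - H0
        if (!is.finite(dH) || dH > 1000) diverged <- TRUE
      }
      a_prob <- if (diverged) 0 else min(1, exp(-dH))
      if (diverged && it > iter_warmup) divergences <- divergences + 1L
      if (!diverged && runif(1) < a_prob) {
        u <- uu; cur <- prop
        if (it > iter_warmup) accepts <- accepts + 1L
      }
      if (it <= iter_warmup) {
        # dual averaging of the step size
        da_count <- da_count + 1
        H_bar <- (1 - 1 / (da_count + t0_da)) * H_bar +
          (target_accept - a_prob) / (da_count + t0_da)
        log_eps <- mu_da - sqrt(da_count) / gamma_da * H_bar
        w <- da_count^(-kappa_da)
        log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
        eps <- exp(log_eps)
        warm_buf[it, ] <- u
        if (it == floor(iter_warmup * 2 / 3)) {
          # diagonal mass from the middle warmup window, then re-adapt eps
          win <- warm_buf[max(1, floor(iter_warmup / 3)):it, , drop = FALSE]
          v <- apply(win, 2, var)
          v[!is.finite(v) | v < 1e-6] <- 1e-6
          minv <- v
          da_count <- 0; H_bar <- 0
          mu_da <- log(10 * eps); log_eps_bar <- log(eps)
        }
        if (it == iter_warmup) eps <- exp(log_eps_bar)
      } else {
        draws[it - iter_warmup, ] <- u
        lp_store[it - iter_warmup] <- cur$lp
      }
    }
    list(draws = draws, lp = lp_store, divergences = divergences,
         accept_rate = accepts / iter_sampling, eps = eps)
  }

  chains_out <- lapply(seq_len(chains), run_chain)
  par_names <- c(free, "sigma_obs")
  arr <- array(NA_real_, c(iter_sampling, chains, d),
               dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(chains)) arr[, ch, ] <- exp(chains_out[[ch]]$draws)

  # pointwise log-likelihood per saved draw (for WAIC)
  flat_u <- do.call(rbind, lapply(chains_out, function(z) z$draws))
  pw <- matrix(NA_real_, nrow(flat_u), pd$n_obs)
  for (i in seq_len(nrow(flat_u))) {
    th <- theta_of_u(flat_u[i, ])
    pw[i, ] <- cpp_panel_loglik(th, vcode, pd$conds, pd$obs_cond, pd$obs_day,
                                pd$obs_lineage, pd$obs_count, rtol,
                                atol)$pointwise
  }

  rhat <- vapply(seq_len(d), function(j) split_rhat(arr[, , j, drop = FALSE]),
                 numeric(1))
  ess <- vapply(seq_len(d), function(j) bulk_ess(arr[, , j, drop = FALSE]),
                numeric(1))
  diagnostics <- data.frame(parameter = par_names, rhat = rhat, ess = ess)
  divergences <- sum(vapply(chains_out, `[[`, integer(1), "divergences"))
  if (any(rhat > 1.05, na.rm = TRUE))
    warn_("convergence warning: split R-hat > 1.05 for %s",
          paste(par_names[rhat > 1.05], collapse = ", "))
  structure(list(
    draws = arr, pointwise_loglik = pw,
    lp = do.call(cbind, lapply(chains_out, `[[`, "lp")),
    diagnostics = diagnostics, divergences = divergences,
    accept_rate = mean(vapply(chains_out, `[[`, numeric(1), "accept_rate")),
    variant = variant, free = free, params = params, priors = priors,
    n_obs = pd$n_obs, seed = seed),
    class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %s model, %d chains x %d draws, %d parameters\n",
              x$variant, dim(x$draws)[2], dim(x$draws)[1], dim(x$draws)[3]))
  cat(sprintf("  mean acceptance %.2f, %d post-warmup divergences\n",
              x$accept_rate, x$divergences))
  print(summary(x), ...)
  invisible(x)
}

#' @export
summary.posterior_draws <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  d <- dim(object$draws)[3]
  out <- do.call(rbind, lapply(seq_len(d), function(j) {
    v <- as.vector(object$draws[, , j])
    q <- quantile(v, probs)
    data.frame(parameter = dimnames(object$draws)[[3]][j],
               mean = mean(v), q2.5 = q[[1]], median = q[[2]], q97.5 = q[[3]],
               rhat = object$diagnostics$rhat[j],
               ess = object$diagnostics$ess[j])
  }))
  rownames(out) <- NULL
  out
}

# split R-hat (two halves per chain)
split_rhat <- function(a) {
  n <- dim(a)[1]; m <- dim(a)[2]
  half <- floor(n / 2)
  sub <- lapply(seq_len(m), function(ch)
    list(a[seq_len(half), ch, 1], a[(n - half + 1):n, ch, 1]))
  chains <- unlist(sub, recursive = FALSE)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars); B <- half * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size via Geyer's initial positive sequence on
# chain-centred draws
bulk_ess <- function(a) {
  n <- dim(a)[1]; m <- dim(a)[2]
  centred <- sapply(seq_len(m), function(ch) a[, ch, 1] - mean(a[, ch, 1]))
  centred <- as.matrix(centred)
  v <- mean(apply(centred, 2, var))
  if (v <= 0) return(NA_real_)
  max_lag <- min(n - 2, 200)
  rho <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    acov <- mean(sapply(seq_len(m), function(ch)
      mean(centred[seq_len(n - lag), ch] * centred[(lag + 1):n, ch])))
    rho[lag] <- acov / v
  }
  tau <- 1; lag <- 1
  while (lag + 1 <= max_lag) {
    pair <- rho[lag] + rho[lag + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    lag <- lag + 2
  }
  n * m / tau
}

#' Watanabe-Akaike information criterion across fitted model variants
#'
#' `waic = -2 (lppd - p_waic)` with the effective parameter count taken
#' from the per-observation variance of the pointwise log-likelihood over
#' draws. Pairwise differences against the best model are reported with
#' standard errors from the pointwise contrasts.
#'
#' @param fits named list of [fit_posterior()] results on the same
#'   observation table.
#' @return object of class `waic_result` with a per-model table and the
#'   name of the best (lowest-WAIC) model.
#' @export
compute_waic <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, `[[`, character(1), "variant")
  nobs <- vapply(fits, function(f) ncol(f$pointwise_loglik), integer(1))
  if (length(unique(nobs)) != 1)
    stop_("models were fitted to differently sized observation tables")
  comp <- lapply(fits, function(f) {
    ll <- f$pointwise_loglik
    lmax <- apply(ll, 2, max)
    lppd_i <- lmax + log(colMeans(exp(sweep(ll, 2, lmax, "-"))))
    p_i <- apply(ll, 2, var)
    list(lppd_i = lppd_i, p_i = p_i,
         waic_i = -2 * (lppd_i - p_i),
         waic = -2 * (sum(lppd_i) - sum(p_i)),
         p_waic = sum(p_i))
  })
  tab <- data.frame(
    model = names(fits),
    waic = vapply(comp, `[[`, numeric(1), "waic"),
    p_waic = vapply(comp, `[[`, numeric(1), "p_waic"))
  best <- tab$model[which.min(tab$waic)]
  bi <- which.min(tab$waic)
  tab$delta_waic <- tab$waic - tab$waic[bi]
  tab$se_delta <- vapply(seq_along(comp), function(i) {
    if (i == bi) return(0)
    di <- comp[[i]]$waic_i - comp[[bi]]$waic_i
    sqrt(length(di) * var(di))
  }, numeric(1))
  rownames(tab) <- NULL
  structure(list(table = tab[order(tab$waic), ], best = best),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat("WAIC model comparison (lower is better)\n")
  print(transform(x$table, waic = round(waic, 1), p_waic = round(p_waic, 1),
                  delta_waic = round(delta_waic, 1),
                  se_delta = round(se_delta, 1)))
  cat("best model:", x$best, "\n")
  invisible(x)
}

#' Relative performance of resistant versus sensitive cells
#'
#' Per-draw ratios R/S of secretion (`gamma`), competitive ability (`K`),
#' baseline division (`r`), quiescence (`lambda`) and drug tolerance (`k`),
#' summarised by the median and central 95% interval. Parameters that were
#' not sampled contribute their fixed values.
#'
#' @param fit a [fit_posterior()] result.
#' @return `data.frame` with one row per trait ratio.
#' @export
relative_performance <- function(fit) {
  traits <- c("gamma", "K", "r", "lambda", "k")
  base <- as_param_vector(fit$params)
  nm <- dimnames(fit$draws)[[3]]
  get_draws <- function(p) {
    if (p %in% nm) as.vector(fit$draws[, , p]) else base[[p]]
  }
  out <- do.call(rbind, lapply(traits, function(tr) {
    num <- get_draws(paste0(tr, "_R"))
    den <- get_draws(paste0(tr, "_S"))
    ratio <- num / den
    bad <- !is.finite(ratio)
    if (any(bad)) ratio <- ratio[!bad]
    q <- quantile(ratio, c(0.025, 0.5, 0.975))
    data.frame(trait = tr, median = q[[2]], q2.5 = q[[1]], q97.5 = q[[3]],
               n_excluded = sum(bad))
  }))
  rownames(out) <- NULL
  out
}
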