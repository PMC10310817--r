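# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

#' Multi-start bounded optimisation on the log-parameter scale
#'
#' Runs Nelder-Mead from several dispersed starting points (positive
#' parameters are optimised as logs so scale differences do not matter) and
#' polishes the best solution with BFGS. Used by the nonlinear least-squares
#' fitters, which the design requires to be robust to local minima.
#'
#' @param fn objective taking a positive parameter vector, returning a scalar.
#' @param start named vector of positive starting values.
#' @param n_starts number of starts (the first is `start` itself; the rest
#'   are lognormal perturbations with fixed seeds).
#' @param spread log-scale SD of the perturbations.
#' @return list with `par` (positive scale) and `value`.
#' @keywords internal
multistart_optim <- function(fn, start, n_starts = 8, spread = 1) {
  stopifnot(all(start > 0))
  lfn <- function(lp) {
    v <- fn(exp(lp))
    if (!is.finite(v)) 1e300 else v
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    lp0 <- if (s == 1) log(start) else {
      set.seed(1000 + s)
      log(start) + rnorm(length(start), 0, spread)
    }
    res <- tryCatch(
      optim(lp0, lfn, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop_("optimisation failed from all starting points")
  pol <- tryCatch(
    optim(best$par, lfn, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) best <- pol
  list(par = setNames(exp(best$par), names(start)), value = best$value)
}

# Deterministic per-purpose RNG substream: hash a base seed with a stream
# label so generators never share or depend on global RNG state.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}
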