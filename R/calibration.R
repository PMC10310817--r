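# Cell-count calibration: spheroid area + two-channel fluorescence ->
# per-lineage cell numbers. A standard curve maps total cells to area
# (quadratic for CAMA-1-style data, Michaelis-Menten for MCF7/LY2-style
# data); the split between lineages comes from the fluorescence fractions
# with the R channel down-weighted by its per-cell brightness excess.

#' Standard curve relating total cells to spheroid area
#'
#' @param form `"quadratic"` (`area = c0 + c1 N + c2 N^2`) or
#'   `"michaelis_menten"` (`area = A N / (K + N)` with maximum `A` and
#'   half-saturation cell count `K`).
#' @param coefficients named vector: `c0, c1, c2` (quadratic) or `A, K`
#'   (Michaelis-Menten).
#' @param range cell-number range the curve was fitted over (used to pick
#'   the physical root when inverting a quadratic).
#' @param rss residual sum of squares of the fit, if known.
#' @export
area_curve <- function(form = c("michaelis_menten", "quadratic"),
                       coefficients, range = NULL, rss = NA_real_) {
  form <- match.arg(form)
  co <- coefficients
  if (form == "michaelis_menten") {
    if (!all(c("A", "K") %in% names(co))) stop_("MM curve needs A and K")
    if (co[["A"]] <= 0 || co[["K"]] <= 0) stop_("MM curve needs A > 0, K > 0")
  } else {
    if (!all(c("c0", "c1", "c2") %in% names(co)))
      stop_("quadratic curve needs c0, c1, c2")
  }
  structure(list(form = form, coefficients = co, range = range, rss = rss),
            class = "area_curve")
}

#' @export
print.area_curve <- function(x, ...) {
  co <- x$coefficients
  if (x$form == "michaelis_menten")
    cat(sprintf("Michaelis-Menten area curve: A = %.6g, K = %.6g (RSS = %.4g)\n",
                co[["A"]], co[["K"]], x$rss))
  else
    cat(sprintf("Quadratic area curve: %.6g + %.6g N + %.6g N^2 (RSS = %.4g)\n",
                co[["c0"]], co[["c1"]], co[["c2"]], x$rss))
  invisible(x)
}

#' @export
predict.area_curve <- function(object, N, ...) {
  co <- object$coefficients
  if (object$form == "michaelis_menten")
    co[["A"]] * N / (co[["K"]] + N)
  else
    co[["c0"]] + co[["c1"]] * N + co[["c2"]] * N^2
}

#' Fit a standard curve to calibration records
#'
#' Least-squares fit of area as a function of total cells. The separate
#' curves the experiments use per composition class (pure-S, pure-R, mixed)
#' are obtained by fitting this on the corresponding subset of records.
#'
#' @param records calibration table.
#' @param form curve form (see [area_curve()]).
#' @return an [area_curve()] with the residual sum of squares attached.
#' @export
fit_area_curve <- function(records, form = c("michaelis_menten", "quadratic")) {
  form <- match.arg(form)
  N <- records$n_sensitive + records$n_resistant
  area <- records$area
  nx <- length(unique(N))
  if (max(area) - min(area) < 1e-12 * max(1, max(abs(area))))
    stop_("degenerate calibration: area does not vary with cell number")
  if (form == "quadratic") {
    if (nx < 3) stop_("quadratic curve needs >= 3 distinct cell numbers")
    fit <- lm(area ~ N + I(N^2))
    co <- setNames(coef(fit), c("c0", "c1", "c2"))
    curve <- area_curve("quadratic", co, range = range(N),
                        rss = sum(fit$residuals^2))
    grid <- seq(min(N), max(N), length.out = 64)
    if (any(diff(predict(curve, grid)) < 0))
      warn_("fitted quadratic is not monotone increasing over the data range")
    curve
  } else {
    if (nx < 2) stop_("Michaelis-Menten curve needs >= 2 distinct cell numbers")
    start <- list(A = max(area) * 1.5, K = stats::median(N))
    fit <- minpack.lm::nlsLM(area ~ A * N / (K + N), start = start,
                             lower = c(1e-12, 1e-12),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    co <- coef(fit)
    area_curve("michaelis_menten", c(A = unname(co[["A"]]), K = unname(co[["K"]])),
               range = range(N), rss = sum(stats::residuals(fit)^2))
  }
}

#' Invert a standard curve: area to total cells
#'
#' Michaelis-Menten: `N = K a / (A - a)`, defined for `a < A`. Quadratic:
#' the non-negative root on the monotone branch; if two non-negative roots
#' exist, the one inside the fitted range is used (tie: the smaller, with a
#' warning).
#'
#' @param curve an [area_curve()].
#' @param area observed area(s).
#' @return total cell number(s), >= 0.
#' @export
invert_area <- function(curve, area) {
  co <- curve$coefficients
  if (curve$form == "michaelis_menten") {
    if (any(area < 0)) stop_("area must be >= 0")
    if (any(area >= co[["A"]]))
      stop_("area >= curve maximum A: outside the invertible range")
    co[["K"]] * area / (co[["A"]] - area)
  } else {
    vapply(area, function(a) {
      c2 <- co[["c2"]]; c1 <- co[["c1"]]; c0 <- co[["c0"]] - a
      if (abs(c2) < 1e-300) {
        if (c1 == 0) stop_("quadratic inversion undefined: zero slope")
        root <- -c0 / c1
        if (root < 0) stop_("no non-negative root for area %.4g", a)
        return(root)
      }
      disc <- c1^2 - 4 * c2 * c0
      if (disc < 0) stop_("no real root for area %.4g", a)
      roots <- sort((-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2))
      roots <- roots[roots >= 0]
      if (length(roots) == 0) stop_("no non-negative root for area %.4g", a)
      if (length(roots) == 2 && !is.null(curve$range)) {
        inside <- roots >= curve$range[1] & roots <= curve$range[2]
        if (sum(inside) == 1) return(roots[inside])
        warn_("ambiguous quadratic inversion at area %.4g: using smaller root", a)
      }
      roots[1]
    }, numeric(1))
  }
}

#' Per-cell fluorescence model
#'
#' @param slope_S,slope_R intensity per cell in each channel.
#' @return object with slopes and `weight = slope_R / slope_S`, the factor
#'   by which each resistant cell out-shines a sensitive cell.
#' @export
fluorescence_model <- function(slope_S, slope_R) {
  if (slope_S <= 0 || slope_R <= 0) stop_("slopes must be positive")
  structure(list(slope_S = slope_S, slope_R = slope_R,
                 weight = slope_R / slope_S),
            class = "fluorescence_model")
}

#' @export
print.fluorescence_model <- function(x, ...) {
  cat(sprintf("Fluorescence model: slope_S = %.6g, slope_R = %.6g, weight = %.3f\n",
              x$slope_S, x$slope_R, x$weight))
  invisible(x)
}

#' Fit the per-cell fluorescence slopes from pure cultures
#'
#' Through-origin regressions of each channel's intensity against the known
#' cell numbers of the matching pure cultures (zero cells produce zero
#' signal).
#'
#' @param records calibration table containing pure-S and pure-R rows.
#' @return a [fluorescence_model()].
#' @export
fit_fluorescence <- function(records) {
  pureS <- records[records$n_resistant == 0 & records$n_sensitive > 0, ]
  pureR <- records[records$n_sensitive == 0 & records$n_resistant > 0, ]
  if (nrow(pureS) == 0 || nrow(pureR) == 0)
    stop_("need pure-culture records of both lineages")
  sS <- coef(lm(fluor_s ~ 0 + n_sensitive, data = pureS))[[1]]
  sR <- coef(lm(fluor_r ~ 0 + n_resistant, data = pureR))[[1]]
  fluorescence_model(sS, sR)
}

#' Split a total cell count into lineages by fluorescence fractions
#'
#' `S = N f_S / (f_S + f_R / w)` and `R = N - S`, where `w` is the per-cell
#' brightness of R relative to S. The split conserves the total exactly.
#'
#' @param total_cells total cells from [invert_area()].
#' @param fluor_S,fluor_R channel intensities.
#' @param model a [fluorescence_model()].
#' @return named vector `c(S = , R = )`.
#' @export
unmix_counts <- function(total_cells, fluor_S, fluor_R, model) {
  if (total_cells < 0) stop_("total cells must be >= 0")
  if (fluor_S < 0 || fluor_R < 0) stop_("fluorescence must be >= 0")
  if (total_cells > 0 && fluor_S == 0 && fluor_R == 0)
    stop_("both channels zero with cells present: proportions undefined")
  if (total_cells == 0) return(c(S = 0, R = 0))
  S <- total_cells * fluor_S / (fluor_S + fluor_R / model$weight)
  c(S = S, R = total_cells - S)
}
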