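#' Endpoint response as percent of vehicle
#'
#' @param treated_endpoint Endpoint signal under treatment (e.g. live-cell
#'   count).
#' @param vehicle_endpoint Same-plate vehicle endpoint; must be positive.
#' @return Percent response, `100 * treated / vehicle`. Values above 100
#'   (treated exceeding vehicle) are returned unclipped with attribute
#'   `exceeds_vehicle` set.
#' @export
percent_response <- function(treated_endpoint, vehicle_endpoint) {
  if (any(vehicle_endpoint <= 0)) stop("vehicle endpoint must be positive")
  out <- 100 * treated_endpoint / vehicle_endpoint
  attr(out, "exceeds_vehicle") <- any(out > 100)
  out
}

#' Predicted four-parameter logistic response
#'
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`; at dose 0 the
#' response equals the limit `top` (for positive hill).
#'
#' @param dose Doses (same units as `ic50`); zero allowed.
#' @param top,bottom,ic50,hill 4PL parameters.
#' @return Predicted response.
#' @export
fourpl <- function(dose, top, bottom, ic50, hill) {
  y <- rep(if (hill > 0) top else bottom, length(dose))
  pos <- dose > 0
  y[pos] <- bottom + (top - bottom) / (1 + (dose[pos] / ic50)^hill)
  y
}

#' Constrained four-parameter logistic IC50 fit
#'
#' Least-squares fit of the 4PL model to percent-of-vehicle responses with
#' the asymptotes restrained to \[0, 100\]% (bottom >= 0, top <= 100,
#' bottom <= top). The IC50 is optimized on the log scale with a 10-point
#' log-spaced multi-start grid spanning the nonzero dose range (times hill
#' starts of 0.5, 1 and 2), followed by local refinement; the lowest
#' residual sum of squares wins. Degenerate inputs (constant responses)
#' return a non-converged fit rather than an error.
#'
#' @param dose Doses in nM; vehicle rows coded as dose 0 participate through
#'   the top asymptote.
#' @param response Responses in percent of vehicle.
#' @return A `fourpl_fit` list: `top`, `bottom`, `ic50`, `hill`, `rss`,
#'   `converged`.
#' @export
fit_4pl <- function(dose, response) {
  stopifnot(length(dose) == length(response), all(dose >= 0))
  nz <- sort(unique(dose[dose > 0]))
  if (length(nz) < 3L) stop("need >= 3 distinct nonzero doses")
  degenerate <- stats::sd(response) < sqrt(.Machine$double.eps)
  obj <- function(par) {
    bottom <- par[1]; top <- par[2]
    if (bottom > top) return(1e12 * (1 + bottom - top))
    sum((response - fourpl(dose, top, bottom, exp(par[3]), par[4]))^2)
  }
  grid_ic50 <- exp(seq(log(min(nz)), log(max(nz)), length.out = 10))
  b0 <- min(max(min(response), 0), 100)
  t0 <- min(max(max(response), 0), 100)
  best <- NULL
  objectives <- numeric(0)
  for (g in grid_ic50) {
    for (h in c(0.5, 1, 2)) {
      fit <- try(stats::nlminb(
        start = c(b0, t0, log(g), h), objective = obj,
        lower = c(0, 0, log(min(nz)) - 12, -10),
        upper = c(100, 100, log(max(nz)) + 12, 10),
        control = list(iter.max = 500, eval.max = 1000,
                       rel.tol = 1e-12, x.tol = 1e-12)
      ), silent = TRUE)
      if (inherits(fit, "try-error")) next
      objectives <- c(objectives, fit$objective)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  }
  if (is.null(best) || !is.finite(best$objective)) {
    return(structure(list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                          hill = NA_real_, rss = NA_real_, converged = FALSE),
                     class = "fourpl_fit"))
  }
  # convergence is judged by multi-start agreement, not optimizer exit
  # codes (nlminb reports "singular/false convergence" at box bounds even
  # when the optimum is found): at least two independent starts must land
  # in the same minimum
  agree <- sum(objectives <= best$objective * (1 + 1e-6) + 1e-9)
  structure(list(
    top = best$par[2], bottom = best$par[1],
    ic50 = exp(best$par[3]), hill = best$par[4],
    rss = best$objective,
    converged = !degenerate && agree >= 2L
  ), class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: IC50 = %.4g, hill = %.3g, top = %.4g%%, bottom = %.4g%% (RSS %.4g%s)\n",
    x$ic50, x$hill, x$top, x$bottom, x$rss,
    if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' Summarize IC50 over independent experiments
#'
#' Arithmetic mean of the converged per-experiment IC50 estimates with a
#' t-based 95% confidence interval. With fewer than two converged fits the
#' interval is undefined and flagged.
#'
#' @param fits List of [fit_4pl()] results (or a numeric vector of IC50s).
#' @param conf_level Confidence level for the interval.
#' @return List: `mean_ic50`, `ci_lower`, `ci_upper`, `n`, `ci_defined`.
#' @export
ic50_summary <- function(fits, conf_level = 0.95) {
  ic50 <- if (is.numeric(fits)) fits else
    vapply(Filter(function(f) isTRUE(f$converged), fits),
           `[[`, numeric(1), "ic50")
  n <- length(ic50)
  if (n < 2L) {
    return(list(mean_ic50 = if (n) mean(ic50) else NA_real_,
                ci_lower = NA_real_, ci_upper = NA_real_,
                n = n, ci_defined = FALSE))
  }
  m <- mean(ic50)
  half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
    stats::sd(ic50) / sqrt(n)
  list(mean_ic50 = m, ci_lower = m - half, ci_upper = m + half,
       n = n, ci_defined = TRUE)
}

#' Apoptotic death ratio
#'
#' Ratio of caspase-3/7 positive (dead) cells to live cells at a timepoint,
#' the per-timepoint apoptosis measure that corrects for reduced cell
#' numbers at growth-inhibitory doses.
#'
#' @param caspase_positive Dead (caspase-positive) cell count.
#' @param live Live cell count; zero yields `NA` with a warning.
#' @return Numeric ratio.
#' @export
death_ratio <- function(caspase_positive, live) {
  stopifnot(all(caspase_positive >= 0), all(live >= 0))
  out <- ifelse(live > 0, caspase_positive / live, NA_real_)
  if (any(live == 0)) warning("live == 0: death ratio undefined (NA)")
  out
}

#' Exponential growth-rate fit
#'
#' Ordinary least squares of `log(signal)` on time: `k` is the slope
#' (per unit time) and `r2` the coefficient of determination on the log
#' scale, the standard analysis for log-transformed tumour-growth data.
#'
#' @param time Timepoints (e.g. days).
#' @param signal Positive growth signal (e.g. bioluminescence).
#' @return An `exponential_fit` list: `k`, `intercept`, `r2`.
#' @export
exponential_fit <- function(time, signal) {
  stopifnot(length(time) == length(signal), length(time) >= 3L)
  if (any(signal <= 0)) {
    stop("nonpositive signal at timepoint ", time[which(signal <= 0)[1]])
  }
  fit <- stats::lm(log(signal) ~ time)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((log(signal) - mean(log(signal)))^2)
  r2 <- if (tss == 0) 1 else max(0, 1 - rss / tss)
  structure(list(
    k = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = r2
  ), class = "exponential_fit")
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#'         (Ct_target,vehicle - Ct_ref,vehicle)`; fold change `2^-ddCt`
#' relative to vehicle, normalized to the reference gene (e.g. GAPDH).
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_vehicle,ct_ref_vehicle
#'   Cycle-threshold values; vectorized.
#' @return List: `delta_delta_ct`, `fold_change`.
#' @export
delta_delta_ct <- function(ct_target_treated, ct_ref_treated,
                           ct_target_vehicle, ct_ref_vehicle) {
  stopifnot(is.finite(ct_target_treated), is.finite(ct_ref_treated),
            is.finite(ct_target_vehicle), is.finite(ct_ref_vehicle))
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_vehicle - ct_ref_vehicle)
  list(delta_delta_ct = ddct, fold_change = 2^(-ddct))
}
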