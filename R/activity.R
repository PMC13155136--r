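#' Clonogenic activity with confidence interval
#'
#' The clonogenic activity `a = exp(-alpha / b)` is the number of cells that
#' must be seeded per well so that on average one clonogenic cell arises
#' (`lambda = 1`), i.e. the seeding density at which about 37% (`exp(-1)`)
#' of wells show growth failure. Under linear clonogenicity (`b = 1`) it
#' equals the inverse of the active cell frequency; under cooperation or
#' competition a frequency reading is misleading and `a` is interpreted
#' directly as a cell number.
#'
#' Two interval methods are provided:
#' \describe{
#'   \item{`band_inversion`}{Fieller-type inversion of the link-scale
#'     confidence band: the bounds are the seeding densities at which the
#'     band around `eta(S) = alpha + b ln S` crosses zero (`mu = exp(-1)`),
#'     i.e. the roots in `x = ln S` of
#'     `(alpha + b x)^2 = z^2 (Var(alpha) + 2 x Cov(alpha,b) + x^2 Var(b))`.
#'     When the quadratic's leading coefficient `b^2 - z^2 Var(b)` is not
#'     positive, or the roots fail to bracket `ln a`, the band never
#'     re-crosses the 37% line on that side and the affected bound is
#'     reported unbounded (0 or `Inf`) with a warning.}
#'   \item{`delta`}{first-order Taylor (delta-method) propagation on
#'     `ln a = -alpha / b`, with
#'     `Var(ln a) = Var(alpha)/b^2 + alpha^2 Var(b)/b^4 - 2 alpha Cov(alpha,b)/b^3`
#'     and `CI = a * exp(+/- z * sd)`.}
#' }
#'
#' @param fit a converged [fit_loglog_glm()] result with `b > 0`.
#' @param level confidence level, default 0.95 (0.835 is used as the
#'   component level when assembling survival-fraction intervals).
#' @param method `"band_inversion"` (default) or `"delta"`.
#' @return An object of class `activity_estimate`: list with `a`, `lower`,
#'   `upper`, `level`, `method`, `capacity_percent` (`100 / a`; frequency-
#'   interpretable only when `b` is close to 1) and `b`.
#' @examples
#' d <- data.frame(cells_per_well = c(1, 2, 4, 8, 16, 32),
#'                 n_wells = 24, n_negative = c(22, 20, 15, 9, 3, 1))
#' clonogenic_activity(fit_loglog_glm(d))
#' @export
clonogenic_activity <- function(fit, level = 0.95,
                                method = c("band_inversion", "delta")) {
  stopifnot(inherits(fit, "loglog_fit"))
  method <- match.arg(method)
  if (!fit$converged) {
    stop_estimation_error("fit did not converge; clonogenic activity not estimable")
  }
  if (fit$b <= 0) stop_estimation_error("nonlinearity coefficient b must be positive")
  if (level <= 0 || level >= 1) stop_input_error("level must be in (0, 1)")

  a <- exp(-fit$alpha / fit$b)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- if (method == "band_inversion") {
    fieller_bounds(fit, z, log(a))
  } else {
    delta_bounds(fit, z, a)
  }
  structure(list(a = a, lower = ci[1L], upper = ci[2L], level = level,
                 method = method, capacity_percent = 100 / a, b = fit$b),
            class = "activity_estimate")
}

# Roots in x = ln S of g(x) = (alpha + b x)^2 - z^2 * Var(eta(x)) = 0.
# The confidence set for ln a is {x : g(x) <= 0}; since g(ln a) < 0 the set
# always contains ln a. With leading coefficient A = b^2 - z^2 Var(b) > 0 it
# is the finite interval between the roots; with A <= 0 (slope not
# significantly distinct from 0) the band never re-crosses the 37% line on
# one or both sides and the affected bound is unbounded.
fieller_bounds <- function(fit, z, log_a) {
  va <- fit$cov[1L, 1L]
  if (fit$slope_fixed) {
    vb <- 0; cab <- 0
  } else {
    vb <- fit$cov[2L, 2L]; cab <- fit$cov[1L, 2L]
  }
  A <- fit$b^2 - z^2 * vb
  B <- 2 * (fit$alpha * fit$b - z^2 * cab)
  C <- fit$alpha^2 - z^2 * va
  disc <- B^2 - 4 * A * C
  if (A > 0 && disc > 0) {
    roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
    if (roots[1L] <= log_a && log_a <= roots[2L]) {
      return(exp(roots))
    }
  } else if (A < 0 && disc > 0) {
    roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
    if (log_a > roots[2L]) {        # containing component is [r2, Inf)
      warning("link-scale confidence band does not re-cross the 37% failure line above the estimate; upper activity bound unbounded")
      return(c(exp(roots[2L]), Inf))
    }
    if (log_a < roots[1L]) {        # containing component is (-Inf, r1]
      warning("link-scale confidence band does not re-cross the 37% failure line below the estimate; lower activity bound unbounded")
      return(c(0, exp(roots[1L])))
    }
  }
  warning("link-scale confidence band never re-crosses the 37% failure line; activity CI reported unbounded on both sides")
  c(0, Inf)
}

delta_bounds <- function(fit, z, a) {
  va <- fit$cov[1L, 1L]
  if (fit$slope_fixed) {
    v <- va
  } else {
    vb <- fit$cov[2L, 2L]; cab <- fit$cov[1L, 2L]
    v <- va / fit$b^2 + fit$alpha^2 * vb / fit$b^4 -
      2 * fit$alpha * cab / fit$b^3
  }
  a * exp(c(-1, 1) * z * sqrt(max(v, 0)))
}

#' @export
print.activity_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Clonogenic activity a = %.*g, %g%% CI [%.*g, %.*g] (%s)\n",
              digits, x$a, 100 * x$level, digits, x$lower, digits, x$upper,
              x$method))
  cat(sprintf("  capacity = %.*g%% (frequency reading valid only near b = 1; b = %.*g)\n",
              digits, x$capacity_percent, digits, x$b))
  invisible(x)
}

#' Clonogenic activity per treatment (and replicate)
#'
#' Batch version of [clonogenic_activity()]: pooled mode fits each
#' treatment after summing replicate wells, per-replicate mode fits each
#' (treatment, replicate) group separately. Groups whose every well is
#' negative carry no evidence of clonogenic growth; they appear in the
#' output flagged through `refused_reason` instead of being dropped.
#'
#' @param experiment an [lda_experiment()].
#' @param mode `"pooled"` or `"per_replicate"`.
#' @param level confidence level.
#' @param method interval method, see [clonogenic_activity()].
#' @return data.frame with columns `treatment`, `replicate`, `a`,
#'   `ci_lower`, `ci_upper`, `level`, `method`, `capacity_percent`, `b`,
#'   `refused_reason`.
#' @export
activity_table <- function(experiment, mode = c("pooled", "per_replicate"),
                           level = 0.95,
                           method = c("band_inversion", "delta")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  x <- if (mode == "pooled") pool_replicates(experiment) else experiment
  rows <- lapply(lda_groups(x), function(g) {
    base <- data.frame(treatment = g$treatment[1L], replicate = g$replicate[1L])
    est <- tryCatch(
      suppressWarnings(clonogenic_activity(fit_loglog_glm(g), level = level,
                                           method = method)),
      error = function(e) e)
    if (inherits(est, "error")) {
      cbind(base, a = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
            level = level, method = method, capacity_percent = NA_real_,
            b = NA_real_, refused_reason = conditionMessage(est))
    } else {
      cbind(base, a = est$a, ci_lower = est$lower, ci_upper = est$upper,
            level = level, method = method,
            capacity_percent = est$capacity_percent, b = est$b,
            refused_reason = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
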