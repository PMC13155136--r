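# SF intervals at 95% are assembled from 83.5% activity intervals; both are
# configuration constants, not magic numbers inside the formulas.
.sf_level <- 0.95
.sf_component_level <- 0.835

#' Survival fraction of a treated group relative to the reference
#'
#' The survival fraction is the ratio of the numbers of cells required to
#' reach the same reference activity (37% well failure) without and with
#' treatment: `SF = a0 / at = exp(alpha_t / b_t - alpha_0 / b_0)`, where
#' `(alpha_0, b_0)` are fitted to the untreated reference and
#' `(alpha_t, b_t)` to the treated group. "Survival" refers to retention of
#' clonogenic capacity after treatment.
#'
#' The 95% confidence interval is assembled from the `component_level`
#' (default 83.5%) band-inversion intervals of the two activities:
#' `(a0_lb / at_ub, a0_ub / at_lb)`. Combining 83.5% component intervals
#' yields close to 95% coverage for the ratio. If a component bound is
#' unbounded the corresponding SF bound is 0 or `Inf`, with a warning
#' propagated from the activity step.
#'
#' @param fit_ref converged fit of the untreated reference group.
#' @param fit_treat converged fit of the treated group.
#' @param component_level level of the component activity intervals
#'   (default 0.835, targeting a 95% interval for the ratio).
#' @return Object of class `survival_fraction`: list with `sf`, `ci_lower`,
#'   `ci_upper`, `level` (0.95), `a_ref`, `a_treat`.
#' @examples
#' ref <- fit_loglog_glm(data.frame(cells_per_well = c(1, 4, 16, 64),
#'                                  n_wells = 24, n_negative = c(22, 16, 5, 0)))
#' trt <- fit_loglog_glm(data.frame(cells_per_well = c(1, 4, 16, 64),
#'                                  n_wells = 24, n_negative = c(24, 22, 16, 4)))
#' survival_fraction(ref, trt)
#' @export
survival_fraction <- function(fit_ref, fit_treat,
                              component_level = .sf_component_level) {
  stopifnot(inherits(fit_ref, "loglog_fit"), inherits(fit_treat, "loglog_fit"))
  a0 <- clonogenic_activity(fit_ref, level = component_level)
  at <- clonogenic_activity(fit_treat, level = component_level)
  sf <- exp(fit_treat$alpha / fit_treat$b - fit_ref$alpha / fit_ref$b)
  ci <- combine_activity_intervals(a0$lower, a0$upper, at$lower, at$upper)
  structure(list(
    sf = sf,
    ci_lower = ci[["lower"]],
    ci_upper = ci[["upper"]],
    level = .sf_level,
    component_level = component_level,
    a_ref = a0$a, a_treat = at$a
  ), class = "survival_fraction")
}

#' Combine component activity intervals into a ratio interval
#'
#' The 95% interval of a survival fraction `SF = a0 / at` is assembled from
#' the 83.5% intervals of the two clonogenic activities as
#' `(a0_lb / at_ub, a0_ub / at_lb)`: the ratio is smallest when the
#' numerator sits at its lower and the denominator at its upper bound.
#'
#' @param ref_lower,ref_upper component interval of the reference activity.
#' @param treat_lower,treat_upper component interval of the treated
#'   activity.
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' combine_activity_intervals(9, 11, 18, 22)  # c(9/22, 11/18)
#' @export
combine_activity_intervals <- function(ref_lower, ref_upper,
                                       treat_lower, treat_upper) {
  c(lower = ref_lower / treat_upper, upper = ref_upper / treat_lower)
}

#' @export
print.survival_fraction <- function(x, digits = 4, ...) {
  cat(sprintf("Survival fraction SF = %.*g, %g%% CI [%.*g, %.*g]\n",
              digits, x$sf, 100 * x$level, digits, x$ci_lower,
              digits, x$ci_upper))
  invisible(x)
}

#' Survival fractions for all treatments of an experiment
#'
#' In `"pooled"` mode replicate wells are summed per treatment before
#' fitting and one SF (with its combined-interval 95% CI) is reported per
#' treatment. In `"per_replicate"` mode SF is computed within each
#' biological replicate against that replicate's own reference fit; the
#' reported value is the mean across replicates with its standard error,
#' and the 95% CI is `mean +/- t * sem` on `r - 1` degrees of freedom —
#' appropriate for the small replicate counts typical of these assays.
#' There is no automatic choice between the modes; use
#' [binomial_expectation_range()] to judge whether inter-replicate
#' variability exceeds the intrinsic binomial stochasticity.
#'
#' @param experiment an [lda_experiment()] whose reference treatment is
#'   estimable (an all-negative reference is a hard error: nothing can be
#'   normalized).
#' @param mode `"pooled"` or `"per_replicate"`.
#' @param component_level level of the component activity intervals.
#' @return data.frame with columns `treatment`, `reference`, `sf`,
#'   `ci95_lower`, `ci95_upper`, `mode`, `n_replicates`, `sem`, and in
#'   per-replicate mode the attribute `per_replicate_values` (a named list
#'   of the replicate-level SF values per treatment).
#' @export
survival_table <- function(experiment, mode = c("pooled", "per_replicate"),
                           component_level = .sf_component_level) {
  stopifnot(inherits(experiment, "lda_experiment"))
  mode <- match.arg(mode)
  ref_label <- experiment$reference
  treatments <- unique(experiment$data$treatment)

  if (mode == "pooled") {
    pooled <- pool_replicates(experiment)
    fits <- lapply(split(pooled$data, pooled$data$treatment)[treatments],
                   function(g) tryCatch(fit_loglog_glm(g), error = function(e) e))
    if (inherits(fits[[ref_label]], "error")) {
      stop_estimation_error(sprintf(
        "reference treatment '%s' is not estimable: %s", ref_label,
        conditionMessage(fits[[ref_label]])))
    }
    rows <- lapply(treatments, function(tr) {
      base <- data.frame(treatment = tr, reference = ref_label)
      f <- fits[[tr]]
      if (inherits(f, "error")) {
        return(cbind(base, sf = NA_real_, ci95_lower = NA_real_,
                     ci95_upper = NA_real_, mode = mode,
                     n_replicates = NA_integer_, sem = NA_real_))
      }
      s <- survival_fraction(fits[[ref_label]], f,
                             component_level = component_level)
      if (tr == ref_label) s$sf <- 1  # self-comparison is exactly 1
      cbind(base, sf = s$sf, ci95_lower = s$ci_lower, ci95_upper = s$ci_upper,
            mode = mode,
            n_replicates = length(unique(
              experiment$data$replicate[experiment$data$treatment == tr])),
            sem = NA_real_)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }

  # per_replicate: SF within each replicate against its own reference fit
  d <- experiment$data
  replicates <- unique(d$replicate)
  sf_by_rep <- lapply(replicates, function(r) {
    dr <- d[d$replicate == r, ]
    fit_of <- function(tr) tryCatch(fit_loglog_glm(dr[dr$treatment == tr, ]),
                                    error = function(e) e)
    f0 <- fit_of(ref_label)
    if (inherits(f0, "error")) return(NULL)
    vapply(treatments, function(tr) {
      if (!tr %in% dr$treatment) return(NA_real_)
      f <- fit_of(tr)
      if (inherits(f, "error")) return(NA_real_)
      if (tr == ref_label) return(1)
      survival_fraction(f0, f, component_level = component_level)$sf
    }, numeric(1))
  })
  sf_by_rep <- Filter(Negate(is.null), sf_by_rep)
  if (!length(sf_by_rep)) {
    stop_estimation_error(sprintf(
      "reference treatment '%s' is not estimable in any replicate", ref_label))
  }
  sf_mat <- do.call(rbind, sf_by_rep)   # replicates x treatments
  rows <- lapply(seq_along(treatments), function(j) {
    vals <- sf_mat[, j]
    vals <- vals[is.finite(vals)]
    r <- length(vals)
    m <- if (r) mean(vals) else NA_real_
    sem <- if (r > 1) stats::sd(vals) / sqrt(r) else if (r == 1) 0 else NA_real_
    half <- if (r > 1) stats::qt(1 - (1 - .sf_level) / 2, df = r - 1) * sem else 0
    data.frame(treatment = treatments[j], reference = ref_label, sf = m,
               ci95_lower = m - half, ci95_upper = m + half,
               mode = mode, n_replicates = r, sem = sem)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_replicate_values") <-
    stats::setNames(lapply(seq_along(treatments), function(j) sf_mat[, j]),
                    treatments)
  out
}

#' Binomial expectation range of negative-well counts
#'
#' Quantifies the intrinsic stochasticity of a well count: for `n` wells
#' each failing independently with probability `p`, returns the equal-tail
#' expectation range `[lo, hi]` of the number of negative wells at the
#' given level, by exact summation of the binomial CDF (`lo` is the
#' smallest `k` with `CDF(k) >= (1 - level)/2`, `hi` the smallest `k` with
#' `CDF(k) >= 1 - (1 - level)/2`). The corresponding range of the
#' log failure fraction, `ln_mu_range = (ln(lo/n), ln(hi/n))`, is the
#' yardstick against which inter-replicate variability should be judged
#' when deciding whether to pool replicates before fitting; `lo = 0` maps
#' to `-Inf`. For example, 12 wells at `p = 1/3` give an expectation range
#' of 1 to 7 negative wells, i.e. about -2.5 to -0.5 on the `ln(mu)` scale.
#'
#' @param n number of wells (positive integer).
#' @param p failure probability per well, in `[0, 1]`.
#' @param level coverage level of the range, default 0.95.
#' @return list with `lo`, `hi` (integer counts) and `ln_mu_range`
#'   (numeric length 2).
#' @examples
#' binomial_expectation_range(12, 1/3)
#' @export
binomial_expectation_range <- function(n, p, level = 0.95) {
  if (length(n) != 1L || n < 1 || n != round(n)) {
    stop_input_error("n must be a positive integer")
  }
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop_input_error("p must be a probability in [0, 1]")
  }
  if (length(level) != 1L || level <= 0 || level >= 1) {
    stop_input_error("level must be in (0, 1)")
  }
  cdf <- cumsum(stats::dbinom(0:n, n, p))
  lo <- which(cdf >= (1 - level) / 2)[1L] - 1L
  hi <- which(cdf >= 1 - (1 - level) / 2)[1L] - 1L
  list(lo = lo, hi = hi,
       ln_mu_range = c(if (lo == 0L) -Inf else log(lo / n),
                       if (hi == 0L) -Inf else log(hi / n)))
}
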