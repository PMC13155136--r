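#' Fit the power-law single-hit model to LDA counts
#'
#' Maximizes the binomial likelihood of the well failure counts
#' `Y_i ~ Binomial(n_i, mu_i)` with
#' `mu_i = exp(-exp(alpha + b * ln S_i))`, i.e. a binomial regression of the
#' failure fraction with a log-log link and covariate `ln S`. With
#' `slope_fixed = TRUE` the nonlinearity coefficient is held at `b = 1`
#' (the classical single-hit Poisson model, `lambda = p * S`) and only the
#' intercept `alpha = ln p` is estimated.
#'
#' Estimation is by Fisher scoring with step-halving; convergence requires a
#' score norm below `1e-8` on the link scale (at most 100 iterations). The
#' reported covariance is the inverse expected Fisher information at the
#' optimum, as returned by standard GLM machinery for this link.
#' Observations at the boundary (`Y_i = 0` or `Y_i = n_i`) enter the
#' likelihood without any continuity correction.
#'
#' Degenerate data are handled explicitly: if every well in every dilution
#' is negative there is no evidence of clonogenic growth and estimation is
#' refused with an error; if every well is positive everywhere the
#' likelihood is maximized at the parameter-space boundary and the result is
#' flagged `converged = FALSE` with a warning instead of an arbitrary
#' estimate.
#'
#' @param data a data.frame with columns `cells_per_well`, `n_wells`,
#'   `n_negative` (one (treatment, replicate) group), or an
#'   [lda_experiment()] holding exactly one group.
#' @param slope_fixed logical; fix `b = 1`?
#' @return An object of class `loglog_fit` with elements `alpha`, `b`,
#'   `cov` (2x2, or 1x1 for the fixed slope), `log_likelihood`, `deviance`,
#'   `aic`, `n_params`, `slope_fixed`, `converged` and `data`.
#' @examples
#' d <- data.frame(cells_per_well = c(1, 4), n_wells = 4, n_negative = c(2, 1))
#' f <- fit_loglog_glm(d)
#' coef(f)   # alpha = log(log(2)), b = 0.5 (saturated fit)
#' @export
fit_loglog_glm <- function(data, slope_fixed = FALSE) {
  if (inherits(data, "lda_experiment")) {
    g <- lda_groups(data)
    if (length(g) != 1L) {
      stop_input_error("fit_loglog_glm() needs a single (treatment, replicate) group")
    }
    data <- g[[1L]]
  }
  data <- validate_group_counts(data)
  S <- data$cells_per_well
  n <- data$n_wells
  Y <- data$n_negative

  if (all(Y == n)) {
    stop_estimation_error(
      "no well exhibits clonogenic growth in any dilution; clonogenic activity is not estimable")
  }
  n_params <- if (slope_fixed) 1L else 2L
  if (length(unique(S)) < n_params) {
    stop_input_error(sprintf(
      "need at least %d distinct cells_per_well value(s) for %d parameter(s)",
      n_params, n_params))
  }

  lS <- log(S)
  X <- if (slope_fixed) matrix(1, length(S)) else cbind(1, lS)
  offset <- if (slope_fixed) lS else rep(0, length(S))

  boundary_all_positive <- all(Y == 0)

  beta <- start_values(lS, n, Y, slope_fixed)
  fit <- fisher_scoring(beta, X, offset, n, Y,
                        tol = 1e-8, maxit = 100L)
  converged <- fit$converged && !boundary_all_positive
  if (boundary_all_positive) {
    warning("every well is positive in every dilution; likelihood maximized at the boundary, estimates unreliable (converged = FALSE)")
  } else if (!fit$converged) {
    warning("Fisher scoring did not converge (possible quasi-separation); estimates flagged converged = FALSE")
  }

  beta <- fit$beta
  alpha <- beta[1L]
  b <- if (slope_fixed) 1 else beta[2L]
  info <- fisher_information(beta, X, offset, n, Y)
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, n_params, n_params)
  })
  dimnames(cov) <- if (slope_fixed) list("alpha", "alpha") else
    list(c("alpha", "b"), c("alpha", "b"))

  ll <- binom_loglik(beta, X, offset, n, Y)
  dev <- 2 * (saturated_loglik(n, Y) - ll)
  structure(list(
    alpha = unname(alpha), b = unname(b), cov = cov,
    log_likelihood = ll, deviance = max(dev, 0),
    aic = -2 * ll + 2 * n_params, n_params = n_params,
    slope_fixed = slope_fixed, converged = converged,
    n_iter = fit$iter, data = data
  ), class = "loglog_fit")
}

validate_group_counts <- function(data) {
  need <- c("cells_per_well", "n_wells", "n_negative")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop_input_error(
      "expected a data.frame with columns cells_per_well, n_wells, n_negative")
  }
  if (nrow(data) == 0L) stop_input_error("no observations to fit")
  if (any(data$cells_per_well <= 0)) stop_validation_error("cells_per_well must be > 0")
  if (any(data$n_negative < 0 | data$n_negative > data$n_wells)) {
    stop_validation_error("n_negative must lie in [0, n_wells]")
  }
  data
}

# mu and its link derivative; mu = exp(-exp(eta)), d mu / d eta = mu * log(mu)
.mu_eps <- 1e-12
link_mu <- function(eta) pmin(pmax(exp(-exp(eta)), .mu_eps), 1 - .mu_eps)

binom_loglik <- function(beta, X, offset, n, Y) {
  mu <- link_mu(drop(X %*% beta) + offset)
  sum(lchoose(n, Y) + Y * log(mu) + (n - Y) * log1p(-mu))
}

saturated_loglik <- function(n, Y) {
  mu <- Y / n
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  sum(lchoose(n, Y) + xlogy(Y, mu) + xlogy(n - Y, 1 - mu))
}

score_vector <- function(beta, X, offset, n, Y) {
  mu <- link_mu(drop(X %*% beta) + offset)
  dmu <- mu * log(mu)
  r <- (Y - n * mu) / (mu * (1 - mu)) * dmu
  drop(crossprod(X, r))
}

fisher_information <- function(beta, X, offset, n, Y) {
  mu <- link_mu(drop(X %*% beta) + offset)
  dmu <- mu * log(mu)
  w <- n * dmu^2 / (mu * (1 - mu))
  crossprod(X * sqrt(w))
}

fisher_scoring <- function(beta, X, offset, n, Y, tol, maxit) {
  ll <- binom_loglik(beta, X, offset, n, Y)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    U <- score_vector(beta, X, offset, n, Y)
    if (sqrt(sum(U^2)) < tol) { converged <- TRUE; break }
    I <- fisher_information(beta, X, offset, n, Y)
    step <- tryCatch(solve(I, U), error = function(e) U / max(diag(I)))
    # step-halving keeps the likelihood non-decreasing
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- binom_loglik(cand, X, offset, n, Y)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; ll_new <- ll; break }
    }
    beta <- cand
    ll <- ll_new
  }
  if (!converged) {
    converged <- sqrt(sum(score_vector(beta, X, offset, n, Y)^2)) < tol
  }
  list(beta = beta, converged = converged, iter = iter)
}

start_values <- function(lS, n, Y, slope_fixed) {
  # least squares on the empirical link, with boundary counts shrunk inward
  mu_emp <- pmin(pmax(Y / n, 1 / (2 * n)), 1 - 1 / (2 * n))
  eta <- log(-log(mu_emp))
  if (slope_fixed) {
    mean(eta - lS)
  } else {
    cf <- stats::coef(stats::lm(eta ~ lS))
    c(cf[[1L]], max(cf[[2L]], 1e-3))
  }
}

#' @export
print.loglog_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Power-law LDA fit (%s slope)\n",
              if (x$slope_fixed) "fixed b = 1" else "free"))
  se <- sqrt(diag(x$cov))
  cat(sprintf("  alpha = %.*f (SE %.*f), b = %.*f%s\n",
              digits, x$alpha, digits, se[1L], digits, x$b,
              if (x$slope_fixed) "" else sprintf(" (SE %.*f)", digits, se[2L])))
  cat(sprintf("  logLik = %.*f, deviance = %.*f, AIC = %.*f, converged = %s\n",
              digits, x$log_likelihood, digits, x$deviance, digits, x$aic,
              x$converged))
  invisible(x)
}

#' @export
coef.loglog_fit <- function(object, ...) {
  c(alpha = object$alpha, b = object$b)
}

#' @export
vcov.loglog_fit <- function(object, ...) object$cov

#' @export
logLik.loglog_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params,
            nobs = nrow(object$data), class = "logLik")
}

#' Predict the well failure fraction with a confidence band
#'
#' Computes `mu(S) = exp(-exp(alpha + b * ln S))` at the requested seeding
#' densities together with a confidence band obtained by a normal
#' approximation on the link scale,
#' `eta(S) = alpha + b * ln S` with variance
#' `Var(alpha) + 2 ln S Cov(alpha, b) + (ln S)^2 Var(b)`, transformed
#' through the inverse link. By construction the band lies in `[0, 1]` and
#' contains the point prediction. At `S` equal to the clonogenic activity
#' the predicted failure fraction is `exp(-1)`, about 37%.
#'
#' @param fit a converged [fit_loglog_glm()] result.
#' @param S positive seeding densities (cells per well), vectorized.
#' @param level confidence level of the band, default 0.95.
#' @return data.frame with columns `S`, `mu`, `lower`, `upper`.
#' @export
predict_failure_fraction <- function(fit, S, level = 0.95) {
  stopifnot(inherits(fit, "loglog_fit"))
  if (!fit$converged) stop_estimation_error("fit did not converge; refusing prediction")
  if (any(S <= 0)) stop_input_error("S must be positive")
  if (level <= 0 || level >= 1) stop_input_error("level must be in (0, 1)")
  x <- log(S)
  eta <- fit$alpha + fit$b * x
  v <- link_variance(fit, x)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(v)
  # mu is decreasing in eta, so the band flips through the inverse link
  data.frame(S = S,
             mu = exp(-exp(eta)),
             lower = exp(-exp(eta + half)),
             upper = exp(-exp(eta - half)))
}

# Var(eta(x)) at x = ln S, for free- and fixed-slope fits alike
link_variance <- function(fit, x) {
  if (fit$slope_fixed) {
    rep(fit$cov[1L, 1L], length(x))
  } else {
    fit$cov[1L, 1L] + 2 * x * fit$cov[1L, 2L] + x^2 * fit$cov[2L, 2L]
  }
}

#' Compare the power-law fit against the linear single-hit model
#'
#' The linear model (`b = 1`) is nested in the power-law model, so the
#' improvement in fit is assessed by a likelihood-ratio test on the deviance
#' difference (chi-squared with 1 degree of freedom) and by the difference
#' in AIC.
#'
#' @param fit_free free-slope [fit_loglog_glm()] result.
#' @param fit_fixed fixed-slope fit on the identical observations.
#' @return A list of class `lda_model_comparison` with `delta_deviance`
#'   (`deviance_fixed - deviance_free`, clamped at 0 against optimizer
#'   round-off), `lrt_p` and `delta_aic` (`aic_fixed - aic_free`).
#' @export
compare_models <- function(fit_free, fit_fixed) {
  stopifnot(inherits(fit_free, "loglog_fit"), inherits(fit_fixed, "loglog_fit"))
  if (fit_free$slope_fixed || !fit_fixed$slope_fixed) {
    stop_input_error("expected a free-slope fit and a fixed-slope fit, in that order")
  }
  same <- isTRUE(all.equal(
    fit_free$data[c("cells_per_well", "n_wells", "n_negative")],
    fit_fixed$data[c("cells_per_well", "n_wells", "n_negative")],
    check.attributes = FALSE))
  if (!same) stop_input_error("fits were not computed on the same observations")
  dd <- max(fit_fixed$deviance - fit_free$deviance, 0)
  structure(list(
    delta_deviance = dd,
    lrt_p = stats::pchisq(dd, df = 1, lower.tail = FALSE),
    delta_aic = fit_fixed$aic - fit_free$aic
  ), class = "lda_model_comparison")
}

#' @export
print.lda_model_comparison <- function(x, ...) {
  cat(sprintf("LRT free vs fixed slope: delta deviance = %.4f, p = %.4g, delta AIC = %.4f\n",
              x$delta_deviance, x$lrt_p, x$delta_aic))
  invisible(x)
}

#' Summarize fits as a table
#'
#' Fits the power-law model to every treatment (on pooled replicates) or
#' every (treatment, replicate) group and returns one row per fit with the
#' coefficient estimates, their standard errors and covariance, deviance and
#' AIC — the exportable fit summary.
#'
#' @param experiment an [lda_experiment()].
#' @param mode `"pooled"` (replicate wells summed before fitting) or
#'   `"per_replicate"`.
#' @param slope_fixed logical; fit the linear model instead?
#' @return data.frame with columns `treatment`, `replicate`, `alpha`, `b`,
#'   `se_alpha`, `se_b`, `cov_ab`, `deviance`, `aic`, `converged`.
#' @export
fit_table <- function(experiment, mode = c("pooled", "per_replicate"),
                      slope_fixed = FALSE) {
  mode <- match.arg(mode)
  x <- if (mode == "pooled") pool_replicates(experiment) else experiment
  rows <- lapply(lda_groups(x), function(g) {
    base <- data.frame(treatment = g$treatment[1L], replicate = g$replicate[1L])
    f <- tryCatch(suppressWarnings(fit_loglog_glm(g, slope_fixed = slope_fixed)),
                  error = function(e) e)
    if (inherits(f, "error")) {
      cbind(base, alpha = NA_real_, b = NA_real_, se_alpha = NA_real_,
            se_b = NA_real_, cov_ab = NA_real_, deviance = NA_real_,
            aic = NA_real_, converged = FALSE)
    } else {
      se <- sqrt(diag(f$cov))
      cbind(base, alpha = f$alpha, b = f$b, se_alpha = se[1L],
            se_b = if (slope_fixed) 0 else se[2L],
            cov_ab = if (slope_fixed) 0 else f$cov[1L, 2L],
            deviance = f$deviance, aic = f$aic, converged = f$converged)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
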