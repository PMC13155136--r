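# small random but always-fittable datasets for oracle comparisons
random_small_dataset <- function(seed) {
  set.seed(seed)
  repeat {
    n_dil <- sample(4:6, 1)
    dil <- 2^(0:(n_dil - 1)) * stats::runif(1, 0.5, 2)
    cfg <- simulation_config(p = stats::runif(1, 0.05, 0.3),
                             b = stats::runif(1, 0.6, 1.8),
                             dilutions = dil,
                             n_wells = sample(c(8, 12, 24), 1),
                             seed = sample.int(1e6, 1))
    d <- simulate_lda(cfg)$data
    # needs growth somewhere and some failures for a stable interior optimum
    if (any(d$n_negative < d$n_wells) && any(d$n_negative > 0) &&
        sum(d$n_negative > 0 & d$n_negative < d$n_wells) >= 2) {
      return(d)
    }
  }
}

# independent brute-force MLE: coarse grid then Nelder-Mead on a locally
# written likelihood (no shared code with the package's fitting path)
brute_force_mle <- function(d) {
  nll <- function(par) {
    mu <- exp(-exp(par[1] + par[2] * log(d$cells_per_well)))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(d$n_negative * log(mu) + (d$n_wells - d$n_negative) * log(1 - mu))
  }
  grid <- expand.grid(alpha = seq(-6, 2, by = 0.25),
                      b = seq(0.1, 4, by = 0.1))
  vals <- apply(grid, 1, nll)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$par
}

# numeric band-scan oracle: zeros of the link-scale band edges found by
# bracketing + uniroot, instead of the closed-form quadratic
band_scan_bounds <- function(fit, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  eta <- function(x) fit$alpha + fit$b * x
  sdev <- function(x) sqrt(fit$cov[1, 1] + 2 * x * fit$cov[1, 2] +
                             x^2 * fit$cov[2, 2])
  la <- -fit$alpha / fit$b
  # CI bounds are the band-edge crossings NEAREST to ln a: the last sign
  # change below it and the first above it
  find_zero <- function(f, from, to, nearest) {
    xs <- seq(from, to, length.out = 4001)
    fx <- f(xs)
    i <- which(fx[-1] * fx[-length(fx)] <= 0)
    if (!length(i)) return(NA_real_)
    i <- if (nearest == "last") i[length(i)] else i[1]
    uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root
  }
  lower <- find_zero(function(x) eta(x) + z * sdev(x), la - 20, la, "last")
  upper <- find_zero(function(x) eta(x) - z * sdev(x), la, la + 20, "first")
  c(if (is.na(lower)) 0 else exp(lower),
    if (is.na(upper)) Inf else exp(upper))
}
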