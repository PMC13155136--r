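#' Configuration for the LDA count simulator
#'
#' Bundles and validates the generative parameters of a synthetic limiting
#' dilution experiment. The generative chain is exactly the one the model
#' assumes: each well seeded with expected cell number `S` holds a
#' Poisson(`lambda`) number of active cells with `lambda = p * S^b`, so the
#' well fails with probability `mu = exp(-p * S^b)`, and the negative-well
#' count per dilution is Binomial(`n_wells`, `mu`). Wells receive the
#' expected cell number deterministically (no Poisson seeding noise),
#' matching the model assumption that wells are seeded with the same
#' expected number of cells.
#'
#' Treatments scale the activity parameter so that the generative survival
#' fraction is exact: a treatment with true survival fraction `sf` uses
#' `p_t = p * sf^b`, which gives `a_t = a_0 / sf`.
#'
#' @param p per-cell activity scale (`p = exp(alpha)`), positive.
#' @param b nonlinearity coefficient; 1 = linear, > 1 cooperative,
#'   < 1 competitive.
#' @param dilutions distinct positive seeding densities (cells per well);
#'   default the geometric ladder `2^0 ... 2^7`.
#' @param n_wells wells per dilution step (default 12, a standard plate
#'   column count).
#' @param n_replicates biological replicates per treatment.
#' @param treatments named numeric vector of true survival fractions; the
#'   first entry is the reference and should be 1.
#' @param seed integer seed; a fixed seed makes the output bit-identical.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(p = 0.1, b = 1, dilutions = 2^(0:7),
                              n_wells = 12, n_replicates = 1,
                              treatments = c(control = 1), seed = 1L) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0) {
    stop_input_error("p must be a positive scalar")
  }
  if (!is.numeric(b) || length(b) != 1L || b <= 0) {
    stop_input_error("b must be a positive scalar")
  }
  if (any(dilutions <= 0) || anyDuplicated(dilutions)) {
    stop_input_error("dilutions must be distinct and positive")
  }
  if (n_wells < 1 || n_wells != round(n_wells)) {
    stop_input_error("n_wells must be a positive integer")
  }
  if (n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop_input_error("n_replicates must be a positive integer")
  }
  if (is.null(names(treatments)) || any(!nzchar(names(treatments))) ||
      any(treatments <= 0)) {
    stop_input_error("treatments must be a named vector of positive survival fractions")
  }
  structure(list(p = p, b = b, dilutions = dilutions, n_wells = n_wells,
                 n_replicates = n_replicates, treatments = treatments,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a limiting dilution experiment
#'
#' Draws negative-well counts `Y ~ Binomial(n_wells, mu)` with
#' `mu = exp(-p_t * S^b)` for every treatment, replicate and dilution of a
#' [simulation_config()]. The random stream order is fixed and documented —
#' treatment-major, then replicate, then dilution — so a given seed yields
#' bit-identical experiments across calls and releases. The calling
#' session's RNG state is left untouched.
#'
#' @param config a [simulation_config()]; alternatively pass its fields
#'   through `...`.
#' @param ... fields forwarded to [simulation_config()] when `config` is
#'   missing.
#' @return An [lda_experiment()] (reference = first treatment) with the
#'   generating truth attached as attribute `"truth"`: the config plus the
#'   per-treatment `p`, true activities `a = p^(-1/b)` and true survival
#'   fractions.
#' @examples
#' x <- simulate_lda(p = 0.1, b = 1.5, seed = 7)
#' head(x$data)
#' attr(x, "truth")$a
#' @export
simulate_lda <- function(config = NULL, ...) {
  if (is.null(config)) config <- simulation_config(...)
  stopifnot(inherits(config, "simulation_config"))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  p_t <- config$p * config$treatments^config$b
  rows <- list()
  for (tr in names(config$treatments)) {
    mu <- exp(-p_t[[tr]] * config$dilutions^config$b)
    for (r in seq_len(config$n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, replicate = as.character(r),
        cells_per_well = config$dilutions, n_wells = config$n_wells,
        n_negative = stats::rbinom(length(mu), config$n_wells, mu))
    }
  }
  out <- lda_experiment(do.call(rbind, rows),
                        reference = names(config$treatments)[1L])
  attr(out, "truth") <- list(
    config = config, p = p_t,
    a = p_t^(-1 / config$b),
    sf = config$treatments)
  out
}

#' Explore assay design: CI width over wells and dilution count
#'
#' For each combination of wells per dilution (`n_values`) and number of
#' dilution steps used from the ladder (`d_values`, taking the first `d`
#' dilutions of `base$dilutions`), simulates `reps` experiments, fits the
#' power-law model per treatment on pooled replicates, and records the mean
#' width of the clonogenic-activity confidence interval (reference
#' treatment) and of the survival-fraction interval (first non-reference
#' treatment, when present). Unbounded intervals are excluded from the
#' means. Widths shrink as wells are added, quantifying the precision
#' return of technical replication.
#'
#' @param base a [simulation_config()] supplying all parameters not on the
#'   grid; its seed anchors the (deterministic) per-run seeds.
#' @param n_values wells-per-dilution values to scan.
#' @param d_values numbers of dilution steps to scan; at most
#'   `length(base$dilutions)`.
#' @param reps simulated experiments per grid cell.
#' @param level confidence level of the activity intervals.
#' @return data.frame with columns `n`, `d`, `mean_ci_width_activity`,
#'   `mean_ci_width_sf`.
#' @export
design_grid <- function(base, n_values, d_values, reps = 20,
                        level = 0.95) {
  stopifnot(inherits(base, "simulation_config"))
  if (any(n_values < 1) || any(d_values < 1)) {
    stop_input_error("grid values must be positive")
  }
  if (max(d_values) > length(base$dilutions)) {
    stop_input_error("d_values exceed the available dilution ladder")
  }
  ref <- names(base$treatments)[1L]
  non_ref <- setdiff(names(base$treatments), ref)
  grid <- expand.grid(n = n_values, d = d_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    n <- grid$n[i]; d <- grid$d[i]
    w_act <- w_sf <- rep(NA_real_, reps)
    for (k in seq_len(reps)) {
      cfg <- simulation_config(
        p = base$p, b = base$b, dilutions = base$dilutions[seq_len(d)],
        n_wells = n, n_replicates = base$n_replicates,
        treatments = base$treatments,
        seed = base$seed + (i - 1L) * reps + k)
      sim <- simulate_lda(cfg)
      act <- activity_table(sim, mode = "pooled", level = level)
      arow <- act[act$treatment == ref, ]
      if (is.finite(arow$ci_upper) && !is.na(arow$a)) {
        w_act[k] <- arow$ci_upper - arow$ci_lower
      }
      if (length(non_ref)) {
        sf <- tryCatch(suppressWarnings(survival_table(sim, mode = "pooled")),
                       error = function(e) NULL)
        if (!is.null(sf)) {
          srow <- sf[sf$treatment == non_ref[1L], ]
          if (nrow(srow) && is.finite(srow$ci95_upper) && !is.na(srow$sf)) {
            w_sf[k] <- srow$ci95_upper - srow$ci95_lower
          }
        }
      }
    }
    data.frame(n = n, d = d,
               mean_ci_width_activity = mean(w_act, na.rm = TRUE),
               mean_ci_width_sf = if (length(non_ref))
                 mean(w_sf, na.rm = TRUE) else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
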