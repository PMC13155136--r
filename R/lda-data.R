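#' LDA count data containers
#'
#' An `lda_experiment` holds the count table of a limiting dilution assay:
#' one row per dilution step within a (treatment, replicate) group, with the
#' expected number of cells seeded per well `S` (`cells_per_well`, a positive
#' real; fractional seeding densities are legal), the number of wells `n`
#' (`n_wells`), and the number of wells without clonogenic growth `Y`
#' (`n_negative`). The internal canonical response is the failure count
#' `n_negative`, since the binomial likelihood is written on failures; tables
#' that report positive wells are converted on input.
#'
#' @param data data.frame with columns `treatment`, `replicate`,
#'   `cells_per_well`, `n_wells` and `n_negative` (or `n_positive`, which is
#'   converted).
#' @param reference treatment label of the untreated control against which
#'   survival fractions are computed. Defaults to the first treatment
#'   appearing in `data`.
#' @return An object of class `lda_experiment`: a list with elements `data`
#'   (the validated count table) and `reference`.
#' @examples
#' d <- data.frame(treatment = "0Gy", replicate = 1,
#'                 cells_per_well = c(1, 4, 16), n_wells = 12,
#'                 n_negative = c(11, 8, 2))
#' lda_experiment(d)
#' @export
lda_experiment <- function(data, reference = NULL) {
  data <- validate_lda_counts(data)
  if (is.null(reference)) reference <- data$treatment[1L]
  reference <- as.character(reference)
  if (!reference %in% data$treatment) {
    stop_input_error(sprintf(
      "reference treatment '%s' not present among treatments: %s",
      reference, paste(unique(data$treatment), collapse = ", ")))
  }
  structure(list(data = data, reference = reference),
            class = "lda_experiment")
}

#' @export
print.lda_experiment <- function(x, ...) {
  n_grp <- nrow(unique(x$data[c("treatment", "replicate")]))
  cat(sprintf(
    "LDA experiment: %d observations, %d group(s), %d treatment(s), reference '%s'\n",
    nrow(x$data), n_grp, length(unique(x$data$treatment)), x$reference))
  invisible(x)
}

#' Validate an LDA count table
#'
#' Checks the row-level invariants: `cells_per_well > 0`, `n_wells` a
#' positive integer, and `0 <= n_negative <= n_wells`. Violations raise a
#' validation error naming the offending row. If only `n_positive` is
#' present, `n_negative = n_wells - n_positive` is derived first.
#'
#' @param data data.frame of counts (see [lda_experiment()]).
#' @return The canonicalized data.frame (character labels, `n_negative`
#'   response), invisibly usable.
#' @export
validate_lda_counts <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop_input_error("LDA count table is empty")
  }
  for (col in c("treatment", "replicate", "cells_per_well", "n_wells")) {
    if (!col %in% names(data)) {
      stop_schema_error(sprintf("required column '%s' is missing", col))
    }
  }
  if (!"n_negative" %in% names(data)) {
    if (!"n_positive" %in% names(data)) {
      stop_schema_error("need column 'n_negative' or 'n_positive'")
    }
    data$n_negative <- data$n_wells - data$n_positive
  }
  data$treatment <- as.character(data$treatment)
  data$replicate <- as.character(data$replicate)
  for (col in c("cells_per_well", "n_wells", "n_negative")) {
    if (!is.numeric(data[[col]]) || anyNA(data[[col]])) {
      stop_validation_error(sprintf("column '%s' must be numeric without NA", col))
    }
  }
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      stop_validation_error(sprintf("row %d: %s", i[1L], what))
    }
  }
  bad_row(data$cells_per_well <= 0, "cells_per_well must be > 0")
  bad_row(data$n_wells < 1 | data$n_wells != round(data$n_wells),
          "n_wells must be a positive integer")
  bad_row(data$n_negative != round(data$n_negative),
          "n_negative must be an integer")
  bad_row(data$n_negative < 0, "n_negative must be >= 0")
  bad_row(data$n_negative > data$n_wells,
          "n_negative exceeds n_wells")
  rownames(data) <- NULL
  data[c("treatment", "replicate", "cells_per_well", "n_wells", "n_negative")]
}

#' Read an LDA count table from a delimited file
#'
#' Reads a comma-separated UTF-8 table with a header row. Column names can
#' be remapped through `schema`, a named character vector from canonical
#' names (`treatment`, `replicate`, `cells_per_well`, `n_wells`,
#' `n_negative`, `n_positive`) to the names used in the file. Either a
#' negative-well or a positive-well column must resolve; positive counts are
#' stored as `n_negative = n_wells - n_positive`. Row order is preserved
#' within groups.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping canonical column names to
#'   file column names; unmapped names fall back to the canonical name.
#' @param reference reference (control) treatment label; defaults to the
#'   first treatment in the file.
#' @param sep field separator, default `","`.
#' @return An [lda_experiment()].
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write.csv(data.frame(dose = "0Gy", rep = 1, cells = c(1, 4),
#'                      wells = 12, pos = c(2, 9)),
#'           tmp, row.names = FALSE)
#' read_lda_table(tmp, schema = c(treatment = "dose", replicate = "rep",
#'                                cells_per_well = "cells", n_wells = "wells",
#'                                n_positive = "pos"))
#' @export
read_lda_table <- function(path, schema = NULL, reference = NULL, sep = ",") {
  if (!file.exists(path)) {
    stop_input_error(sprintf("input file does not exist: %s", path))
  }
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_input_error(
      sprintf("cannot parse '%s': %s", path, conditionMessage(e))))
  if (nrow(raw) == 0L) stop_input_error(sprintf("input file is empty: %s", path))

  canonical <- c("treatment", "replicate", "cells_per_well", "n_wells",
                 "n_negative", "n_positive")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), canonical)
    if (length(unknown)) {
      stop_schema_error(sprintf("unknown schema key(s): %s",
                                paste(unknown, collapse = ", ")))
    }
    map[names(schema)] <- schema
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in canonical) {
    file_col <- map[[canon]]
    if (file_col %in% names(raw)) out[[canon]] <- raw[[file_col]]
  }
  required <- c("treatment", "replicate", "cells_per_well", "n_wells")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols)) {
    stop_schema_error(sprintf(
      "column '%s' (mapped to '%s') not found in %s",
      missing_cols[1L], map[[missing_cols[1L]]], path))
  }
  if (!"n_negative" %in% names(out) && !"n_positive" %in% names(out)) {
    stop_schema_error(sprintf(
      "neither '%s' nor '%s' found in %s",
      map[["n_negative"]], map[["n_positive"]], path))
  }
  lda_experiment(out, reference = reference)
}

#' Write an LDA count table to CSV
#'
#' Writes the canonical columns (`treatment`, `replicate`, `cells_per_well`,
#' `n_wells`, `n_negative`) so that [read_lda_table()] round-trips to an
#' identical experiment.
#'
#' @param x an [lda_experiment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lda_table <- function(x, path) {
  stopifnot(inherits(x, "lda_experiment"))
  utils::write.csv(x$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# precision at which dilution steps are matched across replicates:
# dilution series are specified values, not measurements
.dilution_digits <- 6L

#' Pool biological replicates by summing well counts
#'
#' When inter-replicate variability is small relative to the intrinsic
#' binomial stochasticity of well counts, replicates of the same treatment
#' may be combined before model fitting by adding up `n_wells` and
#' `n_negative` at each dilution step (see [binomial_expectation_range()]
#' for the diagnostic). Dilution steps are matched on `cells_per_well`
#' rounded to 6 decimals; replicates whose dilution series disagree raise an
#' error listing the unmatched values rather than silently dropping rows.
#'
#' @param x an [lda_experiment()].
#' @param pooled_label replicate label assigned to the pooled groups.
#' @return An [lda_experiment()] with one group per treatment.
#' @examples
#' d <- data.frame(treatment = "ctrl", replicate = rep(1:2, each = 2),
#'                 cells_per_well = c(1, 8, 1, 8), n_wells = 12,
#'                 n_negative = c(11, 4, 10, 4))
#' pool_replicates(lda_experiment(d))$data
#' @export
pool_replicates <- function(x, pooled_label = "pooled") {
  stopifnot(inherits(x, "lda_experiment"))
  d <- x$data
  d$.S <- round(d$cells_per_well, .dilution_digits)
  pooled <- lapply(split(d, d$treatment), function(g) {
    series <- lapply(split(g$.S, g$replicate), sort)
    if (length(series) > 1L) {
      all_s <- sort(unique(unlist(series)))
      missing_any <- !vapply(all_s, function(s)
        all(vapply(series, function(ss) s %in% ss, logical(1))), logical(1))
      if (any(missing_any)) {
        stop_input_error(sprintf(
          "treatment '%s': dilution series differ across replicates; unmatched cells_per_well: %s",
          g$treatment[1L],
          paste(format(all_s[missing_any]), collapse = ", ")))
      }
    }
    agg <- stats::aggregate(cbind(n_wells, n_negative) ~ .S, data = g, FUN = sum)
    agg <- agg[order(match(agg$.S, unique(g$.S))), ]  # preserve input order
    data.frame(treatment = g$treatment[1L], replicate = pooled_label,
               cells_per_well = agg$.S, n_wells = agg$n_wells,
               n_negative = agg$n_negative)
  })
  pooled <- pooled[unique(d$treatment)]   # keep treatment order
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  lda_experiment(out, reference = x$reference)
}

# split an experiment into per-(treatment, replicate) data.frames
lda_groups <- function(x) {
  stopifnot(inherits(x, "lda_experiment"))
  key <- interaction(x$data$treatment, x$data$replicate, drop = TRUE, lex.order = TRUE)
  split(x$data, key)
}
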