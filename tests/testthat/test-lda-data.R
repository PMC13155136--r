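test_that("reading a count table preserves counts and converts positives to negatives", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(dose = "0Gy", rep = 1,
                  cells = 2^(0:7), wells = 12,
                  pos = c(1, 2, 4, 5, 8, 10, 12, 12))
  write.csv(d, tmp, row.names = FALSE)
  x <- read_lda_table(tmp, schema = c(treatment = "dose", replicate = "rep",
                                      cells_per_well = "cells",
                                      n_wells = "wells", n_positive = "pos"))
  expect_s3_class(x, "lda_experiment")
  expect_equal(nrow(x$data), 8)
  expect_equal(length(lda_groups(x)), 1)
  expect_equal(x$data$n_negative, 12 - d$pos)
  expect_equal(x$data$cells_per_well, d$cells)
})

test_that("read -> write -> read round-trips to an identical experiment", {
  sim <- simulate_lda(p = 0.15, b = 1.3, n_replicates = 2,
                      treatments = c(ctrl = 1, irr = 0.4), seed = 11)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_lda_table(sim, f1)
  back <- read_lda_table(f1, reference = "ctrl")
  write_lda_table(back, f2)
  expect_equal(back$data, sim$data)
  expect_equal(back$reference, sim$reference)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("schema and file errors are specific", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(treatment = "a", replicate = 1, cells_per_well = 1),
            tmp, row.names = FALSE)
  expect_error(read_lda_table(tmp), class = "lda_schema_error",
               regexp = "n_wells")
  expect_error(read_lda_table("no/such/file.csv"), class = "lda_input_error")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("treatment,replicate,cells_per_well,n_wells,n_negative", empty)
  expect_error(read_lda_table(empty), class = "lda_input_error",
               regexp = "empty")
})

test_that("validation rejects every constructed invariant violation, naming the row", {
  base <- data.frame(treatment = "t", replicate = "1",
                     cells_per_well = c(1, 2, 4), n_wells = 12,
                     n_negative = c(5, 3, 1))
  expect_silent(validate_lda_counts(base))
  corruptions <- list(
    function(d) { d$n_negative[2] <- 13; d },         # Y > n
    function(d) { d$n_negative[1] <- -1; d },          # Y < 0
    function(d) { d$cells_per_well[3] <- 0; d },       # S = 0
    function(d) { d$cells_per_well[1] <- -2; d },      # S < 0
    function(d) { d$n_wells[2] <- 0; d },              # n = 0
    function(d) { d$n_wells[3] <- 7.5; d },            # fractional n
    function(d) { d$n_negative[2] <- 2.5; d })         # fractional Y
  set.seed(42)
  for (k in seq_len(25)) {
    corrupt <- sample(corruptions, 1)[[1]]
    expect_error(validate_lda_counts(corrupt(base)),
                 class = "lda_validation_error", regexp = "row")
  }
})

test_that("pooling sums wells per dilution and conserves totals", {
  d <- data.frame(treatment = "t", replicate = rep(c("1", "2"), each = 1),
                  cells_per_well = 8, n_wells = 12, n_negative = 4)
  pooled <- pool_replicates(lda_experiment(d))
  expect_equal(pooled$data$n_wells, 24)
  expect_equal(pooled$data$n_negative, 8)
  expect_equal(pooled$data$replicate, "pooled")

  # all-negative boundary, three replicates
  d2 <- data.frame(treatment = "t", replicate = as.character(1:3),
                   cells_per_well = 1, n_wells = 12, n_negative = 12)
  p2 <- pool_replicates(lda_experiment(d2))
  expect_equal(p2$data$n_wells, 36)
  expect_equal(p2$data$n_negative, 36)

  sim <- simulate_lda(p = 0.1, b = 1.4, n_replicates = 3,
                      treatments = c(a = 1, b = 0.5), seed = 5)
  pooled <- pool_replicates(sim)
  expect_equal(sum(pooled$data$n_wells), sum(sim$data$n_wells))
  expect_equal(sum(pooled$data$n_negative), sum(sim$data$n_negative))
})

test_that("mismatched dilution series across replicates are an error listing the S values", {
  d <- data.frame(treatment = "t", replicate = c("1", "1", "2", "2"),
                  cells_per_well = c(1, 2, 4, 8), n_wells = 12,
                  n_negative = 3)
  err <- expect_error(pool_replicates(lda_experiment(d)),
                      class = "lda_input_error")
  for (s in c("1", "2", "4", "8")) {
    expect_match(conditionMessage(err), s)
  }
})

test_that("reference treatment must exist", {
  d <- data.frame(treatment = "t", replicate = "1",
                  cells_per_well = 1, n_wells = 12, n_negative = 3)
  expect_error(lda_experiment(d, reference = "ghost"),
               class = "lda_input_error", regexp = "ghost")
})
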