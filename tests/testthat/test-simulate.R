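noise_free <- function(seed = 1, ...) {
  cfg <- mdia_preset("scBenchmark", seed = seed, n_proteins = 10L,
                     noise_cv = 0, interference_fraction = 0,
                     detection_lambda = 0, ...)
  simulate_report(cfg)
}

test_that("noise-free simulation gives exact designed ion ratios", {
  sim <- noise_free()
  fit <- run_refquant(sim$report, sim$design)
  # targets 250 pg vs 10 ng reference: every ion ratio is exactly 1/40
  expect_equal(fit$ratio, rep(1 / 40, nrow(fit)), tolerance = 1e-12)
  ratios <- summed_channel_ratio(sim$report, 4L, 0L)
  expect_equal(ratios$ratio, rep(1 / 40, nrow(ratios)), tolerance = 1e-12)
})

test_that("empty channels yield no rows without interference", {
  cfg <- mdia_preset("scDecoy", seed = 2, n_proteins = 10L,
                     interference_fraction = 0, noise_cv = 0,
                     detection_lambda = 0)
  sim <- simulate_report(cfg)
  empty_chans <- sim$design[sim$design$role == "empty", ]
  hits <- dplyr::semi_join(sim$report, empty_chans, by = c("run", "channel"))
  expect_equal(nrow(hits), 0L)
})

test_that("identical config and seed reproduce byte-identical output", {
  cfg <- mdia_preset("scBenchmark", seed = 9, n_proteins = 12L)
  s1 <- simulate_report(cfg)
  s2 <- simulate_report(cfg)
  expect_identical(s1$report, s2$report)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim(s1, d1); write_sim(s2, d2)
  expect_identical(readLines(file.path(d1, "report.tsv")),
                   readLines(file.path(d2, "report.tsv")))
  # a different seed changes the data
  expect_false(identical(
    s1$report, simulate_report(mdia_preset("scBenchmark", seed = 10,
                                           n_proteins = 12L))$report))
})

test_that("generated reports are parseable by the reader without modification", {
  sim <- simulate_report(mdia_preset("scQuant", seed = 4, n_proteins = 12L))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  back <- read_report(file.path(dir, "report.tsv"))
  expect_equal(nrow(back), nrow(sim$report))
  expect_equal(back$fragment_quant, sim$report$fragment_quant)
  # channel resolution from label tokens alone agrees with the channel column
  expect_equal(parse_channel(back$precursor_id), back$channel)
  design <- read_design(file.path(dir, "design.tsv"))
  expect_s3_class(design, "mdia_design")
})

test_that("empirical per-ion CV matches the configured noise level", {
  cfg <- simulation_config(
    design = tibble::tibble(run = sprintf("run%02d", 1:12),
                            channel = 0L, role = "reference",
                            amount_pg = 10000),
    n_proteins = 60L, precursors_per_protein = c(3L, 5L),
    noise_cv = 0.1, interference_fraction = 0, detection_lambda = 0,
    seed = 31)
  sim <- simulate_report(cfg)
  ions <- sim$truth$ions |>
    dplyr::group_by(.data$precursor_idx, .data$ion_index) |>
    dplyr::summarise(cv = sd(.data$intensity) / mean(.data$intensity),
                     n = dplyr::n(), .groups = "drop")
  expect_gte(sum(ions$n), 10000)
  expect_equal(median(ions$cv), 0.1, tolerance = 0.1)
})

test_that("missingness decreases with true ion intensity", {
  sim <- simulate_report(mdia_preset("scBenchmark", seed = 17,
                                     n_proteins = 150L))
  ions <- sim$truth$ions |>
    dplyr::filter(.data$true_signal > 0) |>
    dplyr::mutate(bin = dplyr::ntile(.data$true_signal, 5)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(detected = mean(!is.na(.data$intensity)),
                     .groups = "drop")
  expect_true(all(diff(ions$detected) >= 0))
  expect_lt(ions$detected[1], ions$detected[5])
})

test_that("preset catalogue states the benchmark worlds", {
  expect_error(mdia_preset("nope"), "Available")
  sb <- mdia_preset("scBenchmark")
  amounts <- unique(sb$design[c("channel", "role", "amount_pg")])
  expect_equal(amounts$amount_pg[amounts$role == "reference"], 10000)
  expect_equal(amounts$amount_pg[amounts$role == "target"], c(250, 250))

  sq <- mdia_preset("scQuant")
  tgt <- sort(unique(sq$design$amount_pg[sq$design$role == "target"]))
  expect_equal(min(tgt), 62.5)
  expect_equal(max(tgt), 2000)

  sd_ <- mdia_preset("scDecoy")
  expect_equal(sum(sd_$design$role == "empty"), 4L)
  expect_true(all(sd_$design$amount_pg[sd_$design$role == "empty"] == 0))

  fp <- mdia_preset("fiveplex_1_2_4_2_1")
  fp_amt <- fp$design |>
    dplyr::filter(.data$run == "run01") |>
    dplyr::arrange(.data$channel)
  expect_equal(fp_amt$amount_pg / fp_amt$amount_pg[1], c(1, 2, 4, 2, 1))

  # invalid configurations fail before generation
  expect_error(simulation_config(
    design = tibble::tibble(run = "r1", channel = 0L, role = "target",
                            amount_pg = 0)), "amount 0")
})
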