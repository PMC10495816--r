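test_that("ion ratios pair by index and append one MS1 ratio", {
  r <- extract_ion_ratios(c(10, 20, NA, 5), c(1000, 1000, 500, NA), 30, 2000)
  expect_equal(r, c(0.01, 0.02, 0.015))
  expect_equal(extract_ion_ratios(c(5, 5), c(5, 5), 7, 7), c(1, 1, 1))
  expect_equal(extract_ion_ratios(c(NA, NA), c(1, 2)), numeric(0))
  # zeros never form ratios
  expect_equal(extract_ion_ratios(c(0, 4), c(2, 2)), 2)
  expect_error(extract_ion_ratios(c(1, 2), c(1, 2, 3)), "aligned")
})

test_that("estimate_ratio retains the lowest 40% and averages", {
  est <- estimate_ratio(c(0.01, 0.02, 0.03, 0.04, 0.05, 1.0, 1.1))
  expect_equal(est$n_retained, 2L)           # floor(0.4 * 7)
  expect_equal(est$R, 0.015)

  est14 <- estimate_ratio((1:14) * 0.001)
  expect_equal(est14$n_retained, 5L)         # floor(0.4 * 14)
  expect_equal(est14$R, 0.003)

  # constant distribution is a fixed point for any fraction
  for (f in c(0.1, 0.4, 1)) {
    expect_equal(estimate_ratio(rep(2.5, 9), quantile_fraction = f)$R, 2.5)
  }
  expect_equal(estimate_ratio(5)$n_retained, 1L)  # max(1, floor(0.4))
  expect_error(estimate_ratio(numeric(0)), "empty")
  expect_error(estimate_ratio(c(1, -1)), "positive")
})

test_that("estimate_ratio matches the brute-force oracle on all sizes up to 20", {
  set.seed(101)
  for (n in 1:20) {
    for (rep_i in 1:5) {
      ratios <- rlnorm(n, -3, 1)
      est <- estimate_ratio(ratios)
      expect_identical(est$R, oracle_quantile_mean(ratios))
      expect_identical(est$n_retained, max(1L, as.integer(floor(0.4 * n))))
      # R lies within the retained range
      expect_gte(est$R, min(est$retained))
      expect_lte(est$R, max(est$retained))
    }
  }
})

test_that("geometric mean variant averages in log space", {
  est <- estimate_ratio(c(1, 4, 100, 200), quantile_fraction = 0.5,
                        mean_type = "geometric")
  expect_equal(est$R, 2)                     # sqrt(1 * 4)
})

test_that("scaling factor follows the MS1 -> translated -> normalised -> summed hierarchy", {
  s <- reference_scaling_factor(c(100, 200, 300), c(1, 2, 3), c(1, 2, 3),
                                list(c(1), c(1), c(1)))
  expect_equal(s$value, 200)
  expect_equal(s$source, "ms1_area")

  s2 <- reference_scaling_factor(c(150, NA, NA), c(80, 120, 100),
                                 c(1, 2, 3), list(c(1), c(1), c(1)))
  expect_equal(s2$value, 100)
  expect_equal(s2$source, "precursor_translated")

  s3 <- reference_scaling_factor(c(NA, NA), c(NA, NA), c(7, 9),
                                 list(c(1), c(1)))
  expect_equal(s3$value, 8)
  expect_equal(s3$source, "precursor_normalised")

  s4 <- reference_scaling_factor(NA_real_, NA_real_, NA_real_,
                                 list(c(10, 20, 30)))
  expect_equal(s4$value, 60)
  expect_equal(s4$source, "summed_ions")

  expect_error(reference_scaling_factor(numeric(0), numeric(0), numeric(0),
                                        list()), "no reference")
})

test_that("refquant_intensity is the ratio-scale product", {
  expect_equal(refquant_intensity(0.015, 200), 3.0)
  expect_equal(refquant_intensity(1, 123.4), 123.4)
  est <- estimate_ratio(c(0.01, 0.02, 0.03, 0.04, 0.05, 1.0, 1.1))
  expect_equal(refquant_intensity(est, list(value = 200, source = "ms1_area")),
               3.0)
})

test_that("run_refquant composes extraction, estimation and scaling", {
  rep <- toy_report(list(
    list(channel = 0L, fragment_quant = c(1000, 1000, 500, NA),
         ms1_area = 2000),
    list(channel = 4L, fragment_quant = c(10, 20, NA, 5), ms1_area = 30)
  ))
  fit <- run_refquant(rep, toy_design())
  expect_equal(nrow(fit), 1L)
  expect_equal(fit$n_total, 3L)
  expect_equal(fit$n_retained, 1L)
  expect_equal(fit$ratio, 0.01)
  # one run only: every precursor-level source has < 2 values, so the scale
  # falls back to summed available ions (fragments + MS1)
  expect_equal(fit$scale_source, "summed_ions")
  expect_equal(fit$scale, 1000 + 1000 + 500 + 2000)
  expect_equal(fit$intensity, 0.01 * 4500)
})

test_that("the scaling factor is the cross-run reference median, shared by runs", {
  rep <- toy_report(list(
    list(run = "run01", channel = 0L, fragment_quant = c(1000, 800),
         ms1_area = 1000),
    list(run = "run01", channel = 4L, fragment_quant = c(10, 8)),
    list(run = "run02", channel = 0L, fragment_quant = c(3000, 2400),
         ms1_area = 3000),
    list(run = "run02", channel = 4L, fragment_quant = c(30, 24))
  ))
  fit <- run_refquant(rep, toy_design(runs = c("run01", "run02")))
  expect_equal(nrow(fit), 2L)
  expect_equal(unique(fit$scale), 2000)           # median(1000, 3000)
  expect_equal(unique(fit$scale_source), "ms1_area")
  expect_equal(fit$ratio, c(0.01, 0.01))
})

test_that("missing targets stay missing and runs need a reference", {
  rep <- toy_report(list(
    list(channel = 0L, fragment_quant = c(1000, 800), ms1_area = 1000),
    list(channel = 4L, fragment_quant = c(NA_real_, NA_real_))
  ))
  fit <- run_refquant(rep, toy_design())
  expect_equal(nrow(fit), 0L)                     # no usable ratio, no entry

  bad_design <- toy_design(roles = c("target", "target", "target"))
  expect_error(run_refquant(rep, bad_design), "no reference channel")
})

test_that("scale equivariance and reference-shift invariance hold", {
  sim <- simulate_report(mdia_preset("scBenchmark", seed = 21,
                                     n_proteins = 20L))
  fit <- run_refquant(sim$report, sim$design)

  scale_chan <- function(report, chan, c_fac, ref = FALSE) {
    r <- report
    pick <- r$channel == chan
    r$fragment_quant[pick] <- lapply(r$fragment_quant[pick], `*`, c_fac)
    r$ms1_area[pick] <- r$ms1_area[pick] * c_fac
    r$precursor_translated[pick] <- r$precursor_translated[pick] * c_fac
    r$precursor_normalised[pick] <- r$precursor_normalised[pick] * c_fac
    r
  }
  # multiplying all target-channel quantities by c multiplies R and the
  # intensity by exactly c
  fit_x3 <- run_refquant(scale_chan(sim$report, 4L, 3), sim$design)
  both <- dplyr::inner_join(
    dplyr::filter(tidy(fit), .data$channel == 4L),
    dplyr::filter(tidy(fit_x3), .data$channel == 4L),
    by = c("precursor_key", "run"), suffix = c("", "_x3"))
  expect_equal(both$ratio_x3, 3 * both$ratio)
  expect_equal(both$intensity_x3, 3 * both$intensity)

  # multiplying the reference everywhere by c leaves intensities unchanged
  fit_ref <- run_refquant(scale_chan(sim$report, 0L, 5), sim$design)
  both_ref <- dplyr::inner_join(tidy(fit), tidy(fit_ref),
                                by = c("precursor_key", "run", "channel"),
                                suffix = c("", "_ref"))
  expect_equal(both_ref$ratio_ref, both_ref$ratio / 5, tolerance = 1e-12)
  expect_equal(both_ref$intensity_ref, both_ref$intensity, tolerance = 1e-9)
})

test_that("run_refquant is deterministic on identical input", {
  sim <- simulate_report(mdia_preset("scBenchmark", seed = 5,
                                     n_proteins = 10L))
  expect_identical(tidy(run_refquant(sim$report, sim$design)),
                   tidy(run_refquant(sim$report, sim$design)))
})

test_that("summed channel ratios recover a designed mix on shared ions", {
  rep <- toy_report(list(
    list(channel = 0L, fragment_quant = c(170, 340, NA), ms1_area = 1700),
    list(channel = 8L, fragment_quant = c(10, 20, 5), ms1_area = 100)
  ))
  r <- summed_channel_ratio(rep, numerator = 0L, denominator = 8L)
  expect_equal(nrow(r), 1L)
  expect_equal(r$ratio, (170 + 340 + 1700) / (10 + 20 + 100))
})
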