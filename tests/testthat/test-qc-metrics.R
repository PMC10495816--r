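test_that("count-based FDR is max(empty) over min(filled)", {
  expect_equal(count_based_fdr(c(950, 1000, 900, 980),
                               c(100000, 110000, 105000, 102000)), 0.01)
  expect_equal(count_based_fdr(c(0, 0, 0, 0), c(10, 20)), 0)
  expect_true(is.na(count_based_fdr(c(5), c(0, 10))))
  expect_error(count_based_fdr(numeric(0), 1), "at least one")
})

test_that("the FDR curve counts identifications below each cutoff", {
  rep <- toy_report(c(
    lapply(c(0.001, 0.002), function(q) {
      list(channel = 4L, channel_q_value = q, fragment_quant = c(1),
           stripped_sequence = paste0("PEPA", round(q * 1e4), "K"))
    }),
    lapply(c(0.05, 0.30), function(q) {
      list(channel = 8L, channel_q_value = q, fragment_quant = c(1),
           stripped_sequence = paste0("PEPB", round(q * 1e2), "K"))
    })
  ))
  design <- toy_design(roles = c("reference", "target", "empty"))
  curve <- channel_fdr_curve(rep, design, thresholds = c(0.01, 0.10, 1.0))
  expect_equal(curve$fdr, c(0 / 2, 1 / 2, 2 / 2))
  expect_equal(glance(curve)$fdr_at_0.01, 0)
})

test_that("completeness splits ranked rows into quartiles with remainder first", {
  m <- matrix(1000, nrow = 8, ncol = 2,
              dimnames = list(paste0("r", 1:8), c("s1", "s2")))
  m[1:4, ] <- m[1:4, ] * 100          # top half most abundant
  m[5:8, 2] <- NA                     # bottom half half-missing
  comp <- completeness_by_quartile(long_quant(m))
  expect_equal(comp$completeness, c(1, 1, 0.5, 0.5))
  expect_equal(comp$n_rows, rep(2L, 4))

  m5 <- matrix(rev(seq_len(5)), nrow = 5, ncol = 1,
               dimnames = list(paste0("r", 1:5), "s1"))
  expect_equal(completeness_by_quartile(long_quant(m5))$n_rows,
               c(2L, 1L, 1L, 1L))

  full <- matrix(1, 4, 3, dimnames = list(paste0("r", 1:4), paste0("s", 1:3)))
  expect_equal(completeness_by_quartile(long_quant(full))$completeness,
               rep(1, 4))
  expect_error(completeness_by_quartile(long_quant(matrix(NA_real_, 1, 1,
    dimnames = list("r", "s")))), "empty")
})

test_that("quartile completeness decreases when missingness rises as abundance falls", {
  sim <- simulate_report(mdia_preset("scBenchmark", seed = 13,
                                     n_proteins = 120L))
  fit <- run_refquant(sim$report, sim$design)
  comp <- completeness_by_quartile(tidy(fit), row = "precursor_key")
  expect_true(all(diff(comp$completeness) <= 0.02))  # weakly decreasing
  expect_gt(comp$completeness[1], comp$completeness[4])
})

test_that("expected completeness is the Poisson detection law", {
  expect_equal(expected_completeness(0), 0)
  expect_equal(expected_completeness(log(2)), 0.5)
  expect_equal(expected_completeness(50), 1, tolerance = 1e-12)
  expect_error(expected_completeness(-1), "non-negative")
})

test_that("cell filtering drops empties then trims by the 1.5-SD window", {
  cells <- tibble::tibble(cell_id = paste0("c", 1:5),
                          n_proteins = c(0, 5, 2300, 2400, 2500))
  out <- filter_cells(cells, total_proteins = 5000)
  expect_equal(out$reason, c("empty", "empty", "ok", "ok", "ok"))

  # identical counts: SD 0, degenerate window keeps everyone
  same <- tibble::tibble(cell_id = paste0("c", 1:4), n_proteins = rep(100, 4))
  expect_true(all(filter_cells(same, total_proteins = 1000)$retained))

  # one extreme outlier beyond 1.5 SD of the survivors
  counts <- c(100, 102, 98, 104, 96, 500)
  out2 <- filter_cells(tibble::tibble(cell_id = paste0("c", 1:6),
                                      n_proteins = counts),
                       total_proteins = 5000)
  expect_equal(out2$reason[6], "outside_sd_window")
  expect_true(all(out2$retained[1:5]))
  expect_error(filter_cells(same[1:2, ], total_proteins = 10), "three")
})

test_that("summed signal totals non-missing intensities per sample", {
  q <- tibble::tibble(sample_name = c("a", "a", "a", "b", "b"),
                      intensity = c(1, 2, 3, NA, 4))
  s <- summed_signal(q)
  expect_equal(s$summed_signal[s$sample_name == "a"], 6)
  expect_equal(s$summed_signal[s$sample_name == "b"], 4)
  empty <- tibble::tibble(sample_name = "c", intensity = NA_real_)
  expect_warning(s2 <- summed_signal(empty), "no observed")
  expect_equal(s2$summed_signal, 0)
})

test_that("pairwise Pearson works on pairwise-complete log intensities", {
  m <- matrix(c(2, 4, 8,
                4, 8, 16,
                8, 4, 2), ncol = 3,
              dimnames = list(paste0("r", 1:3), c("a", "b", "c")))
  pp <- pairwise_pearson(long_quant(m))
  expect_equal(diag(pp$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(pp$r["a", "b"], 1)            # scaled copy, affine in log
  expect_equal(pp$r["a", "c"], -1)           # anti-monotone
  # fewer than 3 shared rows -> NA
  m2 <- m; m2[1, 2] <- NA
  pp2 <- pairwise_pearson(long_quant(m2))
  expect_true(is.na(pp2$r["a", "b"]))
  expect_error(pairwise_pearson(long_quant(m[, 1, drop = FALSE])),
               "two samples")
})
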