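# Fixture builders and independent oracles shared across test files.

# Minimal in-memory report: one row per (run, channel) entry in `rows`,
# all for a single precursor unless `seq`/`charge` vectors are given.
toy_report <- function(rows) {
  defaults <- tibble::tibble(
    run = "run01", protein_group = "P1", genes = "G1",
    stripped_sequence = "PEPTIDEK", charge = 2L, channel = 0L,
    q_value = 0, global_pg_q_value = 0, pg_q_value = 0,
    lib_pg_q_value = 0, channel_q_value = 0, translated_q_value = 0,
    ms1_area = NA_real_, precursor_translated = NA_real_,
    precursor_normalised = NA_real_
  )
  out <- dplyr::bind_rows(lapply(rows, function(r) {
    row <- defaults
    for (nm in setdiff(names(r), "fragment_quant")) row[[nm]] <- r[[nm]]
    row$fragment_quant <- list(r$fragment_quant)
    row
  }))
  out$modified_sequence <- paste0(
    sprintf("(Dimethyl-n-%d)", out$channel), out$stripped_sequence)
  out$precursor_id <- paste0(out$modified_sequence, out$charge)
  class(out) <- c("mdia_report", class(out))
  out
}

toy_design <- function(runs = "run01", channels = c(0L, 4L, 8L),
                       roles = c("reference", "target", "target")) {
  d <- tidyr::expand_grid(run = runs, i = seq_along(channels))
  d$channel <- channels[d$i]
  d$role <- roles[d$i]
  d$i <- NULL
  d$sample_name <- paste0(d$run, "_d", d$channel)
  validate_design(d)
}

# Independent lowest-quantile-mean oracle: explicit selection by repeated
# minimum extraction, no sort() call shared with the implementation.
oracle_quantile_mean <- function(ratios, fraction = 0.4) {
  n <- length(ratios)
  k <- max(1, floor(fraction * n))
  pool <- ratios
  picked <- numeric(0)
  for (i in seq_len(k)) {
    j <- which.min(pool)
    picked <- c(picked, pool[j])
    pool <- pool[-j]
  }
  mean(picked)
}

# Long-format quant tibble from a named matrix (rows x samples).
long_quant <- function(m, row = "protein_group") {
  out <- tibble::as_tibble(m, rownames = row) |>
    tidyr::pivot_longer(-dplyr::all_of(row), names_to = "sample_name",
                        values_to = "intensity") |>
    dplyr::filter(!is.na(.data$intensity))
  out
}
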