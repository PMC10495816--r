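# Experiment-level QC: count-based empty-channel FDR, completeness by
# abundance quartile, Poisson-expected completeness, cell-level filters,
# summed signal, pairwise correlations.

#' Count-based FDR from empty and filled channel counts
#'
#' The empirical false-discovery proxy for channel-level identifications:
#' maximum identification count across deliberately empty target channels
#' divided by the minimum count across filled target channels.
#'
#' @param empty_counts,filled_counts Non-negative integer vectors of
#'   identification counts per (run, channel).
#' @return `max(empty_counts) / min(filled_counts)`; `NA` if the minimum
#'   filled count is zero (undefined).
#' @examples
#' count_based_fdr(c(950, 1000, 900, 980), c(100000, 110000, 105000, 102000))
#' # 0.01
#' @export
count_based_fdr <- function(empty_counts, filled_counts) {
  if (length(empty_counts) < 1L || length(filled_counts) < 1L) {
    abort("Need at least one empty and one filled channel count.")
  }
  lo <- min(filled_counts)
  if (lo == 0) return(NA_real_)
  max(empty_counts) / lo
}

#' Count-based FDR curve over a Channel.Q.Value sweep
#'
#' At each threshold, counts identifications (distinct precursors, or
#' distinct protein groups) per (run, channel) with `channel_q_value` below
#' the cutoff, then applies [count_based_fdr()] using the design's `empty`
#' versus `target` roles.
#'
#' @param report An `mdia_report` tibble.
#' @param design An `mdia_design` with at least one empty and one target
#'   channel.
#' @param thresholds Ascending Channel.Q.Value cutoffs. The default sweep
#'   covers the working cutoffs discussed for dimethyl mDIA data (0.01, 0.15)
#'   and the 1% calibration points (0.45 precursor-level, 0.17 protein-level).
#' @param level `"precursor"` or `"protein"`.
#' @return Tibble of class `channel_fdr_curve`: `threshold`, `max_empty`,
#'   `min_filled`, `fdr`, `level`.
#' @export
channel_fdr_curve <- function(report, design,
                              thresholds = c(0.01, 0.05, 0.10, 0.15, 0.20,
                                             0.30, 0.45, 1.0),
                              level = c("precursor", "protein")) {
  level <- match.arg(level)
  design <- validate_design(design)
  if (!any(design$role == "empty") || !any(design$role == "target")) {
    abort("Design must declare at least one empty and one target channel.")
  }
  key <- if (level == "precursor") "precursor_id" else "protein_group"
  joined <- as_tibble(report) |>
    dplyr::inner_join(as_tibble(design), by = c("run", "channel")) |>
    dplyr::filter(.data$role %in% c("empty", "target"))
  chans <- design |> dplyr::filter(.data$role %in% c("empty", "target"))
  out <- purrr::map_dfr(sort(thresholds), function(t) {
    counts <- joined |>
      dplyr::filter(.data$channel_q_value < t) |>
      dplyr::group_by(.data$run, .data$channel, .data$role) |>
      dplyr::summarise(n = dplyr::n_distinct(.data[[key]]), .groups = "drop")
    # channels with zero surviving identifications still count as 0
    counts <- chans |>
      dplyr::left_join(counts, by = c("run", "channel", "role")) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
    e <- counts$n[counts$role == "empty"]
    f <- counts$n[counts$role == "target"]
    tibble(threshold = t, max_empty = max(e), min_filled = min(f),
           fdr = count_based_fdr(e, f))
  })
  out$level <- level
  structure(out, class = c("channel_fdr_curve", class(tibble())))
}

#' Data completeness by abundance quartile
#'
#' Ranks rows by decreasing mean intensity, splits them into four quartiles
#' (remainder rows assigned to the earlier quartiles), and reports the
#' fraction of non-missing (row, sample) entries per quartile.
#'
#' @param quant Long tibble with row-key, sample and value columns; absent or
#'   `NA` entries count as missing against the full row x sample grid.
#' @param row,sample,value Column names.
#' @return Tibble: `quartile` (1 = most abundant), `n_rows`, `completeness`.
#' @export
completeness_by_quartile <- function(quant, row = "protein_group",
                                     sample = "sample_name",
                                     value = "intensity") {
  q <- as_tibble(quant) |>
    dplyr::select(row_key = dplyr::all_of(row),
                  sample_name = dplyr::all_of(sample),
                  intensity = dplyr::all_of(value)) |>
    dplyr::filter(!is.na(.data$intensity))
  if (nrow(q) == 0L) abort("`quant` is empty.")
  n_samples <- dplyr::n_distinct(q$sample_name)
  ranked <- q |>
    dplyr::group_by(.data$row_key) |>
    dplyr::summarise(mean_int = mean(.data$intensity),
                     n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_int))
  n <- nrow(ranked)
  base <- n %/% 4L
  extra <- n %% 4L
  sizes <- rep(base, 4L) + (seq_len(4L) <= extra)
  ranked$quartile <- rep(1:4, times = sizes)
  ranked |>
    dplyr::group_by(.data$quartile) |>
    dplyr::summarise(n_rows = dplyr::n(),
                     completeness = sum(.data$n_obs) /
                       (dplyr::n() * n_samples),
                     .groups = "drop")
}

#' Expected completeness under pure shot noise
#'
#' If missing values arise purely from Poisson counting noise, the expected
#' fraction of detections at mean abundance `x` is `1 - exp(-x)`.
#'
#' @param x Non-negative mean abundance (vectorized).
#' @return Expected completeness fraction in `[0, 1)`.
#' @export
expected_completeness <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("Mean abundance must be non-negative.")
  1 - exp(-x)
}

#' Two-stage cell filtering
#'
#' Stage 1 drops near-empty cells: those whose identified-protein count is at
#' or below 1% of the total distinct proteins identified in the experiment.
#' Stage 2 keeps cells whose protein count lies within 1.5 standard
#' deviations of the median, both statistics computed on the stage-1
#' survivors; bounds are inclusive.
#'
#' @param cells Tibble with columns `cell_id` and `n_proteins` (and any
#'   others, carried through).
#' @param total_proteins Total distinct proteins identified across the
#'   experiment (the denominator of the 1% rule).
#' @param empty_fraction Stage-1 fraction, default 0.01.
#' @param sd_window Stage-2 window half-width in standard deviations,
#'   default 1.5.
#' @return `cells` with added columns `retained` (logical) and `reason`
#'   (`"ok"`, `"empty"`, or `"outside_sd_window"`); attribute `bounds` holds
#'   the stage-2 window.
#' @export
filter_cells <- function(cells, total_proteins, empty_fraction = 0.01,
                         sd_window = 1.5) {
  cells <- as_tibble(cells)
  if (nrow(cells) < 3L) abort("Cell filtering needs at least three cells.")
  stopifnot(all(c("cell_id", "n_proteins") %in% names(cells)))
  cutoff <- empty_fraction * total_proteins
  stage1 <- cells$n_proteins > cutoff
  surv <- cells$n_proteins[stage1]
  if (!any(stage1)) {
    warn("All cells fell below the empty-cell cutoff; none retained.")
    cells$retained <- FALSE
    cells$reason <- "empty"
    return(cells)
  }
  ctr <- median(surv)
  s <- sd(surv)
  if (is.na(s)) s <- 0            # single survivor
  lo <- ctr - sd_window * s
  hi <- ctr + sd_window * s
  stage2 <- cells$n_proteins >= lo & cells$n_proteins <= hi
  cells$retained <- stage1 & stage2
  cells$reason <- dplyr::case_when(!stage1 ~ "empty",
                                   !stage2 ~ "outside_sd_window",
                                   TRUE ~ "ok")
  structure(cells, bounds = c(lower = lo, upper = hi),
            empty_cutoff = cutoff)
}

#' Summed MS signal per cell
#'
#' @param quant Long tibble with sample and value columns.
#' @param sample,value Column names.
#' @return Tibble `sample_name`, `summed_signal` (sum of non-missing
#'   intensities; 0 with a warning if a sample has none).
#' @export
summed_signal <- function(quant, sample = "sample_name", value = "intensity") {
  q <- as_tibble(quant)
  out <- q |>
    dplyr::group_by(sample_name = .data[[sample]]) |>
    dplyr::summarise(summed_signal = sum(.data[[value]], na.rm = TRUE),
                     n_obs = sum(!is.na(.data[[value]])), .groups = "drop")
  if (any(out$n_obs == 0)) {
    warn(sprintf("Sample(s) with no observed intensities (summed signal 0): %s",
                 paste(out$sample_name[out$n_obs == 0], collapse = ", ")))
  }
  dplyr::select(out, -"n_obs")
}

#' Pairwise Pearson correlation between samples
#'
#' Pearson r on pairwise-complete log2 intensities. Pairs sharing fewer than
#' three rows are reported as `NA`.
#'
#' @param quant Long tibble with row-key, sample and value columns (linear
#'   intensities).
#' @param row,sample,value Column names.
#' @param log2_transform Correlate log2 intensities (default `TRUE`).
#' @param min_shared Minimum shared rows per pair, default 3.
#' @return List of class `pairwise_pearson`: `r` (correlation matrix,
#'   diagonal 1) and `median_off_diagonal`.
#' @export
pairwise_pearson <- function(quant, row = "protein_group",
                             sample = "sample_name", value = "intensity",
                             log2_transform = TRUE, min_shared = 3L) {
  wide <- quant_wide(as_tibble(quant), row = row, sample = sample, value = value)
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(m) < 2L) abort("Need at least two samples for correlation.")
  if (log2_transform) m <- log2(m)
  n <- ncol(m)
  r <- diag(1, n)
  dimnames(r) <- list(colnames(m), colnames(m))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      r[i, j] <- r[j, i] <-
        if (sum(ok) >= min_shared) cor(m[ok, i], m[ok, j]) else NA_real_
    }
  }
  structure(list(r = r,
                 median_off_diagonal = median(r[lower.tri(r)], na.rm = TRUE)),
            class = "pairwise_pearson")
}

#' @export
print.pairwise_pearson <- function(x, ...) {
  cat(sprintf("<pairwise_pearson: %d samples, median off-diagonal r = %.3f>\n",
              ncol(x$r), x$median_off_diagonal))
  invisible(x)
}
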