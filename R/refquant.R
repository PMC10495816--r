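# RefQuant: estimate each low-input target channel's precursor intensity from
# the distribution of ion-level target/reference ratios, scaled by a cross-run
# reference intensity. The reference channel carries much more material than
# the targets, so target/reference ratios are small; interference inflates a
# subset of them, which motivates retaining only the lowest 40% after an
# ascending sort.

#' Ion-level target/reference ratios for one precursor in one run
#'
#' Forms one ratio per ion where both channels have a positive, non-missing
#' quantity: fragment ions pair by index (the fragment set is shared across
#' channels of a precursor), and the MS1 area contributes one additional
#' ratio. Ratio order is fragment index order, then MS1.
#'
#' @param target_fragments,reference_fragments Aligned numeric vectors of
#'   fragment quantities (`NA` = undetected).
#' @param target_ms1,reference_ms1 MS1 areas (scalars, `NA` = undetected).
#' @return Numeric vector of positive ratios; empty if no ion is shared.
#' @examples
#' extract_ion_ratios(c(10, 20, NA, 5), c(1000, 1000, 500, NA), 30, 2000)
#' # 0.010 0.020 0.015
#' @export
extract_ion_ratios <- function(target_fragments, reference_fragments,
                               target_ms1 = NA_real_, reference_ms1 = NA_real_) {
  if (length(target_fragments) != length(reference_fragments)) {
    abort("Fragment vectors must be aligned (identical length) across channels.")
  }
  ok <- !is.na(target_fragments) & !is.na(reference_fragments) &
    target_fragments > 0 & reference_fragments > 0
  ratios <- target_fragments[ok] / reference_fragments[ok]
  if (!is.na(target_ms1) && !is.na(reference_ms1) &&
      target_ms1 > 0 && reference_ms1 > 0) {
    ratios <- c(ratios, target_ms1 / reference_ms1)
  }
  ratios
}

# Shared kernel: lowest-quantile mean of a ratio sample.
.quantile_mean <- function(ratios, quantile_fraction, geometric = FALSE) {
  n <- length(ratios)
  k <- max(1L, as.integer(floor(quantile_fraction * n)))
  retained <- sort(ratios, method = "radix")[seq_len(k)]  # stable ascending
  r <- if (geometric) exp(mean(log(retained))) else mean(retained)
  list(n_total = n, n_retained = k, retained = retained, R = r)
}

#' Robust ratio estimate from an ion-ratio sample
#'
#' Sorts the ratios in ascending order, retains the first
#' `max(1, floor(quantile_fraction * n))`, and averages them. With the default
#' 40% fraction, the 7–14 ratios typically available per precursor reduce to
#' 2–5. Retaining the low tail acts as a noise filter: additive interference
#' can only inflate a target/reference ratio, so the low quantile is the
#' least contaminated part of the distribution.
#'
#' @param ratios Positive numeric vector, at least one element.
#' @param quantile_fraction Fraction of the sorted ratios to retain, in
#'   `(0, 1]`; default 0.40.
#' @param mean_type `"linear"` (arithmetic mean of the retained ratios, the
#'   default) or `"geometric"` (mean in log space).
#' @return A list of class `ratio_estimate`: `ratios` (input order), `retained`
#'   (ascending), `n_total`, `n_retained`, `R`, `quantile_fraction`.
#' @examples
#' estimate_ratio(c(0.01, 0.02, 0.03, 0.04, 0.05, 1.0, 1.1))$R # 0.015
#' @export
estimate_ratio <- function(ratios, quantile_fraction = 0.4,
                           mean_type = c("linear", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (length(ratios) == 0L) {
    abort("Cannot estimate a ratio from an empty ratio sample.")
  }
  if (any(!is.finite(ratios) | ratios <= 0)) {
    abort("Ratios must be positive and finite.")
  }
  if (quantile_fraction <= 0 || quantile_fraction > 1) {
    abort("`quantile_fraction` must lie in (0, 1].")
  }
  est <- .quantile_mean(ratios, quantile_fraction,
                        geometric = mean_type == "geometric")
  structure(
    list(ratios = ratios, retained = est$retained, n_total = est$n_total,
         n_retained = est$n_retained, R = est$R,
         quantile_fraction = quantile_fraction, mean_type = mean_type),
    class = "ratio_estimate"
  )
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("<ratio_estimate: R = %.6g from %d/%d ratios (lowest %.0f%%)>\n",
              x$R, x$n_retained, x$n_total, 100 * x$quantile_fraction))
  invisible(x)
}

.median2 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) >= 2L) median(x) else NA_real_
}

#' Cross-run reference scaling factor for one precursor
#'
#' The scaling factor that converts a target/reference ratio into an absolute
#' target intensity is the median reference-channel intensity of the precursor
#' over all runs. The intensity source follows a fallback hierarchy: MS1 area
#' if at least two runs have one, else Precursor.Translated, else
#' Precursor.Normalised, else the per-run sum of available ion intensities
#' (fragments plus MS1 where present).
#'
#' @param ms1_area,precursor_translated,precursor_normalised Numeric vectors,
#'   one entry per run in which the precursor's reference channel was observed.
#' @param fragment_quant List of fragment-quantity vectors, one per run.
#' @return List with `value` (positive scalar) and `source` (one of
#'   `"ms1_area"`, `"precursor_translated"`, `"precursor_normalised"`,
#'   `"summed_ions"`).
#' @export
reference_scaling_factor <- function(ms1_area, precursor_translated,
                                     precursor_normalised, fragment_quant) {
  n_runs <- length(fragment_quant)
  if (n_runs == 0L) {
    abort("Precursor has no reference-channel observation in any run.")
  }
  for (src in c("ms1_area", "precursor_translated", "precursor_normalised")) {
    v <- .median2(get(src))
    if (!is.na(v)) return(list(value = v, source = src))
  }
  summed <- purrr::map2_dbl(fragment_quant, seq_len(n_runs), function(fr, i) {
    s <- sum(fr, na.rm = TRUE) + ifelse(is.na(ms1_area[i]), 0, ms1_area[i])
    if (s > 0) s else NA_real_
  })
  summed <- summed[!is.na(summed)]
  if (length(summed) == 0L) {
    abort("Precursor has no usable reference intensity in any run.")
  }
  list(value = median(summed), source = "summed_ions")
}

#' RefQuant target intensity
#'
#' @param R Estimated target/reference ratio (a `ratio_estimate` or a positive
#'   scalar).
#' @param scale Reference scaling factor (result of
#'   [reference_scaling_factor()] or a positive scalar).
#' @return `R * scale`, the absolute intensity estimate of the precursor in
#'   the target channel.
#' @export
refquant_intensity <- function(R, scale) {
  r <- if (inherits(R, "ratio_estimate")) R$R else R
  s <- if (is.list(scale)) scale$value else scale
  r * s
}

.precursor_key <- function(stripped_sequence, charge) {
  paste0(stripped_sequence, "/", charge)
}

#' Run RefQuant on a filtered report
#'
#' For every (precursor, run, target channel) with at least one ion shared
#' with the run's reference channel, estimates the target/reference ratio by
#' the lowest-quantile mean ([estimate_ratio()]) and multiplies it by the
#' precursor's cross-run reference scaling factor
#' ([reference_scaling_factor()]). The scaling factor is computed once per
#' precursor across all runs and reused for every run — this cross-run
#' anchoring is what lets the constant reference stabilize quantification.
#'
#' Precursors never observed in any reference channel are dropped (counted in
#' the result's attributes). A target observation with no shared ion yields no
#' row: missing means missing, never zero.
#'
#' @param report Filtered `mdia_report` tibble (see [apply_qc_filters()]).
#' @param design `mdia_design` tibble; every run present in the report must
#'   declare exactly one reference channel.
#' @param quantile_fraction,mean_type Passed to the ratio estimator.
#' @return A tibble of class `refquant_fit`, one row per quantified
#'   (precursor, run, target channel): `precursor_key`, `protein_group`,
#'   `run`, `channel`, `sample_name`, `n_total`, `n_retained`, `ratio`,
#'   `scale`, `scale_source`, `intensity`. Attributes: `n_dropped_no_reference`
#'   (precursors without any reference observation), `quantile_fraction`,
#'   `mean_type`.
#' @seealso [tidy.refquant_fit()], [glance.refquant_fit()],
#'   [autoplot.refquant_fit()]
#' @export
run_refquant <- function(report, design, quantile_fraction = 0.4,
                         mean_type = c("linear", "geometric")) {
  mean_type <- match.arg(mean_type)
  design <- validate_design(design)
  runs_in_report <- unique(report$run)
  ref_design <- design |> dplyr::filter(.data$role == "reference")
  no_ref <- setdiff(runs_in_report, ref_design$run)
  if (length(no_ref)) {
    abort(sprintf("Run '%s' has no reference channel in the design.", no_ref[1]))
  }

  rep2 <- as_tibble(report) |>
    dplyr::mutate(precursor_key = .precursor_key(.data$stripped_sequence,
                                                 .data$charge)) |>
    dplyr::inner_join(as_tibble(design), by = c("run", "channel"))

  refs <- rep2 |>
    dplyr::filter(.data$role == "reference") |>
    dplyr::select("precursor_key", "run",
                  ref_fragments = "fragment_quant", ref_ms1 = "ms1_area",
                  ref_translated = "precursor_translated",
                  ref_normalised = "precursor_normalised")

  # one scaling factor per precursor, median over all runs' reference channel
  scales <- refs |>
    dplyr::group_by(.data$precursor_key) |>
    dplyr::summarise(scale_fit = list(reference_scaling_factor(
      .data$ref_ms1, .data$ref_translated, .data$ref_normalised,
      .data$ref_fragments)), .groups = "drop") |>
    dplyr::mutate(scale = purrr::map_dbl(.data$scale_fit, "value"),
                  scale_source = purrr::map_chr(.data$scale_fit, "source")) |>
    dplyr::select(-"scale_fit")

  targets <- rep2 |> dplyr::filter(.data$role == "target")
  n_dropped <- length(setdiff(unique(targets$precursor_key),
                              unique(refs$precursor_key)))

  geometric <- mean_type == "geometric"
  quant <- targets |>
    dplyr::inner_join(refs, by = c("precursor_key", "run")) |>
    dplyr::mutate(ratios = purrr::pmap(
      list(.data$fragment_quant, .data$ref_fragments,
           .data$ms1_area, .data$ref_ms1),
      extract_ion_ratios)) |>
    dplyr::filter(lengths(.data$ratios) > 0) |>
    dplyr::mutate(est = purrr::map(.data$ratios, .quantile_mean,
                                   quantile_fraction = quantile_fraction,
                                   geometric = geometric),
                  n_total = purrr::map_int(.data$est, "n_total"),
                  n_retained = purrr::map_int(.data$est, "n_retained"),
                  ratio = purrr::map_dbl(.data$est, "R")) |>
    dplyr::inner_join(scales, by = "precursor_key") |>
    dplyr::mutate(intensity = .data$ratio * .data$scale) |>
    dplyr::select("precursor_key", "protein_group", "run", "channel",
                  "sample_name", "n_total", "n_retained", "ratio", "scale",
                  "scale_source", "intensity") |>
    dplyr::arrange(.data$precursor_key, .data$run, .data$channel)

  structure(quant,
            class = c("refquant_fit", class(tibble())),
            n_dropped_no_reference = n_dropped,
            quantile_fraction = quantile_fraction,
            mean_type = mean_type)
}

#' Pivot a long quantification table to a wide matrix
#'
#' @param quant Long tibble with a sample column and an intensity column
#'   (e.g. a `refquant_fit` or the output of [maxlfq_rollup()]).
#' @param row Name of the row-key column (default `"precursor_key"`).
#' @param sample,value Names of the sample and value columns.
#' @return Wide tibble, one row per row key, one column per sample; absent
#'   observations are `NA`.
#' @export
quant_wide <- function(quant, row = "precursor_key", sample = "sample_name",
                       value = "intensity") {
  as_tibble(quant) |>
    dplyr::select(dplyr::all_of(c(row, sample, value))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(sample),
                       values_from = dplyr::all_of(value))
}

#' Per-precursor channel ratio from summed ion intensities
#'
#' For every (precursor, run) observed in both channels, sums the ion
#' intensities (fragments plus MS1) over the ions detected in both channels
#' and returns their ratio. This is the plain summed-intensity quantification
#' used for bulk mixing-design readouts, independent of the quantile-mean
#' ratio estimator.
#'
#' @param report An `mdia_report` tibble.
#' @param numerator,denominator Channel numbers.
#' @return Tibble: `precursor_key`, `run`, `ratio`
#'   (numerator sum / denominator sum over shared ions).
#' @export
summed_channel_ratio <- function(report, numerator, denominator) {
  rep2 <- as_tibble(report) |>
    dplyr::mutate(precursor_key = .precursor_key(.data$stripped_sequence,
                                                 .data$charge))
  num <- rep2 |> dplyr::filter(.data$channel == numerator) |>
    dplyr::select("precursor_key", "run", num_frag = "fragment_quant",
                  num_ms1 = "ms1_area")
  den <- rep2 |> dplyr::filter(.data$channel == denominator) |>
    dplyr::select("precursor_key", "run", den_frag = "fragment_quant",
                  den_ms1 = "ms1_area")
  dplyr::inner_join(num, den, by = c("precursor_key", "run")) |>
    dplyr::mutate(ratio = purrr::pmap_dbl(
      list(.data$num_frag, .data$den_frag, .data$num_ms1, .data$den_ms1),
      function(nf, df, nm, dm) {
        ok <- !is.na(nf) & !is.na(df)
        top <- sum(nf[ok])
        bot <- sum(df[ok])
        if (!is.na(nm) && !is.na(dm)) { top <- top + nm; bot <- bot + dm }
        if (bot > 0 && top > 0) top / bot else NA_real_
      })) |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::select("precursor_key", "run", "ratio")
}
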