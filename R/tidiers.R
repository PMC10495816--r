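# broom-style tidiers for the package's result objects.

#' Tidy a RefQuant fit
#'
#' @param x A `refquant_fit` from [run_refquant()].
#' @param ... Unused.
#' @return A plain tibble, one row per quantified (precursor, run, target
#'   channel) with ratio and intensity estimates and their provenance.
#' @method tidy refquant_fit
#' @export
tidy.refquant_fit <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Summarize a RefQuant fit
#'
#' @inheritParams tidy.refquant_fit
#' @return One-row tibble: numbers of quantified entries, precursors, runs
#'   and samples, median ratios retained per precursor, median log2 ratio,
#'   and the count of precursors dropped for lack of a reference observation.
#' @method glance refquant_fit
#' @export
glance.refquant_fit <- function(x, ...) {
  tibble(
    n_entries = nrow(x),
    n_precursors = dplyr::n_distinct(x$precursor_key),
    n_runs = dplyr::n_distinct(x$run),
    n_samples = dplyr::n_distinct(x$sample_name),
    median_n_ratios = median(x$n_total),
    median_n_retained = median(x$n_retained),
    median_log2_ratio = median(log2(x$ratio)),
    n_dropped_no_reference = attr(x, "n_dropped_no_reference"),
    quantile_fraction = attr(x, "quantile_fraction")
  )
}

#' @rdname glance.refquant_fit
#' @method glance cv_summary
#' @export
glance.cv_summary <- function(x, ...) {
  tibble(n_rows = nrow(x), median_cv = attr(x, "median_cv"),
         n_samples = length(attr(x, "group")))
}

#' @rdname glance.refquant_fit
#' @method glance channel_fdr_curve
#' @export
glance.channel_fdr_curve <- function(x, ...) {
  at <- function(t) {
    i <- which(abs(x$threshold - t) < 1e-12)
    if (length(i)) x$fdr[i[1]] else NA_real_
  }
  tibble(level = x$level[1], n_thresholds = nrow(x),
         fdr_at_0.01 = at(0.01), fdr_at_0.15 = at(0.15))
}
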