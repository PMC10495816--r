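# End-to-end orchestration: filter -> RefQuant -> protein roll-up -> QC,
# with a reproducible run manifest.

#' Run the full mDIA quantification pipeline
#'
#' Reads a DIA-NN-dialect report and a design table, applies q-value filters,
#' runs RefQuant, rolls precursor intensities up to protein groups with
#' MaxLFQ, computes QC metrics, and writes all outputs plus a run manifest to
#' `out_dir`. All stages are deterministic given identical inputs.
#'
#' @param report_path,design_path Input TSV paths (see [read_report()],
#'   [read_design()]).
#' @param out_dir Output directory, created if needed. Files written:
#'   `filtered_report.tsv`, `precursor_long.tsv` (RefQuant provenance),
#'   `precursor_matrix.tsv` (wide), `protein_matrix.tsv`, `qc.json`,
#'   `manifest.json`.
#' @param filter A [filter_config()]; default the single-cell preset.
#' @param quantile_fraction,mean_type Passed to [run_refquant()].
#' @param min_precursors Passed to [maxlfq_rollup()].
#' @param normalize Apply [median_normalize()] to the protein matrix
#'   (default `TRUE`).
#' @param schema Report column schema.
#' @return Invisibly, a list with the in-memory stage results (`filtered`,
#'   `refquant`, `protein`, `qc`, `manifest`).
#' @export
run_pipeline <- function(report_path, design_path, out_dir,
                         filter = filter_config("single-cell"),
                         quantile_fraction = 0.4,
                         mean_type = "linear",
                         min_precursors = 1L,
                         normalize = TRUE,
                         schema = diann_schema()) {
  t0 <- Sys.time()
  report <- read_report(report_path, schema = schema)
  design <- read_design(design_path)
  filtered <- apply_qc_filters(report, filter)
  fit <- run_refquant(filtered, design, quantile_fraction = quantile_fraction,
                      mean_type = mean_type)
  protein <- maxlfq_rollup(fit, min_precursors = min_precursors)
  if (normalize) protein <- median_normalize(protein)

  qc <- list(
    summed_signal = summed_signal(fit),
    completeness = completeness_by_quartile(protein),
    cv = if (dplyr::n_distinct(fit$sample_name) >= 2)
      glance(cv_per_row(protein)) else NULL,
    fdr_curve = if (any(design$role == "empty"))
      channel_fdr_curve(report, design) else NULL
  )

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report(filtered, file.path(out_dir, "filtered_report.tsv"),
               schema = schema)
  readr::write_tsv(as_tibble(fit), file.path(out_dir, "precursor_long.tsv"),
                   progress = FALSE)
  readr::write_tsv(quant_wide(fit), file.path(out_dir, "precursor_matrix.tsv"),
                   progress = FALSE)
  readr::write_tsv(quant_wide(protein, row = "protein_group"),
                   file.path(out_dir, "protein_matrix.tsv"), progress = FALSE)
  jsonlite::write_json(
    purrr::compact(purrr::map(qc, function(x) {
      if (is.data.frame(x)) as.data.frame(x) else x
    })),
    file.path(out_dir, "qc.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  manifest <- list(
    tool = "mdiaquant",
    version = as.character(utils::packageVersion("mdiaquant")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(
      report = list(path = report_path,
                    md5 = unname(tools::md5sum(report_path))),
      design = list(path = design_path,
                    md5 = unname(tools::md5sum(design_path)))
    ),
    parameters = list(
      filter_preset = filter$preset_name,
      thresholds = unclass(filter)[startsWith(names(unclass(filter)), "max_")],
      quantile_fraction = quantile_fraction, mean_type = mean_type,
      min_precursors = min_precursors, normalize = normalize
    ),
    counts = list(
      report_rows = nrow(report),
      filtered_rows = nrow(filtered),
      removed = as.data.frame(attr(filtered, "removed")),
      quantified_entries = nrow(fit),
      precursors_dropped_no_reference =
        attr(fit, "n_dropped_no_reference"),
      proteins = dplyr::n_distinct(protein$protein_group),
      samples = dplyr::n_distinct(fit$sample_name)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(filtered = filtered, refquant = fit, protein = protein,
                 qc = qc, manifest = manifest))
}

#' Label-scheme table for printing
#'
#' @param kind Scheme name, as in [label_scheme()].
#' @return Tibble with channel, per-label mass, per-label delta and the mass
#'   shift of an example doubly labeled peptide.
#' @export
label_table <- function(kind = c("3plex-trypsin", "5plex-lysn")) {
  kind <- match.arg(kind)
  sch <- label_scheme(kind)
  example <- if (kind == "3plex-trypsin") "PEPTIDEK" else "KPEPTIDE"
  protease <- attr(sch, "protease")
  as_tibble(sch) |>
    dplyr::mutate(
      label_mass = round(.data$label_mass, 4),
      label_delta = round(.data$label_delta, 4),
      example_peptide = example,
      example_shift = round(vapply(.data$channel, function(ch) {
        precursor_mass_shift(example, ch, protease)
      }, numeric(1)), 4))
}
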