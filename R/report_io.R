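# Internal canonical column names -> DIA-NN 1.8.1 report column names.
# Users can rename for other dialects via the `schema` argument of
# read_report(); only names present in the schema are consumed.

#' Default DIA-NN report schema
#'
#' Mapping from the canonical column names used throughout this package to the
#' column headers of a DIA-NN 1.8.1 long report. Override entries to read
#' other dialects, e.g. `diann_schema(run = "File.Name")`.
#'
#' @param ... Named overrides, `canonical = "File.Column"`.
#' @return Named character vector (canonical name -> file column).
#' @export
diann_schema <- function(...) {
  schema <- c(
    run                 = "Run",
    protein_group       = "Protein.Group",
    genes               = "Genes",
    precursor_id        = "Precursor.Id",
    modified_sequence   = "Modified.Sequence",
    stripped_sequence   = "Stripped.Sequence",
    charge              = "Precursor.Charge",
    channel             = "Channel",
    q_value             = "Q.Value",
    global_pg_q_value   = "Global.PG.Q.Value",
    pg_q_value          = "PG.Q.Value",
    lib_pg_q_value      = "Lib.PG.Q.Value",
    channel_q_value     = "Channel.Q.Value",
    translated_q_value  = "Translated.Q.Value",
    ms1_area            = "Ms1.Area",
    precursor_translated  = "Precursor.Translated",
    precursor_normalised  = "Precursor.Normalised",
    fragment_quant_raw  = "Fragment.Quant.Raw"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(schema))
    if (length(bad)) {
      abort(paste0("Unknown schema field(s): ", paste(bad, collapse = ", ")))
    }
    schema[names(overrides)] <- overrides
  }
  schema
}

# Columns that may be absent from the file without a schema error.
.optional_report_cols <- c("genes", "channel", "translated_q_value")
.q_value_cols <- c("q_value", "global_pg_q_value", "pg_q_value",
                   "lib_pg_q_value", "channel_q_value", "translated_q_value")
# Scalar quantity columns where DIA-NN's 0 means "not measured".
.quantity_cols <- c("ms1_area", "precursor_translated", "precursor_normalised")

.parse_numeric_col <- function(x, col, zero_missing = FALSE) {
  x[!is.na(x) & x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    abort(sprintf("Non-numeric token '%s' in column %s at data row %d.",
                  x[bad[1]], col, bad[1]))
  }
  if (zero_missing) out[!is.na(out) & out == 0] <- NA_real_
  out
}

.parse_fragment_col <- function(x) {
  pieces <- stringr::str_split(x, stringr::fixed(";"))
  purrr::imap(pieces, function(p, i) {
    p[p == ""] <- NA_character_
    v <- suppressWarnings(as.numeric(p))
    bad <- which(!is.na(p) & is.na(v))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric fragment token '%s' in Fragment.Quant.Raw at data row %d.",
        p[bad[1]], i))
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort(sprintf("Negative fragment quantity at data row %d.", i))
    }
    v[!is.na(v) & v == 0] <- NA_real_   # DIA-NN emits 0 for undetected ions
    v
  })
}

#' Read a DIA-NN-dialect long report
#'
#' Reads a tab-separated long report (one row per precursor x run x channel)
#' into a tibble with canonical column names. Fragment quantities are split on
#' `;` into a numeric list-column `fragment_quant`; zero or empty quantity
#' tokens become `NA` (an undetected ion is missing, not a measured zero, so
#' that downstream ratio formation never divides by or propagates zeros).
#' Channel identity is taken from the explicit `Channel` column when present,
#' otherwise parsed from the dimethyl label tokens in the precursor id via
#' [parse_channel()].
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Column-name mapping from [diann_schema()].
#' @return A tibble of class `mdia_report`, one row per report row, in file
#'   order.
#' @seealso [write_report()], [apply_qc_filters()]
#' @export
read_report <- function(path, schema = diann_schema()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  required <- setdiff(names(schema), .optional_report_cols)
  missing_cols <- schema[required][!schema[required] %in% names(raw)]
  if (length(missing_cols)) {
    abort(paste0("Report is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  present <- schema[schema %in% names(raw)]
  out <- tibble(.rows = nrow(raw))
  for (canon in names(present)) out[[canon]] <- raw[[present[[canon]]]]

  out$charge <- .parse_numeric_col(out$charge, present[["charge"]])
  if (any(out$charge <= 0 | out$charge != round(out$charge), na.rm = TRUE)) {
    abort("Precursor charge must be a positive integer.")
  }
  out$charge <- as.integer(out$charge)
  for (qc in intersect(.q_value_cols, names(out))) {
    out[[qc]] <- .parse_numeric_col(out[[qc]], present[[qc]])
    if (any(out[[qc]] < 0 | out[[qc]] > 1, na.rm = TRUE)) {
      abort(sprintf("Column %s contains q-values outside [0, 1].", present[[qc]]))
    }
  }
  for (qt in .quantity_cols) {
    out[[qt]] <- .parse_numeric_col(out[[qt]], present[[qt]], zero_missing = TRUE)
  }
  out$fragment_quant <- .parse_fragment_col(out$fragment_quant_raw)
  out$fragment_quant_raw <- NULL

  if ("channel" %in% names(out)) {
    out$channel <- as.integer(.parse_numeric_col(out$channel, present[["channel"]]))
  } else {
    out$channel <- parse_channel(out$precursor_id)
  }
  class(out) <- c("mdia_report", class(out))
  out
}

#' Resolve the dimethyl channel of a precursor id
#'
#' Scans the channel-decorated modified sequence for dimethyl label tokens of
#' the form `Dimethyl-n-<k>` (N-terminal label) or `Dimethyl-K-<k>` (lysine
#' label) and returns the common nominal delta `k`. An explicit channel value
#' (e.g. from a report's `Channel` column) takes precedence over the token
#' scan.
#'
#' @param precursor_id Character vector of channel-decorated precursor ids.
#' @param explicit Optional explicit channel values (numeric or character);
#'   non-`NA` entries override the token scan.
#' @return Integer vector of channels (0, 2, 4, 6 or 8).
#' @examples
#' parse_channel("AAK(Dimethyl-K-4)KPR(Dimethyl-n-4)2") # 4
#' @export
parse_channel <- function(precursor_id, explicit = NULL) {
  tokens <- stringr::str_match_all(precursor_id, "Dimethyl-[nK]-(\\d+)")
  out <- purrr::imap_int(tokens, function(m, i) {
    ks <- unique(as.integer(m[, 2]))
    if (length(ks) > 1L) {
      abort(sprintf(
        "Conflicting channel tokens (%s) in precursor id '%s'.",
        paste(ks, collapse = ", "), precursor_id[i]))
    }
    if (length(ks) == 0L) return(NA_integer_)
    ks
  })
  if (!is.null(explicit)) {
    explicit <- suppressWarnings(as.integer(as.numeric(explicit)))
    out[!is.na(explicit)] <- explicit[!is.na(explicit)]
  }
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    abort(sprintf(
      "Cannot resolve channel for precursor id '%s': no label token and no explicit channel.",
      precursor_id[i]))
  }
  out
}

#' Write a report tibble back to the DIA-NN dialect
#'
#' Inverse of [read_report()] under the documented missingness convention:
#' `NA` quantities are written as `0`, matching the search engine's encoding
#' of undetected ions, and fragment vectors are re-joined with `;`.
#'
#' @param report An `mdia_report` tibble.
#' @param path Output TSV path.
#' @param schema Column-name mapping from [diann_schema()].
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, schema = diann_schema()) {
  num_chr <- function(x) ifelse(is.na(x), "0", vapply(x, function(v) {
    format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1)))
  out <- list()
  for (canon in names(schema)) {
    col <- schema[[canon]]
    if (canon == "fragment_quant_raw") {
      out[[col]] <- vapply(report$fragment_quant, function(v) {
        paste(num_chr(v), collapse = ";")
      }, character(1))
    } else if (canon %in% names(report)) {
      x <- report[[canon]]
      out[[col]] <- if (is.numeric(x)) num_chr(x) else as.character(x)
    }
  }
  readr::write_tsv(as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Q-value filter configurations
#'
#' Two presets mirror standard practice for dimethyl mDIA data: `"bulk"`
#' (Global.PG.Q.Value < 0.01, PG.Q.Value < 0.05, Channel.Q.Value < 0.01) and
#' `"single-cell"` (Lib.PG.Q.Value < 0.01, Q.Value < 0.01, Channel.Q.Value
#' < 0.15). All comparisons are strict. Any threshold can be overridden; `NA`
#' disables a criterion.
#'
#' @param preset `"single-cell"` or `"bulk"`.
#' @param max_global_pg_q,max_pg_q,max_lib_pg_q,max_q,max_channel_q Optional
#'   threshold overrides in `(0, 1]`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(preset = c("single-cell", "bulk"),
                          max_global_pg_q = NULL, max_pg_q = NULL,
                          max_lib_pg_q = NULL, max_q = NULL,
                          max_channel_q = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "bulk") {
    list(max_global_pg_q = 0.01, max_pg_q = 0.05, max_lib_pg_q = NA_real_,
         max_q = NA_real_, max_channel_q = 0.01)
  } else {
    list(max_global_pg_q = NA_real_, max_pg_q = NA_real_, max_lib_pg_q = 0.01,
         max_q = 0.01, max_channel_q = 0.15)
  }
  overrides <- list(max_global_pg_q = max_global_pg_q, max_pg_q = max_pg_q,
                    max_lib_pg_q = max_lib_pg_q, max_q = max_q,
                    max_channel_q = max_channel_q)
  for (nm in names(overrides)) {
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  }
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.na(v) && (v <= 0 || v > 1)) {
      abort(sprintf("Threshold %s must lie in (0, 1].", nm))
    }
  }
  cfg$preset_name <- preset
  structure(cfg, class = "filter_config")
}

#' Apply q-value filters to a report
#'
#' Retains rows passing all configured strict-inequality thresholds. Rows with
#' a missing q-value for an active criterion fail that criterion. The number
#' of rows failing each criterion is attached as attribute `removed` (a row
#' can fail several criteria; the counts are per criterion, not disjoint).
#'
#' @param report An `mdia_report` tibble.
#' @param cfg A [filter_config()].
#' @return Filtered report with attribute `removed`.
#' @export
apply_qc_filters <- function(report, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  crit <- c(max_global_pg_q = "global_pg_q_value", max_pg_q = "pg_q_value",
            max_lib_pg_q = "lib_pg_q_value", max_q = "q_value",
            max_channel_q = "channel_q_value")
  keep <- rep(TRUE, nrow(report))
  removed <- tibble(criterion = character(), threshold = numeric(),
                    n_removed = integer())
  for (nm in names(crit)) {
    thr <- cfg[[nm]]
    if (is.na(thr)) next
    col <- crit[[nm]]
    pass <- !is.na(report[[col]]) & report[[col]] < thr
    removed <- dplyr::bind_rows(removed, tibble(
      criterion = col, threshold = thr, n_removed = sum(!pass)))
    keep <- keep & pass
  }
  out <- report[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Read an experiment design table
#'
#' The design maps every (run, channel) to a role — `reference` (the
#' high-input anchor proteome), `target` (a sample of interest, e.g. one
#' cell), or `empty` (a deliberately blank channel used for count-based FDR
#' estimation) — and a sample name.
#'
#' @param path TSV with columns `run`, `channel`, `role`, `sample_name`.
#' @return A validated design tibble of class `mdia_design`.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    run = readr::col_character(), channel = readr::col_integer(),
    role = readr::col_character(), sample_name = readr::col_character()
  ), progress = FALSE)
  validate_design(d)
}

#' Validate an experiment design
#'
#' @param design Data frame with columns `run`, `channel`, `role`,
#'   `sample_name`.
#' @return The design as an `mdia_design` tibble, or an error describing the
#'   violated invariant (duplicate run/channel, unknown role, more than one
#'   reference channel in a run).
#' @export
validate_design <- function(design) {
  design <- as_tibble(design)
  needed <- c("run", "channel", "role", "sample_name")
  if (!all(needed %in% names(design))) {
    abort(paste0("Design must have columns: ", paste(needed, collapse = ", ")))
  }
  bad_role <- setdiff(unique(design$role), c("reference", "target", "empty"))
  if (length(bad_role)) {
    abort(paste0("Unknown design role(s): ", paste(bad_role, collapse = ", ")))
  }
  dup <- design |> dplyr::count(.data$run, .data$channel) |> dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("Design maps run '%s' channel %d to more than one role.",
                  dup$run[1], dup$channel[1]))
  }
  nref <- design |> dplyr::filter(.data$role == "reference") |>
    dplyr::count(.data$run) |> dplyr::filter(.data$n > 1)
  if (nrow(nref)) {
    abort(sprintf("Run '%s' declares more than one reference channel.",
                  nref$run[1]))
  }
  design$channel <- as.integer(design$channel)
  if (!inherits(design, "mdia_design")) {
    class(design) <- c("mdia_design", class(design))
  }
  design
}

#' @rdname read_design
#' @param design An `mdia_design` tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(as_tibble(design), path, progress = FALSE)
  invisible(path)
}
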