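# Protein-level quantification: MaxLFQ pairwise-median / least-squares
# roll-up, median channel normalization, and CV summaries.

# Largest connected component of samples linked by >=1 shared precursor.
# m: precursors x samples log2 matrix (NA = missing).
.largest_component <- function(obs) {
  n <- ncol(obs)
  adj <- crossprod(obs) > 0          # samples sharing >=1 precursor
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  which(comp == which.max(sizes))
}

# MaxLFQ for one protein: pairwise median log-ratios, least squares on the
# largest connected component, anchored so the summed linear protein
# intensity equals the summed observed precursor intensity.
.maxlfq_one <- function(m_log2) {
  n <- ncol(m_log2)
  if (nrow(m_log2) == 1L) {
    return(unname(2^m_log2[1, ]))    # single precursor: profile passes through
  }
  obs <- !is.na(m_log2)
  comp <- .largest_component(obs)
  out <- rep(NA_real_, n)
  if (length(comp) == 1L) {          # isolated sample: anchor to its own total
    j <- comp[1]
    out[j] <- sum(2^m_log2[obs[, j], j])
    return(out)
  }
  pairs <- utils::combn(comp, 2)
  rows <- list(); rhs <- numeric(0)
  for (p in seq_len(ncol(pairs))) {
    j <- pairs[1, p]; k <- pairs[2, p]
    shared <- obs[, j] & obs[, k]
    if (!any(shared)) next
    r <- median(m_log2[shared, k] - m_log2[shared, j])
    row <- numeric(n); row[j] <- -1; row[k] <- 1
    rows[[length(rows) + 1L]] <- row
    rhs <- c(rhs, r)
  }
  A <- do.call(rbind, rows)
  # minimum-norm least squares via SVD pseudoinverse (A is rank-deficient by
  # the global-shift gauge freedom)
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  x <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
  x <- drop(x)
  total_obs <- sum(2^m_log2[, comp][obs[, comp]])
  shift <- log2(total_obs / sum(2^x[comp]))
  out[comp] <- 2^(x[comp] + shift)
  out
}

#' Roll precursor quantities up to protein groups (MaxLFQ)
#'
#' For each protein group, computes all pairwise sample log2-ratios as the
#' median of per-precursor log-ratios over precursors observed in both
#' samples, solves the least-squares system for per-sample log-abundances
#' over the largest connected component of samples, and anchors the solution
#' so the summed linear protein intensity equals the summed observed
#' precursor intensity. Samples outside the component are missing.
#'
#' @param quant Long tibble of precursor quantities with columns named by
#'   `row`, `protein`, `sample` and `value` (e.g. a `refquant_fit`, or
#'   precursor-normalised quantities from a report).
#' @param min_precursors Proteins with fewer distinct precursors are dropped
#'   (and counted in attribute `n_dropped_proteins`). Default 1.
#' @param row,protein,sample,value Column names in `quant`.
#' @return Long tibble of class `protein_quant`: `protein_group`,
#'   `sample_name`, `intensity`, `n_precursors`.
#' @export
maxlfq_rollup <- function(quant, min_precursors = 1L, row = "precursor_key",
                          protein = "protein_group", sample = "sample_name",
                          value = "intensity") {
  stopifnot(min_precursors >= 1L)
  q <- as_tibble(quant) |>
    dplyr::select(row_key = dplyr::all_of(row),
                  protein_group = dplyr::all_of(protein),
                  sample_name = dplyr::all_of(sample),
                  intensity = dplyr::all_of(value)) |>
    dplyr::filter(!is.na(.data$intensity))
  if (nrow(q) == 0L) abort("`quant` has no non-missing intensities.")
  if (any(q$intensity <= 0)) abort("Intensities must be positive.")
  samples <- sort(unique(q$sample_name))

  counts <- q |>
    dplyr::group_by(.data$protein_group) |>
    dplyr::summarise(n_precursors = dplyr::n_distinct(.data$row_key),
                     .groups = "drop")
  keep <- counts$protein_group[counts$n_precursors >= min_precursors]
  n_dropped <- nrow(counts) - length(keep)

  per_protein <- q |>
    dplyr::filter(.data$protein_group %in% keep) |>
    dplyr::group_by(.data$protein_group) |>
    dplyr::group_map(function(d, key) {
      m <- matrix(NA_real_, nrow = dplyr::n_distinct(d$row_key),
                  ncol = length(samples),
                  dimnames = list(unique(d$row_key), samples))
      m[cbind(match(d$row_key, rownames(m)),
              match(d$sample_name, samples))] <- log2(d$intensity)
      prof <- .maxlfq_one(m)
      tibble(protein_group = key$protein_group, sample_name = samples,
             intensity = prof, n_precursors = nrow(m))
    }) |>
    dplyr::bind_rows() |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::arrange(.data$protein_group, .data$sample_name)

  structure(per_protein, class = c("protein_quant", class(tibble())),
            n_dropped_proteins = n_dropped)
}

#' Median channel normalization
#'
#' Equalizes sample medians in log2 space: each sample's median log2
#' intensity is shifted to the grand median (the median of the per-sample
#' medians). Within-sample ratios are unchanged; the operation is idempotent.
#'
#' @param quant Long tibble with `sample` and `value` columns (linear scale).
#' @param sample,value Column names.
#' @return `quant` with the value column normalized (linear scale), same class
#'   and row order.
#' @export
median_normalize <- function(quant, sample = "sample_name",
                             value = "intensity") {
  x <- as_tibble(quant)
  smp <- x[[sample]]
  v <- x[[value]]
  meds <- tapply(log2(v), smp, median, na.rm = TRUE)
  meds <- setNames(as.numeric(meds), names(meds))
  if (any(is.na(meds))) {
    abort(sprintf("Sample '%s' has no finite intensities to normalize.",
                  names(meds)[which(is.na(meds))[1]]))
  }
  grand <- median(meds)
  quant[[value]] <- 2^(log2(v) - unname(meds[as.character(smp)]) + grand)
  quant
}

#' Per-row coefficients of variation
#'
#' CV (%) = sample standard deviation / mean of the linear intensities x 100,
#' computed over the non-missing entries of each row within a sample group.
#' Rows with fewer than two values are excluded from the summary.
#'
#' @param quant Long tibble with row-key, sample and value columns.
#' @param group Character vector of sample names forming the replicate group;
#'   default all samples in `quant`. Must contain at least two.
#' @param row,sample,value Column names.
#' @return Tibble of class `cv_summary`: one row per row key with `n`, `mean`
#'   and `cv` (%), rows with `n >= 2` only; attribute `median_cv` carries the
#'   summary median (also available via [glance()]).
#' @export
cv_per_row <- function(quant, group = NULL, row = "protein_group",
                       sample = "sample_name", value = "intensity") {
  q <- as_tibble(quant) |>
    dplyr::select(row_key = dplyr::all_of(row),
                  sample_name = dplyr::all_of(sample),
                  intensity = dplyr::all_of(value))
  group <- group %||% unique(q$sample_name)
  if (length(group) < 2L) {
    abort("CV requires a replicate group of at least two samples.")
  }
  out <- q |>
    dplyr::filter(.data$sample_name %in% group, !is.na(.data$intensity)) |>
    dplyr::group_by(.data$row_key) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$intensity),
                     cv = 100 * sd(.data$intensity) / mean(.data$intensity),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2L)
  structure(out, class = c("cv_summary", class(tibble())),
            median_cv = median(out$cv), group = group)
}
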