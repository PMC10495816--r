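# Synthetic DIA-NN-dialect report generator with known ground truth.
# The generator states a world: protein abundances spanning ~4 orders of
# magnitude, per-ion multiplicative log-normal noise, additive exponential
# interference on a fraction of ions, and shot-noise detection
# P(detect) = 1 - exp(-I / lambda), so missingness decreases with intensity.
# 250 pg is one single-cell equivalent; a 10 ng reference is 40x that.

#' Simulation configuration
#'
#' @param design Tibble with columns `run`, `channel`, `role`
#'   (`reference`/`target`/`empty`), `amount_pg` (channel loading in
#'   pg-equivalents; 0 for empty channels) and optionally `sample_name`.
#' @param n_proteins Number of simulated proteins.
#' @param precursors_per_protein Integer range (length 2).
#' @param fragments_per_precursor Integer range; the default 6–13 plus one MS1
#'   ratio yields the 7–14 usable ratios per precursor seen in practice.
#' @param abundance_meanlog10,abundance_sdlog10 Protein abundance is
#'   `10^N(mean, sd)`; the default sd of 1 spans ~4 orders of magnitude
#'   within 2 standard deviations.
#' @param noise_cv Multiplicative log-normal noise CV per ion observation.
#' @param interference_fraction Fraction of ion observations receiving
#'   additive background.
#' @param background_scale Background is `Exp(mean = background_scale *
#'   median single-cell-equivalent ion intensity)`.
#' @param detection_lambda Shot-noise scale of `P(detect) = 1 - exp(-I /
#'   lambda)` (same intensity units as the generated quantities); `0` means
#'   every ion with positive intensity is detected.
#' @param protease `"trypsin"` or `"lysn"` (controls simulated peptide
#'   termini and label tokens).
#' @param single_cell_pg Definition of one single-cell equivalent (250 pg).
#' @param species_fractions,species_ratios Optional multi-species mixing:
#'   named fractions of proteins per species and a named list of per-channel
#'   abundance multipliers (aligned to the sorted channel set).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(design,
                              n_proteins = 150L,
                              precursors_per_protein = c(2L, 5L),
                              fragments_per_precursor = c(6L, 13L),
                              abundance_meanlog10 = 2,
                              abundance_sdlog10 = 1,
                              noise_cv = 0.1,
                              interference_fraction = 0.3,
                              background_scale = 1,
                              detection_lambda = 25,
                              protease = c("trypsin", "lysn"),
                              single_cell_pg = 250,
                              species_fractions = NULL,
                              species_ratios = NULL,
                              seed = 1L) {
  protease <- match.arg(protease)
  design <- as_tibble(design)
  if (!"sample_name" %in% names(design)) {
    design$sample_name <- paste0(design$run, "_d", design$channel)
  }
  stopifnot(all(c("run", "channel", "role", "amount_pg") %in% names(design)))
  if (any(design$amount_pg < 0)) abort("Channel amounts must be non-negative.")
  if (any(design$amount_pg == 0 & design$role != "empty")) {
    abort("Only empty channels may have amount 0.")
  }
  if (any(design$amount_pg > 0 & design$role == "empty")) {
    abort("Empty channels must have amount 0.")
  }
  validate_design(design[c("run", "channel", "role", "sample_name")])
  if (noise_cv < 0 || interference_fraction < 0 || interference_fraction > 1 ||
      background_scale < 0 || detection_lambda < 0) {
    abort("Invalid noise/interference/detection parameters.")
  }
  if (!is.null(species_ratios)) {
    stopifnot(!is.null(species_fractions),
              setequal(names(species_ratios), names(species_fractions)))
  }
  structure(list(
    design = design, n_proteins = as.integer(n_proteins),
    precursors_per_protein = as.integer(precursors_per_protein),
    fragments_per_precursor = as.integer(fragments_per_precursor),
    abundance_meanlog10 = abundance_meanlog10,
    abundance_sdlog10 = abundance_sdlog10,
    noise_cv = noise_cv, interference_fraction = interference_fraction,
    background_scale = background_scale, detection_lambda = detection_lambda,
    protease = protease, single_cell_pg = single_cell_pg,
    species_fractions = species_fractions, species_ratios = species_ratios,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

.aa_pool <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # no K/R internally

.random_peptides <- function(n, protease) {
  core <- vapply(seq_len(n), function(i) {
    paste(sample(.aa_pool, sample(7:12, 1), replace = TRUE), collapse = "")
  }, character(1))
  if (protease == "trypsin") {
    paste0(core, sample(c("K", "R"), n, replace = TRUE))
  } else {
    paste0("K", core)
  }
}

.decorate_sequence <- function(stripped, channel) {
  tag_n <- sprintf("(Dimethyl-n-%d)", channel)
  tag_k <- sprintf("(Dimethyl-K-%d)", channel)
  paste0(tag_n, stringr::str_replace_all(stripped, stringr::fixed("K"),
                                         paste0("K", tag_k)))
}

#' Simulate a multiplexed DIA report with ground truth
#'
#' Generates a long report readable by [read_report()] without modification,
#' plus the ground truth needed for parameter-recovery tests. Each ion
#' observation is `protein abundance x channel amount x fragment base x
#' log-normal noise`, contaminated ions add exponential background, and ions
#' drop out with probability `exp(-I / lambda)`. Channel q-values are a
#' deliberate caricature sufficient to exercise filtering and count-based FDR
#' plumbing: rows backed by true signal draw `U(0, 0.01)`, background-only
#' rows (empty channels) draw `U(0, 1)`.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `mdia_sim`: `report` (`mdia_report` tibble),
#'   `design` (`mdia_design`), and `truth` (list with `proteins`,
#'   `precursors`, `ions` — per-observation true intensity and contamination
#'   flag — and the `config`).
#' @export
simulate_report <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, .simulate_report_impl(cfg))
}

.simulate_report_impl <- function(cfg) {
  design <- cfg$design
  channels <- sort(unique(design$channel))

  proteins <- tibble(
    protein_group = sprintf("PROT%04d", seq_len(cfg$n_proteins)),
    genes = sprintf("GENE%04d", seq_len(cfg$n_proteins)),
    abundance = 10^rnorm(cfg$n_proteins, cfg$abundance_meanlog10,
                         cfg$abundance_sdlog10)
  )
  if (!is.null(cfg$species_ratios)) {
    sp <- names(cfg$species_fractions)
    proteins$species <- sample(sp, cfg$n_proteins, replace = TRUE,
                               prob = unlist(cfg$species_fractions))
  } else {
    proteins$species <- "one"
  }

  n_prec_per <- sample(seq(cfg$precursors_per_protein[1],
                           cfg$precursors_per_protein[2]),
                       cfg$n_proteins, replace = TRUE)
  prec <- tibble(
    protein_group = rep(proteins$protein_group, n_prec_per),
    species = rep(proteins$species, n_prec_per),
    abundance = rep(proteins$abundance, n_prec_per)
  )
  n_prec <- nrow(prec)
  prec$stripped_sequence <- .random_peptides(n_prec, cfg$protease)
  # regenerate any duplicated sequence so precursor keys are unique
  while (anyDuplicated(prec$stripped_sequence)) {
    dup <- duplicated(prec$stripped_sequence)
    prec$stripped_sequence[dup] <- .random_peptides(sum(dup), cfg$protease)
  }
  prec$charge <- sample(2:3, n_prec, replace = TRUE)
  prec$n_frag <- sample(seq(cfg$fragments_per_precursor[1],
                            cfg$fragments_per_precursor[2]),
                        n_prec, replace = TRUE)
  prec$frag_base <- purrr::map(prec$n_frag, function(k) rlnorm(k, 0, 0.5))
  prec$ms1_base <- purrr::map_dbl(prec$frag_base, sum)
  prec$precursor_idx <- seq_len(n_prec)

  # per-ion table: fragments 1..n_frag, ion 0 = MS1
  ions <- tibble(
    precursor_idx = rep(prec$precursor_idx, prec$n_frag + 1L),
    ion_index = unlist(purrr::map(prec$n_frag, function(k) c(seq_len(k), 0L))),
    base = unlist(purrr::map2(prec$frag_base, prec$ms1_base, c))
  )
  # median single-cell-equivalent fragment-ion intensity defines the
  # background and detection scales of this world
  sc_ion <- rep(prec$abundance, prec$n_frag) *
    unlist(prec$frag_base)
  i0 <- median(sc_ion)

  species_mult <- function(species, channel) {
    if (is.null(cfg$species_ratios)) return(rep(1, length(species)))
    mult <- do.call(rbind, cfg$species_ratios)   # species x channel
    colnames(mult) <- as.character(channels)
    mult[cbind(match(species, rownames(mult)), match(as.character(channel),
                                                     colnames(mult)))]
  }

  obs <- tidyr::expand_grid(drow = seq_len(nrow(design)),
                            irow = seq_len(nrow(ions)))
  obs <- dplyr::bind_cols(
    design[obs$drow, c("run", "channel", "role", "amount_pg", "sample_name")],
    ions[obs$irow, ]
  )
  obs$abundance <- prec$abundance[obs$precursor_idx]
  obs$species <- prec$species[obs$precursor_idx]
  n_obs <- nrow(obs)

  signal <- obs$abundance * obs$base * (obs$amount_pg / cfg$single_cell_pg) *
    species_mult(obs$species, obs$channel)
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  signal <- signal * exp(rnorm(n_obs, 0, sdlog))
  contaminated <- runif(n_obs) < cfg$interference_fraction
  background <- ifelse(contaminated,
                       rexp(n_obs, rate = 1 / (cfg$background_scale * i0)), 0)
  intensity <- signal + background
  p_detect <- if (cfg$detection_lambda == 0) as.numeric(intensity > 0) else {
    1 - exp(-intensity / cfg$detection_lambda)
  }
  detected <- runif(n_obs) < p_detect
  obs$true_signal <- signal
  obs$contaminated <- contaminated
  obs$intensity <- ifelse(detected, intensity, NA_real_)

  rows <- obs |>
    dplyr::arrange(.data$precursor_idx, .data$run, .data$channel,
                   .data$ion_index) |>
    dplyr::group_by(.data$precursor_idx, .data$run, .data$channel,
                    .data$role, .data$amount_pg, .data$sample_name) |>
    dplyr::summarise(
      fragment_quant = list(.data$intensity[.data$ion_index > 0]),
      ms1_area = .data$intensity[.data$ion_index == 0],
      any_signal = any(!is.na(.data$intensity) & .data$true_signal > 0),
      .groups = "drop") |>
    dplyr::filter(purrr::map_lgl(.data$fragment_quant,
                                 function(v) any(!is.na(v))) |
                    !is.na(.data$ms1_area))

  n_rows <- nrow(rows)
  pinfo <- prec[rows$precursor_idx, ]
  modseq <- .decorate_sequence(pinfo$stripped_sequence, rows$channel)
  report <- tibble(
    run = rows$run,
    protein_group = pinfo$protein_group,
    genes = proteins$genes[match(pinfo$protein_group, proteins$protein_group)],
    precursor_id = paste0(modseq, pinfo$charge),
    modified_sequence = modseq,
    stripped_sequence = pinfo$stripped_sequence,
    charge = as.integer(pinfo$charge),
    q_value = runif(n_rows, 0, 0.005),
    global_pg_q_value = runif(n_rows, 0, 0.005),
    pg_q_value = runif(n_rows, 0, 0.005),
    lib_pg_q_value = runif(n_rows, 0, 0.005),
    channel_q_value = ifelse(rows$any_signal, runif(n_rows, 0, 0.01),
                             runif(n_rows, 0, 1)),
    translated_q_value = runif(n_rows, 0, 0.01),
    ms1_area = rows$ms1_area,
    precursor_translated = purrr::map_dbl(rows$fragment_quant, function(v) {
      s <- sum(v, na.rm = TRUE); if (s > 0) s else NA_real_
    }),
    fragment_quant = rows$fragment_quant,
    channel = as.integer(rows$channel)
  )
  report$precursor_normalised <- report$precursor_translated
  report <- report[, c("run", "protein_group", "genes", "precursor_id",
                       "modified_sequence", "stripped_sequence", "charge",
                       "q_value", "global_pg_q_value", "pg_q_value",
                       "lib_pg_q_value", "channel_q_value",
                       "translated_q_value", "ms1_area",
                       "precursor_translated", "precursor_normalised",
                       "fragment_quant", "channel")]
  class(report) <- c("mdia_report", class(report))

  truth <- list(
    proteins = proteins,
    precursors = prec[, c("precursor_idx", "protein_group", "species",
                          "abundance", "stripped_sequence", "charge",
                          "n_frag")],
    ions = obs[, c("precursor_idx", "ion_index", "run", "channel",
                   "true_signal", "contaminated", "intensity")],
    median_sc_ion_intensity = i0,
    config = cfg
  )
  structure(list(report = report,
                 design = validate_design(
                   design[c("run", "channel", "role", "sample_name")]),
                 truth = truth),
            class = "mdia_sim")
}

#' @export
print.mdia_sim <- function(x, ...) {
  cat(sprintf("<mdia_sim: %d report rows, %d precursors, %d runs, seed %d>\n",
              nrow(x$report), nrow(x$truth$precursors),
              dplyr::n_distinct(x$design$run), x$truth$config$seed))
  invisible(x)
}

.preset_names <- c("scBenchmark", "scQuant", "scDecoy", "scReference",
                   "bsa17_2_1", "fiveplex_1_2_4_2_1", "mixed_species")

#' Named benchmark simulation presets
#'
#' Ready-made [simulation_config()]s for the standard evaluation designs:
#' \describe{
#'   \item{scBenchmark}{3-plex, reference 10 ng (\eqn{\Delta}0), two 250 pg
#'     single-cell-equivalent targets (\eqn{\Delta}4, \eqn{\Delta}8), 5 runs.}
#'   \item{scQuant}{reference 10 ng; target pairs (\eqn{\Delta}4, \eqn{\Delta}8)
#'     at (62.5, 250), (250, 1000) and (500, 2000) pg across runs — a
#'     four-fold step between the two targets of each run, spanning
#'     62.5–2000 pg.}
#'   \item{scDecoy}{reference 10 ng; two runs with filled 250 pg targets, two
#'     runs with both target channels empty (four empty and four filled
#'     target channels for count-based FDR).}
#'   \item{scReference}{250 pg targets; reference amount graded 250, 1000,
#'     2500, 10000 pg across runs (a 40-fold span).}
#'   \item{bsa17_2_1}{bulk 3-plex mixing design, \eqn{\Delta}0:\eqn{\Delta}4:\eqn{\Delta}8
#'     = 17:2:1 (base 2.5 ng), interference-free.}
#'   \item{fiveplex_1_2_4_2_1}{bulk Lys-N 5-plex accuracy design,
#'     1:2:4:2:1 across \eqn{\Delta}0/\eqn{\Delta}2/\eqn{\Delta}4/\eqn{\Delta}6/\eqn{\Delta}8
#'     (base 50 ng), interference-free.}
#'   \item{mixed_species}{3-plex with three species mixed at per-channel
#'     ratios human 1:1:1, yeast 1:2:4, E. coli 4:2:1.}
#' }
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [simulation_config()] (e.g.
#'   `n_proteins`, `noise_cv`).
#' @return A `simulation_config`.
#' @export
mdia_preset <- function(name, seed = 1L, ...) {
  if (!name %in% .preset_names) {
    abort(paste0("Unknown preset '", name, "'. Available: ",
                 paste(.preset_names, collapse = ", ")))
  }
  runs <- function(n) sprintf("run%02d", seq_len(n))
  grid <- function(run, channel, role, amount_pg) {
    tidyr::expand_grid(run = run, idx = seq_along(channel)) |>
      dplyr::mutate(channel = channel[.data$idx], role = role[.data$idx],
                    amount_pg = amount_pg[.data$idx]) |>
      dplyr::select(-"idx")
  }
  args <- switch(name,
    scBenchmark = list(
      design = grid(runs(5), c(0L, 4L, 8L), c("reference", "target", "target"),
                    c(10000, 250, 250)),
      n_proteins = 150L),
    scQuant = {
      amounts <- list(c(62.5, 250), c(250, 1000), c(500, 2000))
      d <- purrr::imap_dfr(rep(amounts, each = 2), function(a, i) {
        grid(sprintf("run%02d", i), c(0L, 4L, 8L),
             c("reference", "target", "target"), c(10000, a[1], a[2]))
      })
      list(design = d, n_proteins = 150L)
    },
    scDecoy = list(
      design = dplyr::bind_rows(
        grid(runs(4)[1:2], c(0L, 4L, 8L), c("reference", "target", "target"),
             c(10000, 250, 250)),
        grid(runs(4)[3:4], c(0L, 4L, 8L), c("reference", "empty", "empty"),
             c(10000, 0, 0))),
      n_proteins = 150L),
    scReference = {
      ref_amt <- c(250, 1000, 2500, 10000)
      d <- purrr::imap_dfr(ref_amt, function(a, i) {
        grid(sprintf("run%02d", i), c(0L, 4L, 8L),
             c("reference", "target", "target"), c(a, 250, 250))
      })
      list(design = d, n_proteins = 150L)
    },
    bsa17_2_1 = list(
      design = grid(runs(3), c(0L, 4L, 8L), c("target", "target", "reference"),
                    2500 * c(17, 2, 1)),
      n_proteins = 120L, precursors_per_protein = c(4L, 7L),
      interference_fraction = 0),
    fiveplex_1_2_4_2_1 = list(
      design = grid(runs(3), c(0L, 2L, 4L, 6L, 8L), rep("target", 5),
                    50000 * c(1, 2, 4, 2, 1)),
      n_proteins = 330L, protease = "lysn", interference_fraction = 0),
    mixed_species = list(
      design = grid(runs(3), c(0L, 4L, 8L), rep("target", 3),
                    rep(1e5, 3)),
      n_proteins = 300L,
      species_fractions = list(human = 0.5, yeast = 0.25, ecoli = 0.25),
      species_ratios = list(human = c(1, 1, 1), yeast = c(1, 2, 4),
                            ecoli = c(4, 2, 1)),
      interference_fraction = 0)
  )
  args$seed <- seed
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(simulation_config, args)
}

#' Write a simulated experiment to disk
#'
#' @param sim An `mdia_sim` from [simulate_report()].
#' @param dir Output directory (created if needed); writes `report.tsv`,
#'   `design.tsv` and `ground_truth.tsv` (per-protein, per-channel true
#'   relative abundances).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report(sim$report, file.path(dir, "report.tsv"))
  write_design(sim$design, file.path(dir, "design.tsv"))
  cfg <- sim$truth$config
  gt <- tidyr::expand_grid(sim$truth$proteins[c("protein_group", "species",
                                                "abundance")],
                           cfg$design[c("run", "channel", "amount_pg")])
  mult <- if (is.null(cfg$species_ratios)) 1 else {
    chs <- sort(unique(cfg$design$channel))
    m <- do.call(rbind, cfg$species_ratios)
    colnames(m) <- as.character(chs)
    m[cbind(match(gt$species, rownames(m)),
            match(as.character(gt$channel), colnames(m)))]
  }
  gt$true_abundance <- gt$abundance * (gt$amount_pg / cfg$single_cell_pg) * mult
  readr::write_tsv(gt, file.path(dir, "ground_truth.tsv"), progress = FALSE)
  invisible(dir)
}
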