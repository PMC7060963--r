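#' Run configuration for end-to-end pipelines
#'
#' A single configuration object drives both arms; all randomness flows
#' from the one top-level seed (per-group and per-cell sub-seeds are
#' derived deterministically from it).
#'
#' @param arm `"imaging"`, `"transcriptomics"` or `"both"`.
#' @param groups Imaging-arm preset names (see [ca_preset()]).
#' @param n_cells Named integer vector of cells per group; `NULL` uses each
#'   preset's default (181 WT / 183 KO / 180 treated).
#' @param acq An [acquisition_params()] object.
#' @param pacing_hz Stimulation frequency (Hz).
#' @param seed Top-level non-negative integer seed.
#' @param lfc_min,q_max Transcriptomics thresholds.
#' @param concordance A [concordance_preset()]; `NULL` uses the default.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param noise Imaging photon noise on (default) or off.
#' @return A list of class `run_config`.
#' @export
run_config <- function(arm = c("both", "imaging", "transcriptomics"),
                       groups = c("WT", "KO", "WT_HELHO", "KO_HELHO"),
                       n_cells = NULL, acq = acquisition_params(),
                       pacing_hz = 0.25, seed = 1, lfc_min = 1,
                       q_max = 0.05, concordance = NULL, out_dir = NULL,
                       noise = TRUE) {
  arm <- match.arg(arm)
  if (seed < 0 || seed != round(seed)) stop("seed must be a non-negative integer")
  structure(list(arm = arm, groups = groups, n_cells = n_cells, acq = acq,
                 pacing_hz = pacing_hz, seed = as.integer(seed),
                 lfc_min = lfc_min, q_max = q_max,
                 concordance = concordance, out_dir = out_dir,
                 noise = noise),
            class = "run_config")
}

# Deterministic per-group sub-seed (double arithmetic; avoids overflow).
.group_seed <- function(seed, group_index)
  as.integer((as.numeric(seed) * 100 + group_index) %% 2147483647)

.write_manifest <- function(manifest, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, name),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Measure a whole simulated cell group, one cell at a time
#'
#' Generates each cell's recording with the same deterministic per-cell
#' seed path as [gen_cell_population()], runs [analyze_recording()], and
#' discards the raw array before moving on, so population-scale runs stay
#' in modest memory.
#'
#' @param preset A [population_preset()].
#' @param n_cells Cells to simulate (default: the preset's default).
#' @param acq An [acquisition_params()].
#' @param seed Group-level seed.
#' @param pacing_hz Stimulation frequency.
#' @param noise Photon noise on/off.
#' @return A list: `cells` (per-cell summary data frame with `group`,
#'   truth values suffixed `_true`), `n_excluded_epochs`,
#'   `n_excluded_cells`.
#' @export
measure_group <- function(preset, n_cells = preset$default_n_cells,
                          acq = acquisition_params(), seed = 1,
                          pacing_hz = preset$mean_params$pacing_hz,
                          noise = TRUE) {
  truth <- gen_cell_params(preset, n_cells, seed)
  rows <- vector("list", nrow(truth))
  excluded_epochs <- 0L
  for (i in seq_len(nrow(truth))) {
    cp <- transient_params(truth$amplitude_peak[i], truth$rise_time_ms[i],
                           truth$decay50_ms[i],
                           baseline_f0 = preset$mean_params$baseline_f0,
                           pacing_hz = pacing_hz)
    rec <- gen_linescan(cp, acq, seed = .cell_seed(seed, i), noise = noise)
    res <- analyze_recording(rec, pacing_hz = pacing_hz,
                             cell_id = truth$cell_id[i],
                             batch_id = truth$diff_batch[i])
    excluded_epochs <- excluded_epochs + res$n_excluded
    rows[[i]] <- res$summary
  }
  ok <- vapply(rows, is.data.frame, logical(1))
  cells <- do.call(rbind, rows[ok])
  cells$group <- preset$group_label
  cells$amplitude_true <- truth$amplitude_peak[ok]
  cells$rise_time_ms_true <- truth$rise_time_ms[ok]
  cells$decay50_ms_true <- truth$decay50_ms[ok]
  list(cells = cells, n_excluded_epochs = excluded_epochs,
       n_excluded_cells = sum(!ok))
}

#' Run the imaging arm end to end
#'
#' For every configured group: simulate the preset population, run the
#' full single-cell chain (extract, smooth, baseline, normalize, segment,
#' measure, summarize), then compute group statistics and the rescue
#' assessment. Deterministic for a fixed seed. If `out_dir` is set,
#' writes `cells.csv`, `stats.csv` and `imaging_manifest.json` (inputs,
#' parameters and per-stage exclusion counts).
#'
#' @param config A [run_config()].
#' @return A list: `cells` (per-cell summaries across groups),
#'   `stats` (a [compare_groups()] result, when >= 2 groups), `manifest`.
#' @export
run_imaging_arm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  all_cells <- list()
  exclusions <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[gi]
    preset <- ca_preset(g)
    n <- if (!is.null(config$n_cells)) config$n_cells[[g]] else preset$default_n_cells
    res <- measure_group(preset, n_cells = n, acq = config$acq,
                         seed = .group_seed(config$seed, gi),
                         pacing_hz = config$pacing_hz, noise = config$noise)
    all_cells[[g]] <- res$cells
    exclusions[[g]] <- list(epochs = res$n_excluded_epochs,
                            cells = res$n_excluded_cells)
  }
  cells <- do.call(rbind, all_cells)
  rownames(cells) <- NULL
  stats <- NULL
  if (length(config$groups) >= 2) {
    pairs_present <- Filter(function(p) all(p %in% config$groups),
                            default_comparison_plan()$pairs)
    plan <- default_comparison_plan()
    plan$pairs <- pairs_present
    if (!all(unlist(plan$rescue) %in% config$groups)) plan$rescue <- NULL
    stats <- compare_groups(cells, plan)
  }
  manifest <- list(arm = "imaging", seed = config$seed,
                   groups = config$groups,
                   n_cells = vapply(all_cells, nrow, integer(1)),
                   epochs_per_cell_target = floor(
                     config$acq$n_lines / config$acq$line_rate_hz *
                       config$pacing_hz),
                   acquisition = unclass(config$acq),
                   pacing_hz = config$pacing_hz,
                   smoothing = list(order = 6, neighbors = 10),
                   exclusions = exclusions,
                   package_version = as.character(utils::packageVersion("cardiotransit")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells, file.path(config$out_dir, "cells.csv"),
                     row.names = FALSE)
    if (!is.null(stats))
      utils::write.csv(stats$comparisons,
                       file.path(config$out_dir, "stats.csv"),
                       row.names = FALSE)
    .write_manifest(manifest, config$out_dir, "imaging_manifest.json")
  }
  list(cells = cells, stats = stats, manifest = manifest)
}

#' Run the transcriptomics arm end to end
#'
#' Generates paired human/mouse NB counts from the concordance preset,
#' runs the per-species differential-expression chain for both stage
#' contrasts, classifies stage profiles at the configured thresholds, and
#' extracts the conserved set. If `out_dir` is set, writes the four DE
#' tables, `conserved_set.tsv`, `heatmap.tsv` and
#' `transcriptomics_manifest.json`.
#'
#' @param config A [run_config()].
#' @return A list: `tables` (from [gen_de_tables()]), `paired`,
#'   `conserved` (a `conserved_gene_set`), `manifest`.
#' @export
run_transcriptomics_arm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  preset <- if (is.null(config$concordance)) concordance_preset()
            else config$concordance
  tabs <- gen_de_tables(preset, seed = config$seed)
  ph <- species_profiles(tabs$human$ch, tabs$human$hf,
                         config$lfc_min, config$q_max)
  pm <- species_profiles(tabs$mouse$ch, tabs$mouse$hf,
                         config$lfc_min, config$q_max)
  paired <- join_orthologs(ph, pm, tabs$ortholog_map)
  conserved <- conserved_set(paired)
  deg_counts <- list(
    human_ch = nrow(filter_degs(tabs$human$ch, config$lfc_min, config$q_max)),
    human_hf = nrow(filter_degs(tabs$human$hf, config$lfc_min, config$q_max)),
    mouse_ch = nrow(filter_degs(tabs$mouse$ch, config$lfc_min, config$q_max)),
    mouse_hf = nrow(filter_degs(tabs$mouse$hf, config$lfc_min, config$q_max)))
  manifest <- list(arm = "transcriptomics", seed = config$seed,
                   n_genes = preset$human$n_genes,
                   n_planted = preset$n_planted,
                   thresholds = list(lfc_min = config$lfc_min,
                                     q_max = config$q_max),
                   deg_counts = deg_counts,
                   n_conserved = nrow(conserved$entries),
                   package_version = as.character(utils::packageVersion("cardiotransit")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_de_table(tabs$human$ch, file.path(config$out_dir, "human_CH_vs_NF.tsv"))
    write_de_table(tabs$human$hf, file.path(config$out_dir, "human_mHF_vs_NF.tsv"))
    write_de_table(tabs$mouse$ch, file.path(config$out_dir, "mouse_1wTAC_vs_sham.tsv"))
    write_de_table(tabs$mouse$hf, file.path(config$out_dir, "mouse_8wTAC_vs_sham.tsv"))
    utils::write.table(conserved$entries,
                       file.path(config$out_dir, "conserved_set.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (nrow(conserved$entries) > 0)
      export_heatmap_matrix(conserved,
                            file.path(config$out_dir, "heatmap.tsv"))
    .write_manifest(manifest, config$out_dir, "transcriptomics_manifest.json")
  }
  list(tables = tabs, paired = paired, conserved = conserved,
       manifest = manifest)
}
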