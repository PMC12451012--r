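#' Build a pipeline run configuration
#'
#' Bundles inputs and stage parameters for [run_pipeline()]. Either `paths`
#' (on-disk inputs) or `simulation` (a [simulation_config()]) must be given.
#' Stage parameter defaults are the package's canonical values: expression
#' floor 0.2, clip 3, window 100 genes, margin 0.2, Gini cutoff 0.25,
#' adjusted-p cutoff 0.05.
#'
#' @param reference_groups group names forming the CNV reference.
#' @param target_group group whose specific ligands are ranked.
#' @param simulation optional [simulation_config()]; the pipeline generates
#'   its input dataset from it.
#' @param paths optional named list with `expression` (directory or file),
#'   `expression_format`, `positions`, `labels`, and optionally `signatures`
#'   (GMT file).
#' @param ligand_universe character vector of candidate ligand ids; defaults
#'   to the simulation config's universe when simulating.
#' @param signatures optional `signature_set` (overrides `paths$signatures`).
#' @param floor,clip,window,margin CNV parameters.
#' @param gini_cutoff,p_cutoff specificity parameters.
#' @param seed integer seed for the simulation stage.
#' @param outdir output directory for [run_pipeline()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(reference_groups,
                       target_group,
                       simulation = NULL,
                       paths = NULL,
                       ligand_universe = NULL,
                       signatures = NULL,
                       floor = 0.2, clip = 3, window = 100L, margin = 0.2,
                       gini_cutoff = 0.25, p_cutoff = 0.05,
                       seed = 1L,
                       outdir = tempfile("nichescan_run_")) {
  assert_that(!is.null(simulation) || !is.null(paths),
              "either a simulation config or input paths must be given")
  assert_that(!missing(reference_groups) && length(reference_groups) > 0,
              "reference_groups must be given")
  assert_that(!missing(target_group) && length(target_group) == 1,
              "target_group must be a single group name")
  if (!is.null(simulation)) {
    validate_simulation_config(simulation)
    simulation$seed <- as.integer(seed)
    if (is.null(ligand_universe)) ligand_universe <- simulation$ligand_universe
  }
  structure(
    list(reference_groups = reference_groups,
         target_group = target_group,
         simulation = simulation,
         paths = paths,
         ligand_universe = ligand_universe,
         signatures = signatures,
         floor = floor, clip = clip, window = as.integer(window),
         margin = margin,
         gini_cutoff = gini_cutoff, p_cutoff = p_cutoff,
         seed = as.integer(seed),
         outdir = outdir),
    class = "run_config")
}

#' Run the full niche-characterization pipeline
#'
#' Orchestrates simulate (or load) -> normalize -> CNV estimation -> ligand
#' specificity -> signature scoring and ligand-signature correlation, writing
#' every stage's tables plus a machine-readable `report.json` and a manifest
#' under `cfg$outdir`. Identical config and seed produce an identical report.
#'
#' @param cfg a [run_config()].
#' @return A list of class `run_report` (also serialized as
#'   `report.json`): stage summaries, parameters, seed, output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(cfg$outdir, "FAILED"))
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- inputs -------------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    dataset <- stage("simulate", generate_dataset(cfg$simulation))
    counts <- dataset$expression
    positions <- dataset$positions
    labels <- dataset$labels
    ground_truth <- dataset$ground_truth
  } else {
    counts <- stage("load", read_expression(
      cfg$paths$expression, format = cfg$paths$expression_format %||% "mtx_triplet"))
    positions <- stage("load", read_gene_positions(cfg$paths$positions))
    labels <- stage("load", read_group_labels(cfg$paths$labels))
    ground_truth <- NULL
  }
  assert_that(all(cfg$reference_groups %in% labels$group_order),
              "reference_groups not present in labels")
  assert_that(cfg$target_group %in% labels$group_order,
              "target_group not present in labels")

  signatures <- cfg$signatures
  if (is.null(signatures) && !is.null(cfg$paths$signatures)) {
    signatures <- stage("load", read_signatures(cfg$paths$signatures))
  }
  if (is.null(signatures) && !is.null(ground_truth) &&
      length(ground_truth$signature_plants) > 0) {
    signatures <- stats::setNames(
      lapply(ground_truth$signature_plants, `[[`, "signature_genes"),
      vapply(ground_truth$signature_plants, `[[`, character(1), "name"))
  }

  # ---- normalize ----------------------------------------------------------
  norm <- stage("normalize", normalize_cp10k_log(counts))
  message(sprintf("[normalize] %d genes x %d cells", nrow(norm$values),
                  ncol(norm$values)))

  # ---- CNV ----------------------------------------------------------------
  cnv <- stage("cnv", run_cnv(norm, positions, labels,
                              reference_groups = cfg$reference_groups,
                              floor = cfg$floor, clip = cfg$clip,
                              window = cfg$window, margin = cfg$margin))
  write_cnv_result(cnv, file.path(cfg$outdir, "cnv"))
  cnv_summary <- summarize_group_cnv(cnv, labels)
  data.table::fwrite(cnv_summary, file.path(cfg$outdir, "cnv_group_summary.tsv"),
                     sep = "\t")
  message(sprintf("[cnv] %d windows retained of %d genes",
                  nrow(cnv$profile$cnv_o), nrow(norm$values)))

  # ---- ligand specificity -------------------------------------------------
  specificity <- NULL
  if (!is.null(cfg$ligand_universe)) {
    specificity <- stage("ligands", rank_specific_ligands(
      norm, labels, cfg$target_group, cfg$ligand_universe,
      gini_cutoff = cfg$gini_cutoff, p_cutoff = cfg$p_cutoff))
    data.table::fwrite(as.data.frame(specificity),
                       file.path(cfg$outdir, "specific_ligands.tsv"), sep = "\t")
    data.table::fwrite(attr(specificity, "scatter"),
                       file.path(cfg$outdir, "ligand_scatter.tsv"), sep = "\t")
    message(sprintf("[ligands] %d of %d candidates pass at gini > %.2f",
                    sum(specificity$passes), length(cfg$ligand_universe),
                    cfg$gini_cutoff))
  }

  # ---- signature correlation ----------------------------------------------
  correlations <- NULL
  if (!is.null(signatures)) {
    score_mat <- stage("signatures", score_signature(norm, signatures))
    data.table::fwrite(
      data.frame(cell_id = rownames(score_mat), score_mat, check.names = FALSE),
      file.path(cfg$outdir, "signature_scores.tsv"), sep = "\t")
    drivers <- if (!is.null(ground_truth) &&
                   length(ground_truth$signature_plants) > 0) {
      unique(vapply(ground_truth$signature_plants, `[[`, character(1),
                    "driver_ligand"))
    } else if (!is.null(specificity) && nrow(specificity) > 0) {
      utils::head(specificity$gene_id[specificity$passes], 1)
    } else character(0)
    correlations <- do.call(rbind, lapply(drivers, function(lg) {
      cbind(ligand = lg,
            stage("signatures",
                  ligand_signature_correlation(norm, score_mat, lg, labels,
                                               region = cfg$target_group)))
    }))
    if (!is.null(correlations)) {
      data.table::fwrite(correlations,
                         file.path(cfg$outdir, "ligand_signature_correlation.tsv"),
                         sep = "\t")
    }
  }

  # ---- report -------------------------------------------------------------
  params <- cfg[c("reference_groups", "target_group", "floor", "clip",
                  "window", "margin", "gini_cutoff", "p_cutoff", "seed")]
  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("nichescan")),
    parameters = params,
    n_genes = nrow(counts$values),
    n_cells = ncol(counts$values),
    n_windows = nrow(cnv$profile$cnv_o),
    cnv_group_summary = cnv_summary,
    passing_ligands = if (!is.null(specificity))
      specificity$gene_id[specificity$passes] else NULL,
    ligand_signature_correlation = correlations,
    outputs = list(dir = cfg$outdir))
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(parameters = params,
                   simulated = !is.null(cfg$simulation),
                   seed = cfg$seed,
                   input_checksums = if (is.null(cfg$paths)) NULL else
                     lapply(cfg$paths[c("expression", "positions", "labels")],
                            function(p) {
                              # expression may be a triplet directory
                              if (is.character(p) && dir.exists(p)) {
                                p <- file.path(p, "matrix.mtx")
                              }
                              if (is.character(p) && file.exists(p)) {
                                unname(tools::md5sum(p))
                              } else NULL
                            }))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf("[done] %.1f s, outputs in %s",
                  proc.time()[["elapsed"]] - t0, cfg$outdir))
  structure(report, class = c("run_report", "list"))
}
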