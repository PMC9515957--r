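.CONFIG_KEYS <- c("samples", "annotation_db", "control_library",
                  "sc_contigs", "sc_counts", "spatial_cells", "border",
                  "mask", "outdir", "seed", "log_level",
                  "expanded_threshold", "similarity_denominator",
                  "min_count", "public_min_patients", "public_min_cells",
                  "min_support", "motif_k", "motif_min_clonotypes",
                  "motif_min_fold", "hamming_radius", "min_pct",
                  "min_logfc", "profile_range_um", "bin_width_um",
                  "infiltration_epsilon", "tumor_side")

.default_config <- function() {
  list(expanded_threshold = 0.01, similarity_denominator = "union",
       min_count = 1, public_min_patients = 10, public_min_cells = 11,
       min_support = 2, motif_k = c(3, 4), motif_min_clonotypes = 3,
       motif_min_fold = 10, hamming_radius = 1, min_pct = 0.25,
       min_logfc = 0.25, profile_range_um = 500, bin_width_um = 50,
       infiltration_epsilon = 0.1, tumor_side = "left",
       seed = 1, log_level = "info")
}

#' Validate a pipeline run configuration
#'
#' Merges user keys over the defaults and rejects unknown keys.
#'
#' @param config named list, or path to a YAML file
#' @return validated config list
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(.default_config(), config)
  out
}

#' Run the integrated pipeline
#'
#' Executes the analysis stages in dependency order — repertoire
#' diversity, cross-tissue clonotype tracking, database/control-library
#' annotation, specificity grouping, single-cell integration, spatial
#' profiling — skipping stages whose inputs are absent from the config,
#' and writes the stage tables plus an aggregate `summary.json` to the
#' output directory. A rerun with the same config and seed produces an
#' identical summary.
#'
#' @param config named list or YAML path; see [validateRunConfig()].
#'   Input keys: `samples` (sample-sheet TSV), `annotation_db`,
#'   `control_library`, `sc_contigs` + `sc_counts` (TSVs), `spatial_cells`
#'   + `border` (+ optional `mask`).
#' @param outdir output directory (overrides config)
#' @return the summary list, invisibly; side effect: tables and
#'   `summary.json` under `outdir`
#' @export
runPipeline <- function(config, outdir = NULL) {
  cfg <- validateRunConfig(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$outdir)) stop("config error: no output directory")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  summary <- list(seed = cfg$seed, stages = character())
  wtab <- function(x, name) utils::write.table(
    x, file.path(cfg$outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  reps <- NULL
  if (!is.null(cfg$samples)) {
    reps <- tryCatch(readSampleSheet(cfg$samples),
                     error = function(e) stop("stage repertoire: ",
                                              conditionMessage(e)))
    reps <- lapply(reps, filterProductive)
    div <- diversityTable(reps)
    wtab(div, "diversity.tsv")
    summary$stages <- c(summary$stages, "repertoire")
    summary$repertoire <- list(
      n_samples = length(reps),
      total_unique = sum(div$unique_count),
      clonality = stats::setNames(as.list(div$clonality), div$sample_id))

    # tracking per patient
    pats <- unique(vapply(reps, patientId, character(1)))
    tracked_all <- list()
    for (p in pats) {
      rp <- reps[vapply(reps, patientId, character(1)) == p]
      tr <- trackClonotypes(rp, min_count = cfg$min_count,
                            expanded_threshold = cfg$expanded_threshold)
      tr$patient_id <- p
      tracked_all[[p]] <- tr
    }
    tracked <- do.call(rbind, lapply(tracked_all, function(z)
      z[, c("patient_id", "key", "pattern", "expanded_in_tumor")]))
    wtab(tracked, "tracked_clonotypes.tsv")
    pc <- table(tracked$pattern)
    summary$stages <- c(summary$stages, "tracking")
    summary$tracking <- list(
      pattern_counts = as.list(pc),
      expanded_in_tumor = sum(tracked$expanded_in_tumor))

    if (!is.null(cfg$annotation_db)) {
      db <- readAnnotationDb(cfg$annotation_db)
      ann <- lapply(reps, matchDatabase, db = db)
      asum <- do.call(rbind, lapply(names(ann), function(s)
        cbind(sample_id = s, ann[[s]]$summary)))
      wtab(asum, "annotation_summary.tsv")
      summary$stages <- c(summary$stages, "annotation")
      summary$annotation <- list(
        mean_annotated_fraction = mean(asum$annotated_unique_fraction))
    }
    if (!is.null(cfg$control_library)) {
      lib <- utils::read.delim(cfg$control_library, stringsAsFactors = FALSE)
      tum <- reps[vapply(reps, tissueOf, character(1)) == "TUMOR"]
      exp_keys <- unique(unlist(lapply(tum, function(r) {
        rec <- clonotypes(r)
        rec$cdr3_aa[flagExpanded(rec$frequency, cfg$expanded_threshold)]
      })))
      if (length(exp_keys)) {
        scr <- screenControlLibrary(exp_keys, lib)
        wtab(scr, "control_screen.tsv")
        summary$stages <- c(summary$stages, "control_screen")
        summary$control_screen <- list(
          expanded_clonotypes = nrow(scr),
          patient_unique_fraction = mean(scr$patient_unique))
      }
    }
    # specificity groups on tumor repertoires
    tum <- reps[vapply(reps, tissueOf, character(1)) == "TUMOR"]
    if (length(tum)) {
      cdr3 <- unique(unlist(lapply(tum, function(r)
        clonotypes(r)$cdr3_aa)))
      motifs <- mineMotifs(cdr3, k_values = cfg$motif_k,
                           min_clonotypes = cfg$motif_min_clonotypes,
                           min_fold = cfg$motif_min_fold)
      groups <- buildGroups(cdr3, motifs, hamming_radius = cfg$hamming_radius)
      wtab(groups, "specificity_groups.tsv")
      summary$stages <- c(summary$stages, "specificity")
      summary$specificity <- list(
        n_groups = length(unique(groups$group_id)),
        mean_group_size = mean(table(groups$group_id)))
    }
  }

  if (!is.null(cfg$sc_contigs) && !is.null(cfg$sc_counts)) {
    contigs <- utils::read.delim(cfg$sc_contigs, stringsAsFactors = FALSE)
    counts <- as.matrix(utils::read.delim(cfg$sc_counts, row.names = 1,
                                          check.names = FALSE))
    cells <- pairChains(contigs)
    fd <- filterDoublets(cells)
    pairs <- pairedClonotypes(fd$cells)
    dens <- clonotypeDensity(pairs)
    lin <- assignLineage(counts)
    cells2 <- fd$cells
    cells2$lineage <- lin[match(cells2$cell_id, colnames(counts))]
    dp <- dpClonotypeAnalysis(cells2)
    wtab(pairs, "paired_clonotypes.tsv")
    wtab(dens, "clonotype_density.tsv")
    summary$stages <- c(summary$stages, "single_cell")
    summary$single_cell <- list(
      cells = nrow(cells), paired = sum(cells$paired),
      doublets_removed = fd$removed,
      dp_fraction = mean(cells2$lineage == "DP", na.rm = TRUE),
      size_class_density = stats::setNames(as.list(dens$density),
                                           as.character(dens$size_class)))
  }

  if (!is.null(cfg$spatial_cells) && !is.null(cfg$border)) {
    sp <- utils::read.csv(cfg$spatial_cells)
    border <- readBorder(cfg$border)
    mask <- if (!is.null(cfg$mask)) {
      if (is.character(cfg$mask)) readBorder(cfg$mask) else cfg$mask
    } else c(min(sp$x), max(sp$x), min(sp$y), max(sp$y))
    calls <- list()
    for (cls in intersect(c("CD8", "CD4"), names(sp))) {
      prof <- densityProfile(sp, border, mask,
                             class_filter = as.logical(sp$CD3) &
                               as.logical(sp[[cls]]),
                             bin_width = cfg$bin_width_um,
                             range_um = cfg$profile_range_um,
                             tumor_side = cfg$tumor_side)
      wtab(cbind(class = cls, prof), paste0("profile_", cls, ".tsv"))
      cl <- classifyInfiltration(prof, epsilon = cfg$infiltration_epsilon)
      calls[[cls]] <- cl$call
    }
    k8 <- ki67Fraction(sp, "CD8"); k4 <- ki67Fraction(sp, "CD4")
    summary$stages <- c(summary$stages, "spatial")
    summary$spatial <- list(infiltration = calls,
                            ki67_cd8 = k8$fraction, ki67_cd4 = k4$fraction)
  }

  if (length(summary$stages) == 0)
    warning("no inputs configured: nothing to report")
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(cfg$outdir, "summary.json"))
  invisible(summary)
}

#' Simulate a full synthetic study and run the pipeline over it
#'
#' Convenience wrapper: generates the bulk cohort, single-cell tables and
#' spatial table under `dir/input`, writes a run config, and executes
#' [runPipeline()] into `dir/results`.
#'
#' @param dir working directory
#' @param config a [synthConfig()]
#' @return the pipeline summary, invisibly
#' @export
simulateAndRun <- function(dir, config = synthConfig()) {
  ind <- file.path(dir, "input")
  dir.create(ind, showWarnings = FALSE, recursive = TRUE)
  cohort <- generateRepertoireSet(config, dir = ind)
  sc <- generateCells(config, cohort)
  utils::write.table(sc$contigs, file.path(ind, "contigs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(sc$counts), sc$counts,
                                check.names = FALSE),
                     file.path(ind, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # first column is the gene id when read back with row.names = 1
  sp <- generateSpatial(config)
  utils::write.csv(sp$cells, file.path(ind, "spatial_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(sp$border, file.path(ind, "border.csv"), row.names = FALSE)
  run_cfg <- list(samples = file.path(ind, "samples.tsv"),
                  control_library = file.path(ind, "control_library.tsv"),
                  sc_contigs = file.path(ind, "contigs.tsv"),
                  sc_counts = file.path(ind, "counts.tsv"),
                  spatial_cells = file.path(ind, "spatial_cells.csv"),
                  border = file.path(ind, "border.csv"),
                  mask = config$spatial_window,
                  seed = config$seed,
                  outdir = file.path(dir, "results"))
  runPipeline(run_cfg)
}
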