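# ------------------------------------------------------- configuration

.defaultRunConfig <- function() {
  list(
    seed = 1L,
    output_dir = "chromaplex_run",
    overwrite = FALSE,
    optics = NULL,            # path to an optics YAML; NULL = shipped
    simulate = list(n_cells = 500L, width = 640L, height = 640L,
                    phenotype_mix = list(tumor = 0.7, immune = 0.3),
                    autofluorescence = 25,
                    max_shift_px = 4, max_rotation_deg = 0.5),
    noise = list(read_noise_sd = 6, dark_offset = 100, shot_noise = TRUE,
                 quench_residual = 0.02),
    analyze = list(input_dir = NULL, backend = "watershed",
                   normalize_offset = 1, rules = "immune_tumor",
                   write_images = FALSE))
}

#' Read and validate a run configuration
#'
#' A single YAML (or list) drives simulation and analysis; unknown keys
#' are rejected and defaults fill in the rest. The resolved
#' configuration is written next to every run's outputs.
#'
#' @param config path to a YAML file, or a list
#' @return validated configuration list
#' @export
readRunConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- .defaultRunConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sect in c("simulate", "noise", "analyze")) {
    bad <- setdiff(names(config[[sect]]), names(def[[sect]]))
    if (length(bad))
      stop("unknown key(s) in '", sect, "': ", paste(bad, collapse = ", "))
  }
  cfg <- modifyList(def, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.loadOptics <- function(cfg) {
  if (is.null(cfg$optics)) return(defaultOpticalConfig())
  if (!file.exists(cfg$optics))
    stop("optics configuration file not found: ", cfg$optics)
  readOpticalConfig(cfg$optics)
}

.noiseFromConfig <- function(cfg) {
  noiseModel(readNoiseSd = cfg$noise$read_noise_sd,
             darkOffset = cfg$noise$dark_offset,
             shotNoise = isTRUE(cfg$noise$shot_noise),
             quenchResidual = cfg$noise$quench_residual,
             seed = cfg$seed)
}

.writePanelYAML <- function(panel, path) {
  yaml::write_yaml(list(
    cycles = lapply(panel@cycles, as.list),
    igg_controls = list(cycle = panel@iggControls$cycle,
                        fluorochrome = panel@iggControls$fluorochrome),
    nuclear_markers = panel@nuclearMarkers), path)
  invisible(path)
}

.readPanelYAML <- function(path) {
  p <- yaml::read_yaml(path)
  cyclePanel(lapply(p$cycles, function(cy)
    setNames(as.character(unlist(cy)), names(cy))),
    data.frame(cycle = as.integer(unlist(p$igg_controls$cycle)),
               fluorochrome = as.character(
                 unlist(p$igg_controls$fluorochrome))),
    as.character(unlist(p$nuclear_markers)))
}

# -------------------------------------------------------------- simulate

#' Simulate a full cyclic acquisition run to disk
#'
#' Generates a seeded scene, renders the autofluorescence reference
#' (cycle 0) and every panel cycle through the forward optical model
#' (with per-cycle stage transforms), and writes the stacks, the truth
#' table, the fingerprint matrix, the panel and the resolved
#' configuration into `output_dir`. Fully deterministic given the
#' seed.
#'
#' @param config run configuration ([readRunConfig()])
#' @param panel a `CyclePanel` (default [defaultPanel()])
#' @return invisibly, a list with the output paths, the
#'   [Scene-class] and the transforms used
#' @export
runSimulate <- function(config = list(), panel = defaultPanel()) {
  cfg <- readRunConfig(config)
  dir <- cfg$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.exists(file.path(dir, "cycle00.json")) && !isTRUE(cfg$overwrite))
    stop("output directory ", dir,
         " already holds a run (set overwrite: true)")
  optics <- .loadOptics(cfg)
  A <- buildFingerprintMatrix(optics)
  noise <- .noiseFromConfig(cfg)
  sim <- cfg$simulate
  scene <- generateScene(
    nCells = sim$n_cells,
    phenotypeMix = unlist(sim$phenotype_mix),
    width = sim$width, height = sim$height,
    markers = panelMarkers(panel),
    autofluorescence = sim$autofluorescence, seed = cfg$seed)
  nCycles <- length(panel@cycles)
  set.seed(cfg$seed + 271L)
  transforms <- c(list(rigidTransform()), lapply(seq_len(nCycles - 1L),
    function(i) rigidTransform(
      runif(1, -1, 1) * sim$max_rotation_deg * pi / 180,
      runif(2, -1, 1) * sim$max_shift_px)))
  paths <- character()
  for (cyc in 0:nCycles) {
    tf <- transforms[[max(cyc, 1L)]]   # cycle 0 shares cycle 1's mount
    stk <- renderAcquisition(scene, panel, cyc, A, noise, transform = tf)
    paths[length(paths) + 1L] <-
      writeAcquisitionStack(stk, dir, overwrite = isTRUE(cfg$overwrite))
  }
  writeFingerprintCSV(A, file.path(dir, "fingerprint.csv"))
  write.csv(groundTruthTable(scene), file.path(dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  .writePanelYAML(panel, file.path(dir, "panel.yaml"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(list(dir = dir, sidecars = paths, scene = scene,
                 transforms = transforms, fingerprint = A))
}

# --------------------------------------------------------------- analyze

#' Analyze a cyclic acquisition run end to end
#'
#' The full pipeline, in fixed order: dark subtraction, rigid
#' alignment of every cycle to cycle 1 on the DAPI composite,
#' quench/autofluorescence subtraction, pixel-wise bounded
#' least-squares unmixing, segmentation on the DAPI
#' maximum-intensity projection, QC filtering, per-cell
#' quantification, percentile normalization, IgG positivity calling
#' and rule-based phenotyping. Writes `cells.csv`, `qc.json` and a
#' provenance log into the run directory.
#'
#' @param config run configuration; `analyze$input_dir` must point at a
#'   directory written by [runSimulate()] (or with the same layout)
#' @param outputDir where results are written (default: the input
#'   directory)
#' @return invisibly, a list with the cell `table`, `masks`, exclusion
#'   `report`, per-cycle `transforms` and the `qc` log
#' @export
runAnalyze <- function(config = list(), outputDir = NULL) {
  cfg <- readRunConfig(config)
  dir <- cfg$analyze$input_dir
  if (is.null(dir)) stop("analyze: input_dir is required")
  if (is.null(outputDir)) outputDir <- dir
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  sidecars <- sort(list.files(dir, pattern = "^cycle[0-9]+\\.json$",
                              full.names = TRUE))
  if (!length(sidecars)) stop("no cycle sidecars found in ", dir)
  stacks <- lapply(sidecars, readAcquisitionStack)
  cycles <- vapply(stacks, function(s) s@cycleIndex, 0L)
  names(stacks) <- as.character(cycles)
  if (!"0" %in% names(stacks))
    stop("missing autofluorescence reference (cycle 0) in ", dir)
  A <- readFingerprintCSV(file.path(dir, "fingerprint.csv"))
  panel <- .readPanelYAML(file.path(dir, "panel.yaml"))
  nCycles <- length(panel@cycles)
  qc <- list(stages = list())

  # dark subtraction (noise floor estimated from the dark frames)
  readSd <- median(vapply(stacks, function(s) sd(s@dark), 0))
  clampTol <- 3 * readSd
  dk <- lapply(stacks, subtractDarkStack, clampTol = clampTol)

  # alignment to cycle 1 on the DAPI composite
  ref <- dapiComposite(dk[["1"]])
  transforms <- list("1" = rigidTransform())
  for (cyc in setdiff(seq_len(nCycles), 1L)) {
    tf <- estimateAlignment(dapiComposite(dk[[as.character(cyc)]]), ref)
    transforms[[as.character(cyc)]] <- tf
  }
  transforms[["0"]] <- transforms[["1"]]   # shares cycle 1's mount
  aligned <- lapply(names(dk), function(k)
    applyAlignment(dk[[k]], transforms[[k]]))
  names(aligned) <- names(dk)

  # quench subtraction and unmixing, cycle by cycle
  noiseFloor <- 2 * readSd
  corrected <- list()
  unmixed <- list()
  for (cyc in seq_len(nCycles)) {
    bg <- if (cyc == 1L) aligned[["0"]]
          else aligned[[as.character(cyc - 1L)]]
    if (is.null(bg))
      stop("missing predecessor stack for cycle ", cyc)
    cc <- quenchSubtract(aligned[[as.character(cyc)]], bg,
                         cycleIndex = cyc, clampTol = clampTol)
    corrected[[cyc]] <- cc
    unmixed[[cyc]] <- unmixImage(cc$planes, A, noiseFloor = noiseFloor)
    if (isTRUE(cfg$analyze$write_images))
      writeFluorImages(unmixed[[cyc]], file.path(outputDir, "images"),
                       prefix = sprintf("cycle%02d", cyc))
  }
  qc$stages$clampFraction <- lapply(corrected, function(cc)
    as.list(cc$provenance$clampFraction))

  # segmentation on the DAPI maximum-intensity projection
  dapiMip <- dapiMaxProjection(lapply(unmixed, function(u)
    u$abundances$DAPI))
  masks <- segmentCells(dapiMip, backend = cfg$analyze$backend)
  flt <- qcFilter(masks)
  qc$stages$exclusions <- setNames(as.list(flt$report$count),
                                   flt$report$reason)

  # quantification -> normalization -> positivity -> phenotype
  table <- quantifyCells(flt$masks, unmixed, panel)
  table <- normalizeCellTable(table, offset = cfg$analyze$normalize_offset)
  igg <- iggStats(table, panel)
  table <- callPositivity(table, igg, panel)
  rules <- switch(cfg$analyze$rules,
                  immune_tumor = immuneTumorRules(),
                  mosaic = mosaicRules(),
                  stop("unknown rule set: ", cfg$analyze$rules))
  table <- classifyPhenotypes(table, rules)

  qc$stages$transforms <- lapply(transforms, function(tf)
    list(rotation_rad = tf@rotation, translation_px = tf@translation))
  qc$stages$igg <- igg
  qc$stages$thresholds <- as.list(attr(table, "thresholds"))
  qc$nCells <- nrow(table)
  qc$noiseFloor <- noiseFloor
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  writeCellTable(table, file.path(outputDir, "cells.csv"))
  jsonlite::write_json(qc, file.path(outputDir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  # wall-clock timings are volatile by nature and live outside qc.json,
  # so analysis outputs are byte-deterministic given (config, seed)
  cat(sprintf("analyze %s: %.1f s\n", dir, elapsed),
      file = file.path(outputDir, "timings.log"), append = TRUE)
  qc$elapsedSec <- elapsed
  yaml::write_yaml(cfg, file.path(outputDir, "analyze_config.yaml"))
  invisible(list(table = table, masks = flt$masks, report = flt$report,
                 transforms = transforms, qc = qc, unmixed = unmixed,
                 dapiMip = dapiMip))
}

# ---------------------------------------------------- truth comparison

#' Match analyzed cells to simulator ground truth
#'
#' Nearest-centroid matching of segmented cells to truth cells within
#' `maxDist` pixels (one truth cell per segmented cell, closest first).
#'
#' @param table analyzed cell table
#' @param truth [groundTruthTable()] output (or `truth.csv`)
#' @param maxDist maximum centroid distance in px (default 10)
#' @return the table with `true_label` and `true_phenotype` columns
#'   (NA when unmatched)
#' @export
matchToTruth <- function(table, truth, maxDist = 10) {
  d2 <- outer(table$row, truth$row, "-")^2 +
    outer(table$col, truth$col, "-")^2
  table$true_label <- NA_integer_
  table$true_phenotype <- NA_character_
  ord <- order(apply(d2, 1L, min))
  taken <- logical(nrow(truth))
  for (i in ord) {
    j <- which.min(replace(d2[i, ], taken, Inf))
    if (length(j) && d2[i, j] <= maxDist^2 && !taken[j]) {
      taken[j] <- TRUE
      table$true_label[i] <- truth$label[j]
      table$true_phenotype[i] <- truth$phenotype[j]
    }
  }
  table
}

#' @describeIn matchToTruth fraction of matched cells whose called
#'   phenotype equals the truth phenotype
#' @export
phenotypeAccuracy <- function(table, truth, maxDist = 10) {
  m <- matchToTruth(table, truth, maxDist)
  ok <- !is.na(m$true_phenotype)
  if (!any(ok)) return(NA_real_)
  mean(m$phenotype[ok] == m$true_phenotype[ok])
}

# ----------------------------------------------------------------- cohort

#' Summarize marker positivity across a cohort of samples
#'
#' Per sample, the fraction of retained cells positive for each
#' marker, plus pooled phenotype counts; the cohort-level view of a
#' multi-sample study.
#'
#' @param tables list of cell tables or paths to `cells.csv` files
#' @param sampleNames names for the samples (defaults to list names or
#'   file names)
#' @return list with `positiveFractions` (data.frame sample x marker,
#'   long format), `phenotypeCounts` (sample x phenotype) and `nCells`
#' @export
runCohort <- function(tables, sampleNames = NULL) {
  if (!length(tables)) stop("need at least one cell table")
  if (is.character(tables)) {
    if (is.null(sampleNames))
      sampleNames <- sub("\\.csv$", "", basename(tables))
    tables <- lapply(tables, readCellTable)
  }
  if (is.null(sampleNames))
    sampleNames <- if (!is.null(names(tables))) names(tables)
                   else sprintf("sample%02d", seq_along(tables))
  keep <- vapply(tables, nrow, 0L) > 0L
  if (!all(keep)) {
    warning("excluding empty cell table(s): ",
            paste(sampleNames[!keep], collapse = ", "))
    tables <- tables[keep]; sampleNames <- sampleNames[keep]
  }
  if (!length(tables)) stop("all cell tables are empty")
  markerSets <- lapply(tables, function(tb)
    sort(sub("^pos\\.", "", grep("^pos\\.", names(tb), value = TRUE))))
  shared <- Reduce(intersect, markerSets)
  if (!length(shared))
    stop("cell tables share no positivity-called markers; marker sets: ",
         paste(vapply(markerSets, paste, "", collapse = "/"),
               collapse = " | "))
  frac <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    data.frame(sample = sampleNames[i], marker = shared,
               fraction_positive = vapply(shared, function(mk)
                 mean(tb[[paste0("pos.", mk)]]), 0),
               n_cells = nrow(tb), row.names = NULL)
  }))
  phen <- NULL
  if (all(vapply(tables, function(tb) "phenotype" %in% names(tb), NA))) {
    allPhen <- sort(unique(unlist(lapply(tables, `[[`, "phenotype"))))
    phen <- do.call(rbind, lapply(seq_along(tables), function(i) {
      counts <- table(factor(tables[[i]]$phenotype, levels = allPhen))
      cbind(data.frame(sample = sampleNames[i]),
            as.data.frame.matrix(t(as.matrix(counts))))
    }))
  }
  list(positiveFractions = frac, phenotypeCounts = phen,
       nCells = setNames(vapply(tables, nrow, 0L), sampleNames))
}

#' Plot cohort positivity fractions
#'
#' Box-plus-points summary of per-sample positive fractions per
#' marker; requires ggplot2.
#'
#' @param cohort result of [runCohort()]
#' @return a ggplot object
#' @export
plotCohort <- function(cohort) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotCohort requires the ggplot2 package")
  df <- cohort$positiveFractions
  ggplot2::ggplot(df, ggplot2::aes(x = marker, y = fraction_positive)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "fraction of cells positive") +
    ggplot2::theme_bw()
}
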