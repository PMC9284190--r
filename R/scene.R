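#' Cycle panel: cycle x fluorochrome -> marker assignment
#'
#' A panel maps, for each staining cycle, every fluorochrome to the
#' marker it reports. DAPI is the nuclear counterstain and must be
#' assigned in every cycle (it doubles as the spatial alignment map);
#' any other marker may appear at most once across the panel. IgG
#' isotype controls are designated by (cycle, fluorochrome) pairs and
#' define the null staining distribution per fluorochrome channel.
#'
#' @param cycles list, one named character vector per cycle
#'   (`fluorochrome = marker`)
#' @param iggControls data.frame with columns `cycle` and
#'   `fluorochrome`
#' @param nuclearMarkers markers quantified over the nucleus mask
#' @return a `CyclePanel`
#' @name cyclePanel
#' @exportClass CyclePanel
#' @export cyclePanel
#' @aliases CyclePanel-class
setClass("CyclePanel",
  representation(cycles = "list", iggControls = "data.frame",
                 nuclearMarkers = "character"))

setValidity("CyclePanel", function(object) {
  if (!length(object@cycles)) return("panel needs at least one cycle")
  hasDAPI <- vapply(object@cycles, function(cy) "DAPI" %in% names(cy),
                    NA)
  if (!all(hasDAPI))
    return("DAPI must be assigned in every cycle")
  mk <- unlist(lapply(object@cycles, function(cy) cy[names(cy) != "DAPI"]))
  if (anyDuplicated(mk))
    return(sprintf("marker assigned more than once: %s",
                   paste(unique(mk[duplicated(mk)]), collapse = ", ")))
  TRUE
})

cyclePanel <- function(cycles, iggControls = NULL,
                       nuclearMarkers = c("DAPI", "ER", "PR", "Ki67",
                                          "GATA3")) {
  if (is.null(iggControls))
    iggControls <- data.frame(cycle = integer(), fluorochrome = character())
  obj <- new("CyclePanel", cycles = cycles, iggControls = iggControls,
             nuclearMarkers = nuclearMarkers)
  validObject(obj)
  obj
}

#' @describeIn cyclePanel markers of the panel (DAPI first, IgG last)
#' @param panel a `CyclePanel`
#' @export
panelMarkers <- function(panel) {
  mk <- unique(unlist(lapply(panel@cycles, unname)))
  igg <- .iggMarkers(panel)
  c("DAPI", setdiff(mk, c("DAPI", igg)), igg)
}

.iggMarkers <- function(panel) {
  if (!nrow(panel@iggControls)) return(character())
  unname(vapply(seq_len(nrow(panel@iggControls)), function(i) {
    cy <- panel@cycles[[panel@iggControls$cycle[i]]]
    unname(cy[panel@iggControls$fluorochrome[i]])
  }, character(1)))
}

# marker -> fluorochrome channel lookup (first occurrence)
.markerChannel <- function(panel) {
  out <- character()
  for (cy in panel@cycles)
    for (fl in names(cy))
      if (!(cy[[fl]] %in% names(out))) out[[cy[[fl]]]] <- fl
  out
}

#' Default four-cycle breast panel
#'
#' DAPI counterstain in every cycle; cycle 1 carries the
#' tumor/immune separation markers (CD45 and the QUAD set
#' HER2/EpCAM/MUC1/EGFR), cycles 2-3 the remaining tumor, proliferation
#' and host markers, and cycle 4 IgG isotype controls on all five
#' fluorochrome channels.
#'
#' @return a `CyclePanel`
#' @examples
#' panelMarkers(defaultPanel())
#' @export
defaultPanel <- function() {
  cyc <- list(
    c(DAPI = "DAPI", AF488 = "CD45", AF555 = "HER2", BV605 = "EpCAM",
      AF647 = "MUC1", CF750 = "EGFR"),
    c(DAPI = "DAPI", AF488 = "CK7", AF555 = "ER", BV605 = "GATA3",
      AF647 = "PR", CF750 = "SMA"),
    c(DAPI = "DAPI", AF488 = "CD31", AF555 = "Ki67", BV605 = "CD68",
      AF647 = "CD8", CF750 = "TROP2"),
    c(DAPI = "DAPI", AF488 = "IgG_AF488", AF555 = "IgG_AF555",
      BV605 = "IgG_BV605", AF647 = "IgG_AF647", CF750 = "IgG_CF750"))
  igg <- data.frame(cycle = 4L,
                    fluorochrome = c("AF488", "AF555", "BV605", "AF647",
                                     "CF750"))
  cyclePanel(cyc, igg)
}

#' Default per-phenotype expression parameters
#'
#' Log-normal abundance parameters (meanlog, sdlog) per phenotype and
#' marker, in expected-count units of the brightest fingerprint entry.
#' Tumor cells express the epithelial/receptor set (QUAD =
#' HER2/EpCAM/MUC1/EGFR, plus ER/PR/Ki67/CK7/GATA3/TROP2); immune cells
#' express CD45 (plus CD8/CD68); unlisted markers are truly absent
#' (abundance 0), and DAPI stains every nucleus. The default level of
#' ~300 counts against a ~6-count background SD corresponds to a
#' single-stain SNR of about 50.
#'
#' @return nested list: phenotype -> marker -> c(meanlog, sdlog)
#' @export
defaultExpressionParams <- function() {
  hi <- c(log(300), 0.35)
  list(
    tumor = list(HER2 = hi, EpCAM = hi, MUC1 = hi, EGFR = hi,
                 ER = hi, PR = hi, Ki67 = c(log(200), 0.5),
                 CK7 = hi, GATA3 = hi, TROP2 = hi,
                 DAPI = c(log(400), 0.2)),
    immune = list(CD45 = hi, CD8 = c(log(150), 0.4),
                  CD68 = c(log(120), 0.4), DAPI = c(log(400), 0.2)))
}

#' Generate a seeded synthetic scene
#'
#' Places elliptical cells (with contained elliptical nuclei) by
#' minimum-distance rejection sampling, assigns phenotypes by the given
#' mixture, and draws per-cell marker abundances log-normally from the
#' phenotype's expression parameters. Deterministic given `seed`.
#'
#' @param nCells number of cells (>= 0)
#' @param phenotypeMix named fractions summing to 1
#' @param width,height frame size in pixels
#' @param pixelSizeUm pixel size (default 0.6 um)
#' @param cellRadius range of cell semi-axes (px)
#' @param nucleusFrac range of nucleus/cell semi-axis ratio
#' @param minDist minimum center-to-center distance (px)
#' @param expression expression parameters, see
#'   [defaultExpressionParams()]
#' @param markers marker set of the scene (defaults to the markers of
#'   [defaultPanel()])
#' @param autofluorescence expected autofluorescence counts in cell
#'   bodies
#' @param seed RNG seed
#' @return a [Scene-class]
#' @examples
#' sc <- generateScene(50, width = 256, height = 256, seed = 1)
#' sc
#' @export
generateScene <- function(nCells,
                          phenotypeMix = c(tumor = 0.7, immune = 0.3),
                          width = 640, height = 640, pixelSizeUm = 0.6,
                          cellRadius = c(8, 10.5),
                          nucleusFrac = c(0.55, 0.68), minDist = 20,
                          expression = defaultExpressionParams(),
                          markers = panelMarkers(defaultPanel()),
                          autofluorescence = 25, seed = 1L) {
  stopifnot(nCells >= 0, abs(sum(phenotypeMix) - 1) < 1e-8)
  set.seed(seed)
  margin <- max(cellRadius) + 1
  centers <- matrix(numeric(), 0L, 2L)
  attempts <- 0L
  maxAttempts <- max(200L * nCells, 1000L)
  while (nrow(centers) < nCells) {
    if ((attempts <- attempts + 1L) > maxAttempts)
      stop("could not place ", nCells, " cells at minimum distance ",
           minDist, " px in a ", width, " x ", height,
           " frame; use a larger frame or fewer cells")
    cand <- c(runif(1, margin, height - margin),
              runif(1, margin, width - margin))
    if (nrow(centers) == 0L ||
        min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >=
        minDist^2)
      centers <- rbind(centers, cand)
  }
  phen <- if (nCells > 0)
    sample(names(phenotypeMix), nCells, replace = TRUE,
           prob = phenotypeMix) else character()
  cellA <- runif(nCells, cellRadius[1], cellRadius[2])
  cellB <- runif(nCells, cellRadius[1], cellRadius[2])
  nf <- runif(nCells, nucleusFrac[1], nucleusFrac[2])
  cells <- data.frame(
    id = seq_len(nCells), row = centers[, 1], col = centers[, 2],
    cellA = cellA, cellB = cellB, nucA = cellA * nf, nucB = cellB * nf,
    theta = runif(nCells, 0, pi), phenotype = phen)
  lev <- matrix(0, nCells, length(markers),
                dimnames = list(NULL, markers))
  for (i in seq_len(nCells)) {
    pars <- expression[[phen[i]]]
    for (mk in intersect(markers, names(pars)))
      lev[i, mk] <- rlnorm(1, pars[[mk]][1], pars[[mk]][2])
  }
  obj <- new("Scene", width = as.integer(width),
             height = as.integer(height), pixelSizeUm = pixelSizeUm,
             cells = cells, markerLevels = lev,
             autofluorescence = autofluorescence,
             afProfile = numeric(0))
  validObject(obj)
  obj
}

#' Ground-truth cell table of a scene
#'
#' One row per simulated cell with its geometry, phenotype and true
#' marker abundances; the oracle for end-to-end accuracy checks.
#'
#' @param scene a [Scene-class]
#' @return data.frame with columns label, row, col, nucleus_area_px,
#'   cell_area_px, phenotype and one `true.<marker>` column per marker
#' @export
groundTruthTable <- function(scene) {
  cl <- scene@cells
  out <- data.frame(label = cl$id, row = cl$row, col = cl$col,
                    nucleus_area_px = pi * cl$nucA * cl$nucB,
                    cell_area_px = pi * cl$cellA * cl$cellB,
                    phenotype = cl$phenotype)
  lev <- scene@markerLevels
  if (ncol(lev)) {
    colnames(lev) <- paste0("true.", colnames(lev))
    out <- cbind(out, as.data.frame(lev))
  }
  out[seq_len(nrow(cl)), , drop = FALSE]
}
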