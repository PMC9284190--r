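# registry of segmentation backends; a backend is any function
# (dapiMip, cytoplasm, params) -> LabelMasks
.backendRegistry <- new.env(parent = emptyenv())

#' Register or list segmentation backends
#'
#' Segmentation is pluggable: learned segmenters can be wrapped and
#' registered under a name; the built-in `"watershed"` backend is a
#' classical reference (DAPI thresholding, hole filling,
#' distance-transform watershed splitting, fixed-radius or
#' cytoplasm-guided cell expansion).
#'
#' @param name backend name
#' @param fun function `(dapiMip, cytoplasm, params) -> LabelMasks`
#' @return `segmentationBackends` returns the registered names.
#' @export
registerSegmentationBackend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .backendRegistry)
  invisible(name)
}

#' @rdname registerSegmentationBackend
#' @export
segmentationBackends <- function() {
  sort(ls(.backendRegistry))
}

# built-in classical backend
.watershedBackend <- function(dapiMip, cytoplasm, params) {
  p <- modifyList(list(sigma = 2, minNucleusArea = 20, cellRadius = 4,
                       tolerance = 1), params)
  h <- nrow(dapiMip); w <- ncol(dapiMip)
  s <- as.matrix(EBImage::gblur(EBImage::Image(dapiMip), sigma = p$sigma))
  rng <- range(s)
  if (diff(rng) == 0) {
    z <- matrix(0L, h, w)
    return(new("LabelMasks", nucleusLabels = z, cellLabels = z,
               nucleusToCell = integer()))
  }
  sn <- (s - rng[1L]) / diff(rng)
  mask <- sn > EBImage::otsu(EBImage::Image(sn))
  mask <- EBImage::fillHull(EBImage::Image(mask))
  dm <- EBImage::distmap(mask)
  nuc <- EBImage::watershed(dm, tolerance = p$tolerance, ext = 1)
  nuc <- as.matrix(nuc)
  # drop specks and relabel contiguously
  area <- tabulate(nuc[nuc > 0L])
  keep <- which(area >= p$minNucleusArea)
  remap <- integer(length(area))
  remap[keep] <- seq_along(keep)
  nuc[nuc > 0L] <- remap[nuc[nuc > 0L]]
  if (!any(nuc > 0L)) {
    z <- matrix(0L, h, w)
    return(new("LabelMasks", nucleusLabels = z, cellLabels = z,
               nucleusToCell = integer()))
  }
  cellMask <- if (!is.null(cytoplasm)) {
    cn <- cytoplasm / max(cytoplasm, 1e-12)
    (cn > EBImage::otsu(EBImage::Image(cn))) | as.matrix(mask) > 0
  } else {
    brush <- EBImage::makeBrush(2L * p$cellRadius + 1L, "disc")
    as.matrix(EBImage::dilate(EBImage::Image(as.matrix(mask) > 0),
                              brush)) > 0
  }
  cells <- EBImage::propagate(EBImage::Image(s),
                              seeds = EBImage::Image(nuc),
                              mask = EBImage::Image(cellMask))
  cells <- matrix(as.integer(as.matrix(cells)), h, w)
  nucIds <- sort(setdiff(unique(as.vector(nuc)), 0L))
  new("LabelMasks", nucleusLabels = matrix(as.integer(nuc), h, w),
      cellLabels = cells,
      nucleusToCell = setNames(nucIds, nucIds))
}

#' Segment nuclei and cells
#'
#' Runs the named segmentation backend on the DAPI maximum-intensity
#' projection (and optionally a cytoplasmic image that guides the cell
#' outline). The built-in `"watershed"` backend splits touching nuclei
#' on the distance transform and grows cell bodies from the nucleus
#' seeds.
#'
#' @param dapiMip DAPI maximum-intensity projection (matrix)
#' @param cytoplasm optional cytoplasmic intensity image
#' @param backend registered backend name (default `"watershed"`)
#' @param params backend parameter list (built-in: `sigma`,
#'   `minNucleusArea`, `cellRadius`, `tolerance`)
#' @return a [LabelMasks-class]
#' @export
segmentCells <- function(dapiMip, cytoplasm = NULL,
                         backend = "watershed", params = list()) {
  if (!backend %in% segmentationBackends())
    stop("unknown segmentation backend '", backend,
         "'; registered backends: ",
         paste(segmentationBackends(), collapse = ", "))
  fun <- get(backend, envir = .backendRegistry)
  masks <- fun(dapiMip, cytoplasm, params)
  stopifnot(is(masks, "LabelMasks"))
  masks
}

#' Quality-control filter on segmented cells
#'
#' Applies the exclusion rules of the analysis: cells containing more
#' than one nucleus and cells with a nucleus-to-cell size ratio greater
#' than 1 are removed; nuclei without a cell and cells without a
#' nucleus are removed and logged separately. Idempotent.
#'
#' @param masks a [LabelMasks-class]
#' @return list with `masks` (filtered [LabelMasks-class]) and
#'   `report`: a data.frame of exclusion reasons (`multi_nucleus`,
#'   `ratio_gt_1`, `no_nucleus`, `orphan_nucleus`, `retained`) and
#'   counts, with per-cell detail in the `detail` attribute
#' @export
qcFilter <- function(masks) {
  nuc <- masks@nucleusLabels
  cell <- masks@cellLabels
  nucIds <- sort(setdiff(unique(as.vector(nuc)), 0L))
  cellIds <- sort(setdiff(unique(as.vector(cell)), 0L))
  # nucleus -> cell by majority overlap
  ov <- table(nucleus = nuc[nuc > 0L & cell > 0L],
              cell = cell[nuc > 0L & cell > 0L])
  n2c <- integer(0)
  if (length(ov)) {
    n2c <- setNames(as.integer(colnames(ov)[max.col(ov,
                                                    ties.method = "first")]),
                    rownames(ov))
  }
  orphanNuc <- setdiff(nucIds, as.integer(names(n2c)))
  nucArea <- tabulate(nuc[nuc > 0L], nbins = max(nucIds, 0L))
  cellArea <- tabulate(cell[cell > 0L], nbins = max(cellIds, 0L))
  perCell <- data.frame(cell = cellIds)
  perCell$nNuclei <- vapply(cellIds, function(cid)
    sum(n2c == cid), 0L)
  perCell$nucleusArea <- vapply(cellIds, function(cid)
    sum(nucArea[as.integer(names(n2c))[n2c == cid]]), 0)
  perCell$cellArea <- cellArea[cellIds]
  perCell$ratio <- perCell$nucleusArea / perCell$cellArea
  perCell$reason <- "retained"
  perCell$reason[perCell$nNuclei == 0L] <- "no_nucleus"
  perCell$reason[perCell$ratio > 1] <- "ratio_gt_1"
  perCell$reason[perCell$nNuclei > 1L] <- "multi_nucleus"
  keepCells <- perCell$cell[perCell$reason == "retained"]
  keepNuc <- as.integer(names(n2c))[n2c %in% keepCells]
  nucOut <- nuc; cellOut <- cell
  nucOut[!(nuc %in% keepNuc)] <- 0L
  cellOut[!(cell %in% keepCells)] <- 0L
  counts <- c(multi_nucleus = sum(perCell$reason == "multi_nucleus"),
              ratio_gt_1 = sum(perCell$reason == "ratio_gt_1"),
              no_nucleus = sum(perCell$reason == "no_nucleus"),
              orphan_nucleus = length(orphanNuc),
              retained = length(keepCells))
  report <- data.frame(reason = names(counts), count = as.integer(counts))
  attr(report, "detail") <- perCell
  filtered <- new("LabelMasks", nucleusLabels = nucOut,
                  cellLabels = cellOut,
                  nucleusToCell = setNames(n2c[n2c %in% keepCells],
                                           names(n2c)[n2c %in% keepCells]))
  list(masks = filtered, report = report)
}
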