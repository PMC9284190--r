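#' Quantify per-cell marker intensities
#'
#' Computes the mean unmixed abundance of every marker over each
#' retained cell: membrane/cytoplasmic markers over the whole cell
#' mask, nuclear markers (per the panel's `nuclearMarkers`) over the
#' nucleus mask. DAPI is quantified from the pixel-wise maximum of its
#' abundance across cycles. Marker values are routed through the panel
#' (cycle, fluorochrome) -> marker assignment.
#'
#' @param masks a QC-filtered [LabelMasks-class]
#' @param fluorImages list over cycles; element `i` is the
#'   [unmixImage()] result (or its `abundances` list) of cycle `i`
#' @param panel a `CyclePanel`
#' @return a cell table: data.frame with `label`, centroid `row`/`col`,
#'   `nucleus_area_px`, `cell_area_px`, and one `mean.<marker>` column
#'   per marker
#' @export
quantifyCells <- function(masks, fluorImages, panel) {
  cellLab <- masks@cellLabels
  nucLab <- masks@nucleusLabels
  ids <- sort(setdiff(unique(as.vector(cellLab)), 0L))
  if (!length(ids)) {
    return(data.frame(label = integer(), row = numeric(),
                      col = numeric(), nucleus_area_px = numeric(),
                      cell_area_px = numeric()))
  }
  abund <- lapply(fluorImages, function(fi)
    if (!is.null(fi$abundances)) fi$abundances else fi)
  meanOver <- function(img, lab) {
    sums <- rowsum(img[lab > 0L], lab[lab > 0L])
    cnt <- rowsum(rep(1, sum(lab > 0L)), lab[lab > 0L])
    setNames(as.vector(sums / cnt), rownames(sums))
  }
  idx <- which(cellLab > 0L)
  rows <- (idx - 1L) %% nrow(cellLab) + 1L
  cols <- (idx - 1L) %/% nrow(cellLab) + 1L
  lv <- cellLab[idx]
  out <- data.frame(
    label = ids,
    row = as.vector(rowsum(rows, lv) / rowsum(rep(1L, length(lv)), lv)),
    col = as.vector(rowsum(cols, lv) / rowsum(rep(1L, length(lv)), lv)),
    nucleus_area_px = vapply(ids, function(i) sum(nucLab == i), 0),
    cell_area_px = vapply(ids, function(i) sum(cellLab == i), 0))
  key <- as.character(ids)
  dapiImgs <- list()
  for (cyc in seq_along(panel@cycles)) {
    if (cyc > length(abund)) stop("no unmixed images for cycle ", cyc)
    map <- panel@cycles[[cyc]]
    for (fl in names(map)) {
      mk <- map[[fl]]
      img <- abund[[cyc]][[fl]]
      if (is.null(img))
        stop("cycle ", cyc, " has no unmixed image for fluorochrome ",
             fl, " (marker ", mk, ")")
      if (mk == "DAPI") {
        dapiImgs[[length(dapiImgs) + 1L]] <- img
        next
      }
      lab <- if (mk %in% panel@nuclearMarkers) nucLab else cellLab
      m <- meanOver(img, lab)
      out[[paste0("mean.", mk)]] <- unname(m[key])
    }
  }
  if (length(dapiImgs)) {
    m <- meanOver(dapiMaxProjection(dapiImgs), nucLab)
    out[["mean.DAPI"]] <- unname(m[key])
  }
  out
}

#' Percentile normalization of a cell table
#'
#' Per marker, cell means are divided by the marker's 10th percentile
#' across cells (so 1 is the low-end reference), and values above the
#' 99th percentile are winsorized to the 99th-percentile value to
#' suppress outliers. Both reference values are recorded in the
#' `normalization` attribute. An additive `offset` (in intensity
#' counts) stabilizes channels whose 10th percentile is zero, as
#' happens for background-only channels after bounded unmixing.
#'
#' @param table a cell table from [quantifyCells()]
#' @param offset added to all values before normalization (default 0)
#' @return the table with one `norm.<marker>` column per marker
#' @export
normalizeCellTable <- function(table, offset = 0) {
  mcols <- grep("^mean\\.", names(table), value = TRUE)
  if (nrow(table) < 10L)
    stop("normalization needs at least 10 cells per marker")
  ref <- data.frame(marker = sub("^mean\\.", "", mcols), p10 = NA_real_,
                    p99 = NA_real_)
  for (i in seq_along(mcols)) {
    v <- table[[mcols[i]]] + offset
    p10 <- quantile(v, 0.10, names = FALSE)
    if (p10 == 0)
      stop("degenerate baseline: 10th percentile of ", mcols[i],
           " is zero; consider a noise-floor offset (see `offset`)")
    vn <- v / p10
    p99 <- quantile(vn, 0.99, names = FALSE)
    ref$p10[i] <- p10; ref$p99[i] <- p99
    table[[sub("^mean\\.", "norm.", mcols[i])]] <- pmin(vn, p99)
  }
  attr(table, "normalization") <- ref
  table
}

#' IgG control statistics per fluorochrome channel
#'
#' Mean and standard deviation of the normalized per-cell intensities
#' of the IgG-designated (cycle, fluorochrome) channels: the null
#' staining distribution that sets positivity thresholds.
#'
#' @param table a normalized cell table
#' @param panel a `CyclePanel` with `iggControls`
#' @return data.frame with `channel` (fluorochrome), `marker`, `mean`,
#'   `sd`, `n`
#' @export
iggStats <- function(table, panel) {
  ig <- panel@iggControls
  if (!nrow(ig)) stop("panel designates no IgG controls")
  rows <- lapply(seq_len(nrow(ig)), function(i) {
    mk <- panel@cycles[[ig$cycle[i]]][[ig$fluorochrome[i]]]
    col <- paste0("norm.", mk)
    if (is.null(table[[col]]))
      stop("cell table has no normalized column for IgG marker ", mk)
    v <- table[[col]]
    if (length(v) < 2L) stop("IgG statistics need >= 2 cells")
    data.frame(channel = ig$fluorochrome[i], marker = mk,
               mean = mean(v), sd = sd(v), n = length(v))
  })
  do.call(rbind, rows)
}

#' Call per-marker positivity
#'
#' A cell is positive for a marker when its normalized intensity
#' strictly exceeds the IgG threshold of the marker's fluorochrome
#' channel, `mean + 3 * sd` of the IgG control cells (ties at the
#' threshold are negative). Thresholds are recorded in the
#' `thresholds` attribute.
#'
#' @param table a normalized cell table
#' @param igg IgG statistics from [iggStats()], or a named numeric
#'   vector of constant thresholds per marker (accepted with a warning)
#' @param panel a `CyclePanel` (used to route each marker to its
#'   fluorochrome channel)
#' @param nSd number of IgG standard deviations (default 3)
#' @return the table with one logical `pos.<marker>` column per
#'   non-control marker (DAPI and IgG channels excluded)
#' @export
callPositivity <- function(table, igg, panel, nSd = 3) {
  chan <- .markerChannel(panel)
  iggMk <- .iggMarkers(panel)
  markers <- setdiff(sub("^norm\\.", "",
                         grep("^norm\\.", names(table), value = TRUE)),
                     c("DAPI", iggMk))
  if (is.numeric(igg)) {
    warning("using user-supplied constant thresholds instead of IgG ",
            "statistics")
    thr <- igg[markers]
    if (any(is.na(thr)))
      stop("missing constant threshold for marker(s): ",
           paste(markers[is.na(thr)], collapse = ", "))
  } else {
    thr <- vapply(markers, function(mk) {
      row <- igg[igg$channel == chan[[mk]], , drop = FALSE]
      if (!nrow(row))
        stop("no IgG statistics for channel ", chan[[mk]],
             " (marker ", mk, ")")
      row$mean[1L] + nSd * row$sd[1L]
    }, 0)
  }
  for (mk in markers)
    table[[paste0("pos.", mk)]] <- table[[paste0("norm.", mk)]] >
      thr[[mk]]
  attr(table, "thresholds") <- thr
  table
}

#' Rule-based phenotype classification
#'
#' Assigns each cell the label of the first rule whose boolean
#' expression over marker positivity evaluates TRUE; unmatched cells
#' get `"other"`. Expressions use bare marker names as logicals, e.g.
#' `"CD45"` or `"(HER2 | EpCAM | MUC1 | EGFR) & !CD45"`.
#'
#' @param table a cell table with `pos.<marker>` columns
#' @param rules ordered list of `list(label = , expr = )`; see
#'   [immuneTumorRules()] and [mosaicRules()]
#' @return the table with a `phenotype` column
#' @export
classifyPhenotypes <- function(table, rules = immuneTumorRules()) {
  pcols <- grep("^pos\\.", names(table), value = TRUE)
  env <- as.data.frame(setNames(lapply(pcols, function(cn) table[[cn]]),
                                sub("^pos\\.", "", pcols)))
  phen <- rep("other", nrow(table))
  assigned <- rep(FALSE, nrow(table))
  for (rule in rules) {
    if (is.null(rule$label) || is.null(rule$expr))
      stop("malformed rule: each rule needs label and expr")
    expr <- tryCatch(str2lang(rule$expr),
                     error = function(e)
                       stop("malformed rule expression: ", rule$expr))
    vars <- all.vars(expr)
    unknown <- setdiff(vars, names(env))
    if (length(unknown))
      stop("rule '", rule$expr, "' references marker(s) without ",
           "positivity calls: ", paste(unknown, collapse = ", "))
    hit <- eval(expr, envir = env, enclos = baseenv())
    if (!is.logical(hit) || length(hit) != nrow(table))
      stop("malformed rule expression (not a per-cell boolean): ",
           rule$expr)
    sel <- hit & !assigned
    phen[sel] <- rule$label
    assigned <- assigned | hit
  }
  table$phenotype <- phen
  table
}

#' Built-in phenotype rule sets
#'
#' `immuneTumorRules()` separates CD45-positive immune cells from
#' tumor cells positive for any of the QUAD markers
#' (HER2/EpCAM/MUC1/EGFR) while CD45-negative. `mosaicRules()` is the
#' five-way receptor/proliferation split used for cohort mosaics:
#' multi-marker (two or more of HER2/ER/PR/Ki67), Ki67-only,
#' HER2-only, ER/PR-only, and quad-negative.
#'
#' @return ordered list of rules for [classifyPhenotypes()]
#' @export
immuneTumorRules <- function() {
  list(list(label = "immune", expr = "CD45"),
       list(label = "tumor",
            expr = "(HER2 | EpCAM | MUC1 | EGFR) & !CD45"))
}

#' @rdname immuneTumorRules
#' @export
mosaicRules <- function() {
  list(list(label = "multi_marker",
            expr = "(HER2 + ER + PR + Ki67) >= 2"),
       list(label = "ki67_only", expr = "Ki67 & !HER2 & !ER & !PR"),
       list(label = "her2_only", expr = "HER2 & !ER & !PR & !Ki67"),
       list(label = "erpr_only", expr = "(ER | PR) & !HER2 & !Ki67"),
       list(label = "quad_negative",
            expr = "!HER2 & !ER & !PR & !Ki67"))
}
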