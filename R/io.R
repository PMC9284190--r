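#' Write / read an acquisition stack as multi-page TIFF + JSON sidecar
#'
#' Each cycle is stored as 16-bit multi-page TIFFs (page order:
#' LED-major, then R, G, B) for the stained, quenched and dark images,
#' with a JSON sidecar recording the cycle index, LED names, intensity
#' scale, truth transform (if any) and seed. Counts are scaled by a
#' recorded factor into the 16-bit range, so round-tripping is exact to
#' about 1/65535 of the brightest pixel.
#'
#' @param stack an [AcquisitionStack-class]
#' @param dir output directory (created if needed)
#' @param overwrite allow replacing existing files (default FALSE)
#' @return `writeAcquisitionStack` returns the sidecar path invisibly;
#'   `readAcquisitionStack` returns the [AcquisitionStack-class].
#' @export
writeAcquisitionStack <- function(stack, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- sprintf("cycle%02d", stack@cycleIndex)
  sidecar <- file.path(dir, paste0(base, ".json"))
  if (file.exists(sidecar) && !overwrite)
    stop("refusing to overwrite ", sidecar, " (set overwrite = TRUE)")
  leds <- names(stack@stained)
  scale <- max(unlist(lapply(c(stack@stained, stack@quenched,
                               list(stack@dark)), max)), 1e-12)
  pages <- function(planes)
    unlist(lapply(planes, function(arr)
      lapply(1:3, function(ch) arr[, , ch] / scale)), recursive = FALSE)
  wr <- function(planes, suffix) {
    p <- file.path(dir, paste0(base, "_", suffix, ".tif"))
    tiff::writeTIFF(pages(planes), p, bits.per.sample = 16L,
                    compression = "none")
    p
  }
  files <- list(stained = wr(stack@stained, "stained"),
                dark = wr(list(stack@dark), "dark"))
  if (length(stack@quenched))
    files$quenched <- wr(stack@quenched, "quenched")
  tf <- stack@transformTruth
  meta <- list(cycle = stack@cycleIndex, leds = as.list(leds),
               scale = scale,
               files = lapply(files, basename),
               transform_truth = if (is(tf, "RigidTransform"))
                 list(rotation_rad = tf@rotation,
                      translation_px = tf@translation) else NULL,
               seed = stack@meta$seed)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sidecar)
}

#' @rdname writeAcquisitionStack
#' @param sidecar path to a cycle's JSON sidecar
#' @export
readAcquisitionStack <- function(sidecar) {
  if (!file.exists(sidecar)) stop("no such sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  leds <- as.character(meta$leds)
  rd <- function(name) {
    path <- file.path(dir, name)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e)
                        stop("cannot read TIFF ", path, ": ",
                             conditionMessage(e)))
    lapply(pages, function(p) p * meta$scale)
  }
  toStacks <- function(pages) {
    n <- length(pages) / 3L
    out <- lapply(seq_len(n), function(i) {
      arr <- array(0, c(dim(pages[[1L]]), 3L))
      for (ch in 1:3) arr[, , ch] <- pages[[(i - 1L) * 3L + ch]]
      arr
    })
    out
  }
  stained <- toStacks(rd(meta$files$stained))
  names(stained) <- leds
  quenched <- list()
  if (!is.null(meta$files$quenched)) {
    quenched <- toStacks(rd(meta$files$quenched))
    names(quenched) <- leds
  }
  dark <- toStacks(rd(meta$files$dark))[[1L]]
  tf <- if (!is.null(meta$transform_truth))
    rigidTransform(meta$transform_truth$rotation_rad,
                   meta$transform_truth$translation_px) else NULL
  new("AcquisitionStack", cycleIndex = as.integer(meta$cycle),
      stained = stained, quenched = quenched, dark = dark,
      transformTruth = tf,
      meta = list(leds = leds, seed = meta$seed, sidecar = sidecar))
}

#' Write / read a cell table as CSV
#'
#' Stable column names: `label`, `row`, `col`, `nucleus_area_px`,
#' `cell_area_px`, `mean.<marker>`, `norm.<marker>`, `pos.<marker>`,
#' `phenotype`.
#'
#' @param table a cell table
#' @param path CSV path
#' @export
writeCellTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  read.csv(path, check.names = FALSE)
}
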