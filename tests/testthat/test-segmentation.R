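test_that("well-separated nuclei are each found once", {
  fx <- fxNoiselessField()   # 30 cells
  masks <- segmentCells(fx$unmixed$abundances$DAPI)
  expect_equal(length(setdiff(unique(as.vector(masks@nucleusLabels)),
                              0L)), 30L)
  expect_equal(length(setdiff(unique(as.vector(masks@cellLabels)), 0L)),
               30L)
})

test_that("a blank image yields empty masks without error", {
  masks <- segmentCells(matrix(0, 64, 64))
  expect_equal(max(masks@nucleusLabels), 0L)
  expect_equal(max(masks@cellLabels), 0L)
})

test_that("two touching equal nuclei are split by the watershed", {
  r <- rep(1:64, times = 64); cl <- rep(1:64, each = 64)
  img <- matrix(300 * exp(-((r - 32)^2 + (cl - 24)^2) / 50), 64, 64) +
    matrix(300 * exp(-((r - 32)^2 + (cl - 40)^2) / 50), 64, 64)
  masks <- segmentCells(img)
  expect_equal(length(setdiff(unique(as.vector(masks@nucleusLabels)),
                              0L)), 2L)
})

test_that("unknown backends are rejected with the registered list", {
  expect_error(segmentCells(matrix(1, 8, 8), backend = "mesmer"),
               "watershed")
})

test_that("custom backends can be registered and used", {
  registerSegmentationBackend("onecell", function(dapi, cyto, params) {
    lab <- matrix(0L, nrow(dapi), ncol(dapi))
    lab[3:6, 3:6] <- 1L
    cell <- matrix(0L, nrow(dapi), ncol(dapi))
    cell[2:7, 2:7] <- 1L
    new("LabelMasks", nucleusLabels = lab, cellLabels = cell,
        nucleusToCell = c("1" = 1L))
  })
  masks <- segmentCells(matrix(1, 10, 10), backend = "onecell")
  expect_equal(max(masks@cellLabels), 1L)
  expect_true("onecell" %in% segmentationBackends())
})

test_that("QC filtering excludes exactly the constructed violations", {
  masks <- fxQcMasks()   # 10 cells: 2 multi-nucleus, 2 ratio > 1
  flt <- qcFilter(masks)
  counts <- setNames(flt$report$count, flt$report$reason)
  expect_equal(counts[["multi_nucleus"]], 2L)
  expect_equal(counts[["ratio_gt_1"]], 2L)
  expect_equal(counts[["retained"]], 6L)
  expect_equal(length(setdiff(unique(as.vector(flt$masks@cellLabels)),
                              0L)), 6L)
  detail <- attr(flt$report, "detail")
  expect_equal(detail$reason[detail$cell %in% 1:2],
               rep("multi_nucleus", 2))
  expect_equal(detail$reason[detail$cell %in% 3:4],
               rep("ratio_gt_1", 2))
  # a healthy ratio is retained
  expect_true(all(detail$ratio[detail$reason == "retained"] < 1))
})

test_that("QC filtering is idempotent", {
  flt1 <- qcFilter(fxQcMasks())
  flt2 <- qcFilter(flt1$masks)
  expect_identical(flt2$masks@cellLabels, flt1$masks@cellLabels)
  expect_identical(flt2$masks@nucleusLabels, flt1$masks@nucleusLabels)
  expect_equal(flt2$report$count[flt2$report$reason == "retained"],
               flt1$report$count[flt1$report$reason == "retained"])
  expect_equal(sum(flt2$report$count[flt2$report$reason != "retained"]),
               0L)
})

# minimal quantification scaffold: one square cell with known levels
.uniformQuantFixture <- function(level = 7) {
  nuc <- matrix(0L, 20, 20); cell <- matrix(0L, 20, 20)
  cell[5:16, 5:16] <- 1L
  nuc[8:13, 8:13] <- 1L
  masks <- new("LabelMasks", nucleusLabels = nuc, cellLabels = cell,
               nucleusToCell = c("1" = 1L))
  pan <- cyclePanel(list(c(DAPI = "DAPI", AF488 = "CD45")))
  img <- matrix(0, 20, 20); img[cell == 1L] <- level
  dapi <- matrix(0, 20, 20); dapi[nuc == 1L] <- 2 * level
  list(masks = masks, panel = pan,
       images = list(list(AF488 = img, DAPI = dapi)))
}

test_that("quantification recovers uniform abundances and is linear", {
  fx <- .uniformQuantFixture(7)
  tb <- quantifyCells(fx$masks, fx$images, fx$panel)
  expect_equal(tb$mean.CD45, 7)
  expect_equal(tb$mean.DAPI, 14)
  expect_equal(tb$cell_area_px, 144)
  expect_equal(tb$nucleus_area_px, 36)
  scaled <- fx$images
  scaled[[1]] <- lapply(scaled[[1]], `*`, 3)
  tb3 <- quantifyCells(fx$masks, scaled, fx$panel)
  expect_equal(tb3$mean.CD45, 3 * tb$mean.CD45)
})

test_that("the union mean equals the area-weighted mean of its parts", {
  img <- matrix(runif(400), 20, 20)
  cell <- matrix(0L, 20, 20)
  cell[2:10, 2:10] <- 1L
  nucA <- matrix(0L, 20, 20); nucA[3:5, 3:5] <- 1L
  masks <- new("LabelMasks", nucleusLabels = nucA, cellLabels = cell,
               nucleusToCell = c("1" = 1L))
  pan <- cyclePanel(list(c(DAPI = "DAPI", AF488 = "CD45")))
  tb <- quantifyCells(masks, list(list(AF488 = img, DAPI = img)), pan)
  part1 <- img[2:10, 2:6]; part2 <- img[2:10, 7:10]
  expect_equal(tb$mean.CD45,
               (sum(part1) + sum(part2)) /
                 (length(part1) + length(part2)))
})

test_that("normalization divides by p10, winsorizes at p99 and records both", {
  set.seed(3)
  tb <- data.frame(label = 1:200, row = 0, col = 0,
                   nucleus_area_px = 10, cell_area_px = 20,
                   mean.CD45 = rlnorm(200, log(50), 0.6))
  nt <- normalizeCellTable(tb)
  ref <- attr(nt, "normalization")
  expect_equal(quantile(nt$norm.CD45, 0.10, names = FALSE), 1)
  expect_equal(max(nt$norm.CD45), ref$p99)
  # scale invariance
  tb2 <- tb; tb2$mean.CD45 <- 5 * tb$mean.CD45
  nt2 <- normalizeCellTable(tb2)
  expect_equal(nt2$norm.CD45, nt$norm.CD45)
  # constant values map to exactly 1
  tb3 <- tb; tb3$mean.CD45 <- 4
  expect_equal(normalizeCellTable(tb3)$norm.CD45, rep(1, 200))
  # degenerate baseline errors with advice
  tb4 <- tb; tb4$mean.CD45[1:50] <- 0
  expect_error(normalizeCellTable(tb4), "degenerate baseline")
  expect_silent(normalizeCellTable(tb4, offset = 1))
  expect_error(normalizeCellTable(tb[1:5, ]), "at least 10 cells")
})

test_that("positivity thresholds follow mean + 3 sd with strict inequality", {
  pan <- cyclePanel(
    list(c(DAPI = "DAPI", AF488 = "CD45", AF555 = "IgG_1")),
    iggControls = data.frame(cycle = 1L, fluorochrome = "AF555"))
  # CD45 shares no channel with the IgG here, so route CD45 through the
  # IgG channel stats by putting both on AF555-equivalent numbers
  tb <- data.frame(label = 1:12,
                   norm.CD45 = c(16.1, 15.9, rep(10, 10)),
                   norm.IgG_1 = rep(c(8, 12), 6))
  igg <- data.frame(channel = "AF488", marker = "IgG_1",
                    mean = 10, sd = 2, n = 12)
  out <- callPositivity(tb, igg, pan)
  expect_equal(unname(attr(out, "thresholds")["CD45"]), 16)
  expect_identical(out$pos.CD45,
                   c(TRUE, FALSE, rep(FALSE, 10)))
  # zero SD: threshold equals the mean, ties stay negative
  igg0 <- igg; igg0$sd <- 0
  tb0 <- tb; tb0$norm.CD45 <- c(10, 10.01, rep(9, 10))
  out0 <- callPositivity(tb0, igg0, pan)
  expect_identical(out0$pos.CD45, c(FALSE, TRUE, rep(FALSE, 10)))
  # missing channel stats error
  expect_error(callPositivity(tb, igg[0, ], pan), "IgG statistics")
})

test_that("IgG statistics come from the designated channels", {
  pan <- defaultPanel()
  set.seed(4)
  tb <- data.frame(label = 1:50)
  for (mk in panelMarkers(pan))
    tb[[paste0("norm.", mk)]] <- rlnorm(50, 0, 0.2)
  st <- iggStats(tb, pan)
  expect_equal(nrow(st), 5L)
  expect_setequal(st$channel, c("AF488", "AF555", "BV605", "AF647",
                                "CF750"))
  expect_true(all(st$n == 50))
  expect_equal(st$mean[st$marker == "IgG_AF488"],
               mean(tb$norm.IgG_AF488))
})

test_that("phenotype rules apply in order with a default label", {
  tb <- data.frame(label = 1:4,
                   pos.CD45 = c(TRUE, FALSE, FALSE, TRUE),
                   pos.HER2 = c(FALSE, TRUE, FALSE, TRUE),
                   pos.EpCAM = FALSE, pos.MUC1 = FALSE,
                   pos.EGFR = FALSE)
  out <- classifyPhenotypes(tb, immuneTumorRules())
  expect_identical(out$phenotype, c("immune", "tumor", "other",
                                    "immune"))
  expect_error(classifyPhenotypes(tb, list(list(label = "x",
                                                expr = "NOPE"))),
               "NOPE")
  expect_error(classifyPhenotypes(tb, list(list(expr = "CD45"))),
               "malformed rule")
})

test_that("the five-way mosaic split is exclusive and exhaustive", {
  combos <- expand.grid(HER2 = c(TRUE, FALSE), ER = c(TRUE, FALSE),
                        PR = c(TRUE, FALSE), Ki67 = c(TRUE, FALSE))
  tb <- data.frame(label = seq_len(nrow(combos)),
                   pos.HER2 = combos$HER2, pos.ER = combos$ER,
                   pos.PR = combos$PR, pos.Ki67 = combos$Ki67)
  out <- classifyPhenotypes(tb, mosaicRules())
  expect_false(any(out$phenotype == "other"))
  nPos <- rowSums(combos)
  expect_true(all(out$phenotype[nPos >= 2] == "multi_marker"))
  expect_true(all(out$phenotype[nPos == 0] == "quad_negative"))
  expect_identical(out$phenotype[combos$HER2 & nPos == 1], "her2_only")
})
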