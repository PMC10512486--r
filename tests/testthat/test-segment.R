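params_fixed <- function(thr, ...) segmentation_params(
  smoothing_sigma_px = 0, threshold_mode = "fixed", fixed_threshold = thr,
  min_nucleus_area_px = 5, min_cell_area_px = 5, ...)

test_that("constant images yield zero labels, not errors", {
  z <- matrix(0, 64, 64)
  labs <- segment_nuclei(z, segmentation_params(0, "otsu"))
  expect_identical(max(labs), 0L)
  labs <- segment_nuclei(z + 7, segmentation_params(0, "otsu"))
  expect_identical(max(labs), 0L)
})

test_that("separated bright disks match the flood-fill oracle exactly", {
  img <- matrix(10, 64, 64)
  img <- paint_disk(img, c(20, 17), 6, 1000)
  img <- paint_disk(img, c(20, 47), 6, 1000)
  labs <- segment_nuclei(img, params_fixed(500))
  oracle <- flood_fill_label(img > 500)
  expect_identical(max(labs), 2L)
  expect_identical(sort(unname(label_areas(labs))),
                   sort(unname(label_areas(oracle))))
  # identical partition up to label naming
  expect_identical(labs > 0L, oracle > 0L)
})

test_that("touching disks are split by the distance-transform watershed", {
  img <- matrix(10, 64, 64)
  img <- paint_disk(img, c(32, 26), 8, 1000)
  img <- paint_disk(img, c(32, 38), 8, 1000)
  mask <- img > 500
  labs <- segment_nuclei(img, params_fixed(500))
  expect_identical(max(labs), 2L)
  # oracle: the true distance transform has exactly two regional-max clusters
  d <- brute_distmap(mask)
  expect_identical(regional_max_clusters(d, mask), 2L)
  # each label contains one of the two distance peaks (the disk centres)
  expect_true(labs[32, 26] != labs[32, 38])
  expect_true(all(labs[mask] > 0L))
})

test_that("label counts and areas match the oracle on many toy configurations", {
  # >= 20 disk/blob layouts: varying radii, counts and touching pairs
  set.seed(11)
  configs <- 0
  for (rad in 3:7) {
    for (k in 1:2) {
      img <- matrix(0, 72, 72)
      centers <- list(c(20, 20), c(20, 52), c(52, 20), c(52, 52))[1:(k + 1)]
      for (ct in centers) img <- paint_disk(img, ct, rad, 800)
      labs <- segment_nuclei(img, params_fixed(400))
      oracle <- flood_fill_label(img > 400)
      expect_identical(max(labs), max(oracle))
      expect_identical(sort(unname(label_areas(labs))),
                       sort(unname(label_areas(oracle))))
      configs <- configs + 1
    }
  }
  # irregular blobs: union of offset disks (still one component each)
  for (i in 1:10) {
    img <- matrix(0, 72, 72)
    c0 <- c(sample(20:50, 1), sample(20:50, 1))
    img <- paint_disk(img, c0, 6, 800)
    img <- paint_disk(img, c0 + c(3, 4), 5, 800)
    labs <- segment_nuclei(img, params_fixed(400))
    oracle <- flood_fill_label(img > 400)
    expect_identical(max(labs), max(oracle))
    expect_identical(sort(unname(label_areas(labs))),
                     sort(unname(label_areas(oracle))))
    configs <- configs + 1
  }
  expect_gte(configs, 20)
})

test_that("segment_cells with no nuclei returns empty maps", {
  out <- segment_cells(matrix(500, 32, 32), matrix(0L, 32, 32),
                       params_fixed(100))
  expect_identical(max(out$cell_labels), 0L)
  expect_identical(max(out$nuclei_labels), 0L)
})

test_that("one nucleus in one blob claims the blob plus the nucleus", {
  img <- matrix(10, 64, 64)
  img <- paint_disk(img, c(32, 32), 12, 900)
  nuc <- matrix(0L, 64, 64)
  nuc <- paint_disk(nuc, c(32, 32), 4, 1L)
  storage.mode(nuc) <- "integer"
  out <- segment_cells(img, nuc, params_fixed(450))
  oracle <- flood_fill_label(img > 450) > 0 | nuc > 0
  expect_identical(max(out$cell_labels), 1L)
  expect_identical(out$cell_labels > 0L, oracle)
  # a foreground blob without any nucleus is discarded
  img2 <- paint_disk(img, c(12, 52), 6, 900)
  out2 <- segment_cells(img2, nuc, params_fixed(450))
  expect_identical(max(out2$cell_labels), 1L)
  expect_identical(out2$cell_labels[12, 52], 0L)
})

test_that("two nuclei in one blob partition it by proximity", {
  img <- matrix(10, 64, 80)
  for (cc in 28:52) img <- paint_disk(img, c(32, cc), 10, 900)
  nuc <- matrix(0L, 64, 80)
  nuc <- paint_disk(nuc, c(32, 28), 3, 1L)
  nuc <- paint_disk(nuc, c(32, 52), 3, 2L)
  storage.mode(nuc) <- "integer"
  out <- segment_cells(img, nuc, params_fixed(450))
  blob <- img > 450
  expect_identical(max(out$cell_labels), 2L)
  # partition: disjoint, union = blob, one nucleus each with equal label
  expect_identical(out$cell_labels > 0L, blob)
  for (l in 1:2) {
    nlab <- unique(out$nuclei_labels[out$nuclei_labels > 0L &
                                       out$cell_labels == l])
    expect_identical(nlab, l)
  }
  # symmetric geometry: the two halves are equal-sized up to the midline
  areas <- label_areas(out$cell_labels)
  expect_lte(abs(areas[["1"]] - areas[["2"]]), sum(blob[, 40]))
  # nearest-seed property away from the midline
  expect_true(all(out$cell_labels[, 1:38][blob[, 1:38]] == 1L))
  expect_true(all(out$cell_labels[, 42:80][blob[, 42:80]] == 2L))
})

test_that("undersized cells are dropped together with their nucleus", {
  img <- matrix(10, 64, 64)
  img <- paint_disk(img, c(20, 20), 10, 900)   # big blob
  nuc <- matrix(0L, 64, 64)
  nuc <- paint_disk(nuc, c(20, 20), 3, 1L)
  nuc <- paint_disk(nuc, c(48, 48), 3, 2L)     # nucleus with no blob
  storage.mode(nuc) <- "integer"
  p <- segmentation_params(0, "fixed", 450, min_nucleus_area_px = 5,
                           min_cell_area_px = 100)
  out <- segment_cells(img, nuc, p)
  # nucleus 2's "cell" is just the nucleus (< 100 px) and is removed
  expect_identical(max(out$cell_labels), 1L)
  expect_identical(sort(unique(out$nuclei_labels[out$nuclei_labels > 0L])), 1L)
  # bijection with equal label values
  expect_identical(sort(unique(out$cell_labels[out$cell_labels > 0L])),
                   sort(unique(out$nuclei_labels[out$nuclei_labels > 0L])))
})

test_that("perinuclear zones follow the dilation-minus-nucleus definition", {
  expect_error(perinuclear_zones(matrix(0L, 8, 8), matrix(0L, 8, 8), 0),
               "ring_width_px")
  nuc <- matrix(0L, 21, 21); nuc[10, 10] <- 1L
  cell <- matrix(1L, 21, 21)
  z <- perinuclear_zones(nuc, cell, 1)
  idx <- which(z == 1L, arr.ind = TRUE)
  expect_identical(nrow(idx), 8L)  # radius-1 disk = 8-neighbourhood
  expect_true(all(abs(idx[, 1] - 10) <= 1 & abs(idx[, 2] - 10) <= 1))
  # oracle equivalence at larger widths
  z5 <- perinuclear_zones(nuc, cell, 5)
  oracle <- brute_dilate(nuc > 0, 5) & !(nuc > 0)
  expect_identical(z5 > 0L, oracle)
  # clipping: ring pixels outside the cell are absent
  cell2 <- matrix(0L, 21, 21); cell2[1:21, 1:10] <- 1L
  z2 <- perinuclear_zones(nuc, cell2, 3)
  expect_true(all(which(z2 > 0L, arr.ind = TRUE)[, 2] <= 10))
  # nucleus without a cell names the label
  nuc2 <- nuc; nuc2[3, 3] <- 2L
  expect_error(perinuclear_zones(nuc2, cell2, 2), "label 2")
})

test_that("border-cell filtering removes exactly the touching cells", {
  cell <- matrix(0L, 40, 40)
  cell <- paint_disk(cell, c(10, 10), 4, 1L)
  cell <- paint_disk(cell, c(10, 30), 4, 2L)
  cell <- paint_disk(cell, c(38, 20), 4, 3L)   # touches last row
  storage.mode(cell) <- "integer"
  nuc <- matrix(0L, 40, 40)
  nuc[10, 10] <- 1L; nuc[10, 30] <- 2L; nuc[37, 20] <- 3L
  out <- filter_border_cells(cell, nuc)
  expect_identical(max(out$cell_labels), 2L)
  expect_identical(max(out$nuclei_labels), 2L)
  # no-op case is identity up to relabelling
  inner <- filter_border_cells(out$cell_labels, out$nuclei_labels)
  expect_identical(inner$cell_labels, out$cell_labels)
  # all-border case empties both maps
  allb <- matrix(1L, 10, 10)
  out2 <- filter_border_cells(allb, allb)
  expect_identical(max(out2$cell_labels), 0L)
})

test_that("segmentation recovers true cell areas on synthetic fields", {
  sp <- default_seg_params()
  lay <- random_field_specs(9, "stellate", seed = 21)
  # noiseless: exact recovery
  fld <- generate_field(lay$specs, lay$shape, 0, 100, seed = 21)
  nuc <- segment_nuclei(fld$channels$nuclei, sp$nuclei)
  seg <- segment_cells(fld$channels$vimentin, nuc, sp$cells)
  ids <- match_to_truth(seg$nuclei_labels, fld$truth)
  areas <- label_areas(seg$cell_labels)
  truth_areas <- fld$truth$cell_table$cell_area_px[ids]
  expect_identical(unname(areas), truth_areas)
  # 5% noise: per-cell error <= 5%
  fldn <- generate_field(lay$specs, lay$shape, 250, 100, seed = 22)
  nucn <- segment_nuclei(fldn$channels$nuclei, sp$nuclei)
  segn <- segment_cells(fldn$channels$vimentin, nucn, sp$cells)
  idsn <- match_to_truth(segn$nuclei_labels, fldn$truth)
  areasn <- unname(label_areas(segn$cell_labels))
  truthn <- fldn$truth$cell_table$cell_area_px[idsn]
  expect_identical(length(areasn), 9L)
  expect_true(all(abs(areasn - truthn) / truthn <= 0.05))
})

test_that("cell supports are pairwise disjoint and paired with nuclei", {
  lay <- random_field_specs(6, "flat", seed = 31)
  fld <- generate_field(lay$specs, lay$shape, 100, 100, seed = 31)
  sp <- default_seg_params()
  nuc <- segment_nuclei(fld$channels$nuclei, sp$nuclei)
  seg <- segment_cells(fld$channels$vimentin, nuc, sp$cells)
  labs <- sort(unique(seg$cell_labels[seg$cell_labels > 0L]))
  expect_identical(labs, seq_along(labs))   # contiguous 1..n
  for (l in labs) {
    inside <- unique(seg$nuclei_labels[seg$cell_labels == l])
    expect_identical(sort(setdiff(inside, 0L)), l)
  }
})
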