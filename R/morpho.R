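#' Decompose a cell mask into soma and processes
#'
#' The soma candidate is the morphological opening of the cell mask with a
#' disk of `opening_radius_px` (erosion then dilation, package disk
#' convention), restricted to the connected component containing — or, if
#' none contains it, nearest to — the nucleus centroid. If the opening is
#' empty (a cell thinner than the disk everywhere), the fallback soma is the
#' nucleus dilated by 2 px intersected with the cell. Processes are the rest
#' of the cell.
#'
#' @param cell_mask,nucleus_mask logical matrices; the nucleus must intersect
#'   the cell.
#' @param opening_radius_px disk radius of the opening, integer `>= 1`.
#' @return list with logical `soma` and `process` masks
#'   (`soma | process == cell_mask`, disjoint).
#' @export
decompose_soma_processes <- function(cell_mask, nucleus_mask,
                                     opening_radius_px = 4L) {
  cell_mask <- cell_mask != 0
  nucleus_mask <- nucleus_mask != 0
  stopifnot(identical(dim(cell_mask), dim(nucleus_mask)),
            opening_radius_px >= 1)
  if (!any(cell_mask)) stop("empty cell mask")
  if (!any(cell_mask & nucleus_mask)) stop("nucleus outside cell")
  shape <- dim(cell_mask)
  nidx <- which(nucleus_mask, arr.ind = TRUE)
  centroid <- round(colMeans(nidx))

  opened <- as_matrix(EBImage::opening(cell_mask + 0,
                                       disk_kernel(opening_radius_px))) > 0
  opened <- opened & cell_mask
  if (any(opened)) {
    comps <- as_matrix(EBImage::bwlabel(opened))
    lab_at <- comps[centroid[1], centroid[2]]
    if (lab_at == 0) {
      oidx <- which(comps > 0, arr.ind = TRUE)
      d2 <- (oidx[, 1] - centroid[1])^2 + (oidx[, 2] - centroid[2])^2
      lab_at <- comps[oidx[which.min(d2), , drop = FALSE]]
    }
    soma <- comps == lab_at
  } else {
    dil <- dilate_coords(nidx, 2L, shape)
    soma <- matrix(FALSE, shape[1], shape[2])
    soma[dil] <- TRUE
    soma <- soma & cell_mask
  }
  list(soma = soma, process = cell_mask & !soma)
}

#' Measure one cell
#'
#' Areas are pixel counts; the process perimeter is the exposed 4-neighbour
#' edge count of the process mask ([exposed_edge_count()]); perinuclear GFAP
#' is the mean GFAP over the ring zone; Vimentin is the mean over the full
#' cell mask (NA when the channel is absent).
#'
#' @param cell_id integer label.
#' @param masks list with logical `cell`, `soma`, `process`, `perinuclear`
#'   masks; `soma` and `process` must partition `cell`.
#' @param channels a `channel_stack`.
#' @param nucleus_centroid optional `(row, col)` carried into the record.
#' @return one-row data frame (a CellRecord).
#' @export
measure_cell <- function(cell_id, masks, channels,
                         nucleus_centroid = c(NA_real_, NA_real_)) {
  cell <- masks$cell != 0; soma <- masks$soma != 0
  proc <- masks$process != 0; ring <- masks$perinuclear != 0
  if (any(soma & proc) || !identical(soma | proc, cell))
    stop("soma and process masks must partition the cell mask")
  if (!any(ring))
    stop("empty perinuclear zone for cell ", cell_id)
  data.frame(
    cell_id = as.integer(cell_id),
    nucleus_row = nucleus_centroid[1],
    nucleus_col = nucleus_centroid[2],
    cell_area_px = sum(cell),
    soma_area_px = sum(soma),
    process_area_px = sum(proc),
    process_perimeter_px = exposed_edge_count(proc),
    perinuclear_gfap_mean = mean(channels$gfap[ring]),
    vimentin_mean = if (is.null(channels$vimentin)) NA_real_
                    else mean(channels$vimentin[cell]),
    gfap_positive = NA)
}

#' Measure every cell of a segmented field
#'
#' Runs [decompose_soma_processes()] and [measure_cell()] per label on local
#' bounding boxes. Cells with an empty perinuclear zone are dropped with a
#' warning naming them.
#'
#' @param channels a `channel_stack`.
#' @param cell_labels,nuclei_labels paired label maps from [segment_cells()].
#' @param zones ring label map from [perinuclear_zones()].
#' @param opening_radius_px soma opening radius.
#' @return data frame of CellRecords (possibly zero rows).
#' @export
measure_cells <- function(channels, cell_labels, nuclei_labels, zones,
                          opening_radius_px = 4L) {
  labs <- sort(unique(cell_labels[cell_labels > 0L]))
  shape <- dim(cell_labels)
  records <- list()
  dropped <- integer(0)
  for (l in labs) {
    idx <- which(cell_labels == l, arr.ind = TRUE)
    pad <- opening_radius_px + 2L
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(shape[1], max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(shape[2], max(idx[, 2]) + pad)
    cl <- cell_labels[r0:r1, c0:c1] == l
    nl <- nuclei_labels[r0:r1, c0:c1] == l
    zl <- zones[r0:r1, c0:c1] == l
    if (!any(zl)) { dropped <- c(dropped, l); next }
    dec <- decompose_soma_processes(cl, nl, opening_radius_px)
    sub_ch <- list(gfap = channels$gfap[r0:r1, c0:c1],
                   vimentin = if (!is.null(channels$vimentin))
                     channels$vimentin[r0:r1, c0:c1])
    nidx <- which(nuclei_labels == l, arr.ind = TRUE)
    records[[length(records) + 1L]] <- measure_cell(
      l, list(cell = cl, soma = dec$soma, process = dec$process,
              perinuclear = zl),
      sub_ch, nucleus_centroid = colMeans(nidx))
  }
  if (length(dropped))
    warning("dropped cells with empty perinuclear zone: ",
            paste(dropped, collapse = ", "))
  if (!length(records)) return(data.frame())
  do.call(rbind, records)
}

#' Classify cells as GFAP-positive from perinuclear means
#'
#' In `"fixed"` mode a cell is positive when its perinuclear GFAP mean
#' exceeds `fixed_threshold`. In `"otsu"` mode the threshold is computed once
#' over the pooled per-cell means of the whole analysis batch (all fields of
#' a condition), by exhaustive minimization of the within-class sum of
#' squares — pool records across fields before calling.
#'
#' @param records data frame of CellRecords (>= 1 row).
#' @param mode `"fixed"` or `"otsu"`.
#' @param fixed_threshold required iff `mode = "fixed"`.
#' @return `records` with `gfap_positive` filled; the threshold used is
#'   attached as attribute `"threshold"`.
#' @export
classify_gfap_positive <- function(records, mode = c("fixed", "otsu"),
                                   fixed_threshold = NULL) {
  mode <- match.arg(mode)
  if (nrow(records) < 1) stop("no cell records")
  if (mode == "fixed") {
    if (is.null(fixed_threshold)) stop("fixed_threshold required")
    thr <- fixed_threshold
  } else {
    if (!is.null(fixed_threshold))
      stop("fixed_threshold must be NULL in otsu mode")
    thr <- otsu_threshold_values(records$perinuclear_gfap_mean)
  }
  records$gfap_positive <- records$perinuclear_gfap_mean > thr
  attr(records, "threshold") <- thr
  records
}

#' Field-level summed-ratio morphometric summary
#'
#' Ratios are computed from field-level sums, not means of per-cell ratios:
#' soma/cell area, process/soma area, process/cell area and process
#' perimeter/cell area. By default the morphology sums run over
#' GFAP-positive cells only (the mature subpopulation); the GFAP+ fraction
#' always uses all cells.
#'
#' @param records classified CellRecords ([classify_gfap_positive()]).
#' @param gfap_positive_only_for_morphology restrict morphology sums to
#'   GFAP+ cells.
#' @return one-row data frame (a FieldSummary).
#' @export
summarize_field <- function(records, gfap_positive_only_for_morphology = TRUE) {
  if (nrow(records) < 1) stop("no cell records to summarize")
  morpho <- records
  if (isTRUE(gfap_positive_only_for_morphology)) {
    if (!any(records$gfap_positive %in% TRUE))
      stop("no GFAP-positive cells; cannot compute restricted morphology")
    morpho <- records[records$gfap_positive %in% TRUE, , drop = FALSE]
  }
  s_cell <- sum(morpho$cell_area_px)
  s_soma <- sum(morpho$soma_area_px)
  s_proc <- sum(morpho$process_area_px)
  s_per <- sum(morpho$process_perimeter_px)
  data.frame(
    n_cells = nrow(records),
    gfap_positive_fraction = mean(records$gfap_positive %in% TRUE),
    soma_to_cell = s_soma / s_cell,
    process_to_soma = s_proc / s_soma,
    process_to_cell = s_proc / s_cell,
    process_perimeter_to_cell = s_per / s_cell)
}
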