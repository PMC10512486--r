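#' Segmentation parameter set
#'
#' Parameters shared by nucleus and cell segmentation. Thresholding is Otsu
#' on the smoothed image by default; `"fixed"` mode applies a user threshold
#' and is the reproducible choice for synthetic fields rendered without PSF
#' blur.
#'
#' @param smoothing_sigma_px Gaussian smoothing sigma in pixels (`0` disables
#'   smoothing).
#' @param threshold_mode `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold value; required iff
#'   `threshold_mode = "fixed"`.
#' @param min_nucleus_area_px minimum nucleus area kept, pixels.
#' @param min_cell_area_px minimum cell area kept, pixels.
#' @param ring_width_px perinuclear ring width, pixels.
#' @param exclude_border drop cells touching the field border.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma_px = 2,
                                threshold_mode = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_nucleus_area_px = 30L,
                                min_cell_area_px = 100L,
                                ring_width_px = 5L,
                                exclude_border = TRUE) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(smoothing_sigma_px >= 0, min_nucleus_area_px >= 1,
            min_cell_area_px >= 1, ring_width_px >= 1,
            is.logical(exclude_border))
  if (threshold_mode == "fixed" &&
      (is.null(fixed_threshold) || !is.finite(fixed_threshold)))
    stop("fixed_threshold is required when threshold_mode = 'fixed'")
  if (threshold_mode == "otsu" && !is.null(fixed_threshold))
    stop("fixed_threshold must be NULL when threshold_mode = 'otsu'")
  structure(list(smoothing_sigma_px = smoothing_sigma_px,
                 threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold,
                 min_nucleus_area_px = as.integer(min_nucleus_area_px),
                 min_cell_area_px = as.integer(min_cell_area_px),
                 ring_width_px = as.integer(ring_width_px),
                 exclude_border = isTRUE(exclude_border)),
            class = "segmentation_params")
}

.smooth_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as_matrix(EBImage::gblur(img, sigma = sigma))
}

.threshold_image <- function(img, params) {
  if (params$threshold_mode == "fixed") return(img > params$fixed_threshold)
  mx <- max(img)
  if (mx <= min(img)) return(matrix(FALSE, nrow(img), ncol(img)))
  t01 <- EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1),
                       levels = 256)
  img / mx > t01
}

#' Segment nuclei from the Hoechst channel
#'
#' Gaussian smoothing, thresholding, then a watershed on the Euclidean
#' distance transform to split touching nuclei; components smaller than
#' `min_nucleus_area_px` are removed and labels renumbered `1..n`. A constant
#' image under Otsu yields zero labels, not an error.
#'
#' @param nuclei nonnegative intensity matrix.
#' @param params a [segmentation_params()].
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(nuclei, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"),
            is.matrix(nuclei), length(nuclei) > 0, all(is.finite(nuclei)))
  mask <- .threshold_image(.smooth_image(nuclei, params$smoothing_sigma_px),
                           params)
  if (!any(mask)) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  d <- EBImage::distmap(mask)
  labs <- as_matrix(EBImage::watershed(d, tolerance = 1, ext = 1))
  storage.mode(labs) <- "integer"
  areas <- label_areas(labs)
  keep <- as.integer(names(areas)[areas >= params$min_nucleus_area_px])
  relabel_maps(list(labs), keep)[[1]]
}

#' Segment nucleus-anchored cell territories from a cytoplasmic marker
#'
#' Foreground is the smoothed marker above threshold, unioned with the
#' nucleus supports; it is partitioned among the nuclei by seeded propagation
#' (a watershed on the smoothed marker restricted to the foreground), so each
#' cell label contains exactly one nucleus label with the same value.
#' Foreground components containing no nucleus are discarded; cells smaller
#' than `min_cell_area_px` are dropped together with their nucleus and the
#' remaining labels renumbered `1..n` consistently across both maps.
#'
#' @param marker cytoplasmic intensity matrix (e.g. Vimentin or GFAP).
#' @param nuclei_labels nucleus label matrix from [segment_nuclei()].
#' @param params a [segmentation_params()].
#' @return list with `cell_labels` and `nuclei_labels`, in one-to-one
#'   correspondence with equal label values.
#' @export
segment_cells <- function(marker, nuclei_labels,
                          params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"),
            identical(dim(marker), dim(nuclei_labels)))
  empty <- matrix(0L, nrow(marker), ncol(marker))
  if (max(nuclei_labels) == 0L)
    return(list(cell_labels = empty, nuclei_labels = empty))
  sm <- .smooth_image(marker, params$smoothing_sigma_px)
  fg <- .threshold_image(sm, params) | nuclei_labels > 0L
  cells <- as_matrix(EBImage::propagate(EBImage::Image(sm / max(sm, 1)),
                                        seeds = nuclei_labels,
                                        mask = fg, lambda = 1e-4))
  storage.mode(cells) <- "integer"
  areas <- label_areas(cells)
  keep <- as.integer(names(areas)[areas >= params$min_cell_area_px])
  out <- relabel_maps(list(cells, nuclei_labels), keep)
  list(cell_labels = out[[1]], nuclei_labels = out[[2]])
}

#' Perinuclear ring zones
#'
#' For each nucleus, the zone is the nucleus dilated by a disk of radius
#' `ring_width_px` minus the nucleus itself, intersected with that nucleus's
#' cell support; the zone carries the cell label. The disk convention is the
#' package-wide one ([disk_offsets()]): radius 1 equals the 8-neighbourhood.
#'
#' @param nuclei_labels,cell_labels matching label maps with equal label sets.
#' @param ring_width_px ring width, integer `>= 1`.
#' @return integer label matrix of ring zones.
#' @export
perinuclear_zones <- function(nuclei_labels, cell_labels, ring_width_px = 5L) {
  if (ring_width_px < 1) stop("ring_width_px must be >= 1")
  stopifnot(identical(dim(nuclei_labels), dim(cell_labels)))
  shape <- dim(nuclei_labels)
  zones <- matrix(0L, shape[1], shape[2])
  for (l in sort(unique(nuclei_labels[nuclei_labels > 0L]))) {
    if (!any(cell_labels == l))
      stop("nucleus label ", l, " has no matching cell")
    idx <- which(nuclei_labels == l, arr.ind = TRUE)
    dil <- dilate_coords(idx, ring_width_px, shape)
    ring <- dil[nuclei_labels[dil] != l & cell_labels[dil] == l, ,
                drop = FALSE]
    zones[ring] <- l
  }
  zones
}

#' Remove cells touching the field border
#'
#' Any cell whose support touches the first or last row/column is removed
#' together with its nucleus; remaining labels are renumbered `1..n`
#' consistently across both maps.
#'
#' @param cell_labels,nuclei_labels matching label maps.
#' @return list with filtered `cell_labels` and `nuclei_labels`.
#' @export
filter_border_cells <- function(cell_labels, nuclei_labels) {
  stopifnot(identical(dim(cell_labels), dim(nuclei_labels)))
  border <- c(cell_labels[1, ], cell_labels[nrow(cell_labels), ],
              cell_labels[, 1], cell_labels[, ncol(cell_labels)])
  bad <- unique(border[border > 0L])
  keep <- setdiff(unique(cell_labels[cell_labels > 0L]), bad)
  out <- relabel_maps(list(cell_labels, nuclei_labels), keep)
  list(cell_labels = out[[1]], nuclei_labels = out[[2]])
}
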