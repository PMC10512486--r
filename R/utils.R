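#' Disk structuring-element offsets
#'
#' Offsets `(dr, dc)` of the disk of radius `r` used for every dilation,
#' erosion and opening in the package: pixels whose squared Euclidean distance
#' from the centre is at most `r^2 + 1`. The slack of 1 makes the radius-1
#' disk the full 8-neighbourhood (plus centre), matching the package-wide
#' 8-connectivity convention.
#'
#' @param r integer radius >= 0.
#' @return integer matrix with columns `dr`, `dc` (includes the centre).
#' @keywords internal
disk_offsets <- function(r) {
  r <- as.integer(r)
  stopifnot(length(r) == 1L, r >= 0L)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1, , drop = FALSE]
  as.matrix(g)
}

#' Disk structuring element as a 0/1 kernel matrix
#' @param r integer radius >= 1.
#' @return (2r+1) x (2r+1) numeric 0/1 matrix.
#' @keywords internal
disk_kernel <- function(r) {
  off <- disk_offsets(r)
  k <- matrix(0, 2L * r + 1L, 2L * r + 1L)
  k[cbind(off[, "dr"] + r + 1L, off[, "dc"] + r + 1L)] <- 1
  k
}

#' Dilate a set of pixel coordinates by a disk
#'
#' @param idx two-column matrix of (row, col) pixel coordinates.
#' @param r disk radius.
#' @param shape field dimensions c(rows, cols); results are clipped to bounds.
#' @return two-column matrix of unique dilated coordinates.
#' @keywords internal
dilate_coords <- function(idx, r, shape) {
  if (nrow(idx) == 0L) return(idx)
  off <- disk_offsets(r)
  rr <- rep(idx[, 1L], each = nrow(off)) + rep(off[, "dr"], times = nrow(idx))
  cc <- rep(idx[, 2L], each = nrow(off)) + rep(off[, "dc"], times = nrow(idx))
  keep <- rr >= 1L & rr <= shape[1L] & cc >= 1L & cc <= shape[2L]
  unique(cbind(rr[keep], cc[keep]))
}

#' Relabel a label map so labels form the contiguous range 1..n
#'
#' @param map integer matrix, 0 = background.
#' @return integer matrix with the same support, labels renumbered in
#'   ascending order of the original labels.
#' @keywords internal
relabel_map <- function(map) {
  labs <- sort(unique(map[map > 0L]))
  if (length(labs) == 0L) {
    storage.mode(map) <- "integer"
    return(map)
  }
  lut <- integer(max(labs))
  lut[labs] <- seq_along(labs)
  out <- map
  pos <- map > 0L
  out[pos] <- lut[map[pos]]
  storage.mode(out) <- "integer"
  out
}

#' Apply one old-label -> new-label mapping to several maps consistently
#' @keywords internal
relabel_maps <- function(maps, keep_labels) {
  keep_labels <- sort(keep_labels)
  lut <- integer(if (length(keep_labels)) max(keep_labels) else 0L)
  lut[keep_labels] <- seq_along(keep_labels)
  lapply(maps, function(m) {
    out <- m
    pos <- m > 0L
    drop <- pos & !(m %in% keep_labels)
    out[drop] <- 0L
    pos <- out > 0L
    out[pos] <- lut[out[pos]]
    storage.mode(out) <- "integer"
    out
  })
}

#' Pixel areas of every label in a label map
#' @return named integer vector, names = label values present.
#' @keywords internal
label_areas <- function(map) {
  v <- map[map > 0L]
  if (length(v) == 0L) return(integer(0))
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))
}

#' Count exposed pixel edges of a binary mask
#'
#' The perimeter convention used throughout: the number of 4-neighbour pixel
#' edges between a foreground pixel and background (the image border counts
#' as background). Exact integer, e.g. a solid 10x10 square has 40.
#'
#' @param mask logical matrix.
#' @return integer edge count.
#' @export
exposed_edge_count <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  if (sum(mask) == 0L) return(0L)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up    <- pad[1:nr, 2:(nc + 1L)]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left  <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  as.integer(sum(core & !up) + sum(core & !down) +
             sum(core & !left) + sum(core & !right))
}

#' Exhaustive Otsu threshold for a vector of values
#'
#' Minimizes the pooled within-class sum of squares over all midpoints between
#' consecutive sorted unique values. Used to call GFAP-positive cells from
#' pooled perinuclear means.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return the threshold (scalar).
#' @keywords internal
otsu_threshold_values <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L)
    stop("Otsu threshold undefined: fewer than 2 distinct values")
  cand <- (u[-length(u)] + u[-1L]) / 2
  wss <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    s <- 0
    if (length(lo) > 1L) s <- s + sum((lo - mean(lo))^2)
    if (length(hi) > 1L) s <- s + sum((hi - mean(hi))^2)
    s
  }, numeric(1))
  cand[which.min(wss)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  m <- as.matrix(x)
  dim(m) <- dim(m)[1:2]
  m
}
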