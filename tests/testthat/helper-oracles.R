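# Independent brute-force oracles. These deliberately use naive loops and
# never call the package's own primitives, so they can certify them.

# 8-connected flood-fill labelling of a binary mask.
flood_fill_label <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Disk used by the oracles: same published convention (d^2 <= r^2 + 1),
# recoded independently.
oracle_disk <- function(r) {
  pts <- list()
  for (dr in -r:r) for (dc in -r:r)
    if (dr * dr + dc * dc <= r * r + 1) pts[[length(pts) + 1]] <- c(dr, dc)
  do.call(rbind, pts)
}

brute_dilate <- function(mask, r) {
  mask <- mask != 0
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  off <- oracle_disk(r)
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) for (j in seq_len(nrow(off))) {
    rr <- idx[i, 1] + off[j, 1]; cc <- idx[i, 2] + off[j, 2]
    if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask))
      out[rr, cc] <- TRUE
  }
  out
}

brute_erode <- function(mask, r) {
  mask <- mask != 0
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  off <- oracle_disk(r)
  for (rr in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    keep <- TRUE
    for (j in seq_len(nrow(off))) {
      r2 <- rr + off[j, 1]; c2 <- cc + off[j, 2]
      if (r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask) ||
          !mask[r2, c2]) { keep <- FALSE; break }
    }
    if (keep) out[rr, cc] <- TRUE
  }
  out
}

brute_open <- function(mask, r) brute_dilate(brute_erode(mask, r), r)

# Exact Euclidean distance-to-background transform (quadratic scan).
brute_distmap <- function(mask) {
  mask <- mask != 0
  bg <- which(!mask, arr.ind = TRUE)
  d <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    d[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  d
}

# Clusters of 8-connected regional maxima of a distance map.
regional_max_clusters <- function(d, mask) {
  nr <- nrow(d); nc <- ncol(d)
  is_max <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          d[rr, cc] > d[r, c]) ok <- FALSE
    }
    is_max[r, c] <- ok
  }
  max(flood_fill_label(is_max))
}

# Step-up BH adjustment, literal formula.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, p[o[i]] * m / i)
    q[o[i]] <- min(1, run_min)
  }
  q
}

# Two-way balanced ANOVA from explicit group-mean sums of squares.
anova_ss_oracle <- function(values, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B)
  n <- length(values) / (a * b)
  gm <- mean(values)
  mA <- tapply(values, A, mean)
  mB <- tapply(values, B, mean)
  mAB <- tapply(values, interaction(A, B), mean)
  ss_a <- n * b * sum((mA - gm)^2)
  ss_b <- n * a * sum((mB - gm)^2)
  cell_of <- interaction(A, B)
  ss_res <- sum((values - mAB[as.character(cell_of)])^2)
  ss_ab <- sum((values - gm)^2) - ss_a - ss_b - ss_res
  df_res <- a * b * (n - 1)
  ms_res <- ss_res / df_res
  list(F_a = (ss_a / (a - 1)) / ms_res,
       F_b = (ss_b / (b - 1)) / ms_res,
       F_ab = (ss_ab / ((a - 1) * (b - 1))) / ms_res,
       p_a = stats::pf((ss_a / (a - 1)) / ms_res, a - 1, df_res,
                       lower.tail = FALSE))
}

# Exhaustive simplex grid search for a 3-type NNLS proportion fit.
simplex_grid3 <- function(S, b, res = 0.01) {
  best <- NULL; best_val <- Inf
  for (p1 in seq(0, 1, res)) {
    for (p2 in seq(0, 1 - p1, res)) {
      p <- c(p1, p2, 1 - p1 - p2)
      v <- sum((S %*% p - b)^2)
      if (v < best_val) { best_val <- v; best <- p }
    }
  }
  best
}

# Disk raster used to build toy nuclei/blob images.
paint_disk <- function(img, center, radius, value) {
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img)))
    if ((r - center[1])^2 + (c - center[2])^2 <= radius^2)
      img[r, c] <- value
  img
}

# Match segmented cell labels to truth cell ids by nucleus-pixel majority.
match_to_truth <- function(nuclei_labels, truth) {
  labs <- sort(unique(nuclei_labels[nuclei_labels > 0L]))
  vapply(labs, function(l) {
    px <- truth$cell_labels[nuclei_labels == l]
    as.integer(names(sort(table(px[px > 0]), decreasing = TRUE))[1])
  }, integer(1))
}

# Small labelled single-cell reference: 3 subjects x 2 cell types.
toy_sc <- function(seed = 2, genes = 40, per = 5) {
  set.seed(seed)
  base <- matrix(rexp(genes * 2, rate = 1 / 50), genes, 2,
                 dimnames = list(paste0("g", 1:genes), c("astro", "neuron")))
  cells <- list(); types <- c(); subjects <- c()
  for (s in 1:3) for (ty in 1:2) for (i in 1:per) {
    cells[[length(cells) + 1]] <- rpois(genes, base[, ty] * runif(1, 0.5, 2))
    types <- c(types, colnames(base)[ty])
    subjects <- c(subjects, paste0("S", s))
  }
  m <- do.call(cbind, cells)
  rownames(m) <- rownames(base)
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  list(m = m, types = types, subjects = subjects)
}

default_seg_params <- function() {
  list(nuclei = segmentation_params(0, "fixed", 4050),
       cells = segmentation_params(0, "fixed", 1050))
}
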