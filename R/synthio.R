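#' Construct a synthetic cell specification
#'
#' A `cell_spec` describes one astrocyte to be rendered into a field: an
#' elliptical soma, a nucleus disk of radius `0.6 * min(soma_radii)` centred
#' on the cell centre, and `n_processes` straight processes radiating from the
#' soma boundary. Intensities are on an arbitrary 16-bit-like scale.
#'
#' @param center numeric length-2 `(row, col)` centre in pixels (may be `NA`
#'   for presets that are placed later).
#' @param soma_radii numeric length-2 ellipse semi-axes `(a, b)` in pixels,
#'   both `>= 2`.
#' @param orientation soma major-axis orientation, radians.
#' @param n_processes integer `>= 0`.
#' @param process_length process length in pixels, `>= 0`.
#' @param process_width process width in pixels, `>= 1` and
#'   `<= min(soma_radii)`.
#' @param gfap_class `"positive"` or `"negative"`.
#' @param gfap_mean,vimentin_mean,nucleus_mean nonnegative channel intensity
#'   levels rendered inside the corresponding supports.
#' @return an object of class `cell_spec` (a named list).
#' @export
cell_spec <- function(center = c(NA_real_, NA_real_),
                      soma_radii = c(7, 6),
                      orientation = 0,
                      n_processes = 0L,
                      process_length = 0,
                      process_width = 1,
                      gfap_class = c("positive", "negative"),
                      gfap_mean = 5000,
                      vimentin_mean = 2000,
                      nucleus_mean = 8000) {
  gfap_class <- match.arg(gfap_class)
  stopifnot(length(center) == 2L, length(soma_radii) == 2L,
            all(soma_radii >= 2), n_processes >= 0, process_length >= 0,
            process_width >= 1,
            gfap_mean >= 0, vimentin_mean >= 0, nucleus_mean >= 0)
  if (process_width > min(soma_radii))
    stop("process_width must not exceed min(soma_radii)")
  structure(list(center = as.numeric(center),
                 soma_radii = as.numeric(soma_radii),
                 orientation = as.numeric(orientation),
                 n_processes = as.integer(n_processes),
                 process_length = as.numeric(process_length),
                 process_width = as.numeric(process_width),
                 gfap_class = gfap_class,
                 gfap_mean = gfap_mean,
                 vimentin_mean = vimentin_mean,
                 nucleus_mean = nucleus_mean),
            class = "cell_spec")
}

# Default morphology presets. Stellate cells emulate the mature astrocyte
# phenotype (small soma, many long thin processes); "flat" cells emulate the
# fibroblast-like morphology of serum-exposed cultures (large soma, few short
# thick processes). Scale factors are uniform jitter ranges applied per cell.
.astro_presets <- list(
  stellate = list(soma_radii = c(7, 6), radii_scale = c(1.0, 1.25),
                  n_processes = 6L, process_length = 24,
                  length_scale = c(0.9, 1.15), process_width = 2,
                  gfap_mean = 5000, vimentin_mean = 2000, nucleus_mean = 8000),
  flat = list(soma_radii = c(16, 13), radii_scale = c(1.0, 1.25),
              n_processes = 2L, process_length = 12,
              length_scale = c(0.9, 1.15), process_width = 5,
              gfap_mean = 5000, vimentin_mean = 2000, nucleus_mean = 8000)
)

#' Draw a cell specification from a morphology-class preset
#'
#' `"stellate"` presets have a smaller soma and more, longer, thinner
#' processes than `"flat"` presets; the ordering holds for every draw because
#' process count and width are fixed per class while soma radii, process
#' length and orientation carry bounded uniform jitter.
#'
#' @param class_name `"stellate"` or `"flat"`.
#' @param seed optional integer; when given, seeds the RNG before drawing.
#' @param gfap_class `"positive"` or `"negative"`.
#' @return a [cell_spec()] with `NA` centre, to be placed by the caller.
#' @export
morphology_preset <- function(class_name, seed = NULL,
                              gfap_class = "positive") {
  if (!class_name %in% names(.astro_presets))
    stop("unknown morphology class '", class_name, "'; valid classes: ",
         paste(names(.astro_presets), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  p <- .astro_presets[[class_name]]
  cell_spec(center = c(NA_real_, NA_real_),
            soma_radii = p$soma_radii *
              stats::runif(1, p$radii_scale[1], p$radii_scale[2]),
            orientation = stats::runif(1, 0, 2 * pi),
            n_processes = p$n_processes,
            process_length = p$process_length *
              stats::runif(1, p$length_scale[1], p$length_scale[2]),
            process_width = p$process_width,
            gfap_class = gfap_class,
            gfap_mean = p$gfap_mean,
            vimentin_mean = p$vimentin_mean,
            nucleus_mean = p$nucleus_mean)
}

# Maximum in-field reach of a preset cell (soma + process + half width),
# used for collision-free grid placement.
.preset_bound <- function(class_name) {
  p <- .astro_presets[[class_name]]
  ceiling(max(p$soma_radii) * p$radii_scale[2] +
            p$process_length * p$length_scale[2] + p$process_width)
}

#' Place preset cells on a jittered grid
#'
#' Draws `n` cells of one morphology class and places them on a regular grid
#' with spacing that guarantees non-overlap, assigning exactly
#' `round(n * gfap_positive_fraction)` cells the GFAP-positive class.
#'
#' @param n number of cells.
#' @param class_name morphology class passed to [morphology_preset()].
#' @param seed integer seed; all draws (presets, jitter, positive subset) flow
#'   from it.
#' @param gfap_positive_fraction fraction of GFAP+ cells in `[0, 1]`.
#' @return list with `specs` (list of [cell_spec()]) and `shape` (the minimal
#'   field dimensions enclosing the layout).
#' @export
random_field_specs <- function(n, class_name, seed,
                               gfap_positive_fraction = 1) {
  stopifnot(n >= 1, gfap_positive_fraction >= 0, gfap_positive_fraction <= 1)
  set.seed(seed)
  bound <- .preset_bound(class_name)
  spacing <- 2L * bound + 5L
  gc_ <- ceiling(sqrt(n))
  gr_ <- ceiling(n / gc_)
  margin <- bound + 4L
  shape <- c(gr_ * spacing + 2L * margin - spacing,
             gc_ * spacing + 2L * margin - spacing)
  n_pos <- round(n * gfap_positive_fraction)
  pos_idx <- if (n_pos > 0) sample.int(n, n_pos) else integer(0)
  specs <- vector("list", n)
  k <- 0L
  for (i in seq_len(gr_)) {
    for (j in seq_len(gc_)) {
      if (k >= n) break
      k <- k + 1L
      sp <- morphology_preset(class_name,
        gfap_class = if (k %in% pos_idx) "positive" else "negative")
      sp$center <- c(margin + (i - 1L) * spacing + round(stats::runif(1, -2, 2)),
                     margin + (j - 1L) * spacing + round(stats::runif(1, -2, 2)))
      specs[[k]] <- sp
    }
  }
  list(specs = specs, shape = shape)
}

# Render one cell's pixel supports (nucleus, soma, process) as (row, col)
# coordinate matrices. Process angles are drawn from the current RNG stream.
.render_cell <- function(spec, shape) {
  ctr <- spec$center
  a <- spec$soma_radii[1]; b <- spec$soma_radii[2]
  th <- spec$orientation
  reach <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, floor(ctr[1] - reach)); r1 <- min(shape[1], ceiling(ctr[1] + reach))
  c0 <- max(1L, floor(ctr[2] - reach)); c1 <- min(shape[2], ceiling(ctr[2] + reach))
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - ctr[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - ctr[2])
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  soma <- cbind(rep(rows, times = length(cols))[inside],
                rep(cols, each = length(rows))[inside])

  nr <- 0.6 * min(a, b)
  dn <- dr^2 + dc^2 <= nr^2
  nucleus <- cbind(rep(rows, times = length(cols))[dn],
                   rep(cols, each = length(rows))[dn])

  proc <- matrix(integer(0), 0, 2)
  if (spec$n_processes > 0L && spec$process_length > 0) {
    base <- stats::runif(1, 0, 2 * pi)
    angles <- base + 2 * pi * (seq_len(spec$n_processes) - 1) /
      spec$n_processes + stats::rnorm(spec$n_processes, 0, 0.12)
    hw <- spec$process_width / 2
    for (phi in angles) {
      dvec <- c(cos(phi), sin(phi))
      # ellipse support radius along dvec (in the rotated frame)
      uu <- dvec[1] * cos(th) + dvec[2] * sin(th)
      vv <- -dvec[1] * sin(th) + dvec[2] * cos(th)
      rad <- 1 / sqrt((uu / a)^2 + (vv / b)^2)
      p0 <- ctr + 0.8 * rad * dvec
      p1 <- p0 + spec$process_length * dvec
      lo_r <- max(1L, floor(min(p0[1], p1[1]) - hw - 1))
      hi_r <- min(shape[1], ceiling(max(p0[1], p1[1]) + hw + 1))
      lo_c <- max(1L, floor(min(p0[2], p1[2]) - hw - 1))
      hi_c <- min(shape[2], ceiling(max(p0[2], p1[2]) + hw + 1))
      if (lo_r > hi_r || lo_c > hi_c) next
      prows <- lo_r:hi_r; pcols <- lo_c:hi_c
      pr <- rep(prows, times = length(pcols))
      pc <- rep(pcols, each = length(prows))
      # point-to-segment distance
      sx <- p1 - p0
      len2 <- sum(sx^2)
      t <- ((pr - p0[1]) * sx[1] + (pc - p0[2]) * sx[2]) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (pr - (p0[1] + t * sx[1]))^2 + (pc - (p0[2] + t * sx[2]))^2
      keep <- d2 <= hw^2 + 0.25
      proc <- rbind(proc, cbind(pr[keep], pc[keep]))
    }
    if (nrow(proc) > 0) {
      proc <- unique(proc)
      in_soma <- paste(proc[, 1], proc[, 2]) %in% paste(soma[, 1], soma[, 2])
      proc <- proc[!in_soma, , drop = FALSE]
    }
  }
  list(nucleus = nucleus, soma = soma, process = proc)
}

#' Generate a synthetic multi-channel astrocyte field with ground truth
#'
#' Renders each [cell_spec()] into three co-registered channels (nuclei, GFAP,
#' Vimentin) plus pixel-level truth label maps. Channel values are the class
#' intensity inside the corresponding support and `background` elsewhere;
#' additive Gaussian noise with sd `noise_sd` is applied last and clipped at
#' zero. All randomness (process angles, noise) flows from `seed`, so
#' identical calls are bit-identical.
#'
#' GFAP-positive cells carry `gfap_mean` over soma plus processes; negative
#' cells stay at background in the GFAP channel. Vimentin is rendered over the
#' full cell support for every cell (it marks immature and mature astrocytes
#' alike). Processes are clipped at the field border; somata must fit.
#'
#' @param specs list of [cell_spec()] with finite centres.
#' @param shape field dimensions `c(rows, cols)`, at least 64 x 64.
#' @param noise_sd nonnegative Gaussian noise sd.
#' @param background nonnegative background level.
#' @param seed integer seed (mandatory).
#' @param margin non-overlap margin in pixels between rendered cell supports.
#' @return list with `channels` (a `channel_stack`: matrices `nuclei`, `gfap`,
#'   `vimentin`) and `truth` (a `field_truth`: label maps `nuclei_labels`,
#'   `cell_labels`, `soma_labels`, `process_labels` and a `cell_table`
#'   data frame of true per-cell areas, process edge-count perimeters and
#'   GFAP classes).
#' @export
generate_field <- function(specs, shape = c(256, 256), noise_sd = 0,
                           background = 100, seed, margin = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 64), noise_sd >= 0,
            background >= 0)
  if (missing(seed)) stop("seed is mandatory for field generation")
  set.seed(as.integer(seed))
  n <- length(specs)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    if (!inherits(sp, "cell_spec")) stop("specs[[", i, "]] is not a cell_spec")
    if (any(!is.finite(sp$center))) stop("specs[[", i, "]] has no centre")
    reach <- max(sp$soma_radii)
    if (sp$center[1] - reach < 1 || sp$center[1] + reach > shape[1] ||
        sp$center[2] - reach < 1 || sp$center[2] + reach > shape[2])
      stop("specs[[", i, "]]: soma outside field bounds")
  }

  nuclei_lab <- matrix(0L, shape[1], shape[2])
  cell_lab <- matrix(0L, shape[1], shape[2])
  soma_lab <- matrix(0L, shape[1], shape[2])
  proc_lab <- matrix(0L, shape[1], shape[2])
  claim <- matrix(0L, shape[1], shape[2])
  collisions <- list()
  tables <- vector("list", n)

  for (i in seq_len(n)) {
    sp <- specs[[i]]
    parts <- .render_cell(sp, shape)
    cell_idx <- rbind(parts$soma, parts$process)
    guard <- if (margin > 0) dilate_coords(cell_idx, margin, shape) else cell_idx
    hit <- claim[guard]
    if (any(hit > 0L)) {
      others <- sort(unique(hit[hit > 0L]))
      collisions[[length(collisions) + 1L]] <-
        paste0("(", paste(others, collapse = ","), ") vs ", i)
      next
    }
    claim[guard] <- i
    nuclei_lab[parts$nucleus] <- i
    soma_lab[parts$soma] <- i
    if (nrow(parts$process)) proc_lab[parts$process] <- i
    cell_lab[cell_idx] <- i
    pm <- matrix(FALSE, shape[1], shape[2])
    if (nrow(parts$process)) pm[parts$process] <- TRUE
    tables[[i]] <- data.frame(
      cell_id = i,
      center_row = sp$center[1], center_col = sp$center[2],
      gfap_class = sp$gfap_class,
      nucleus_area_px = nrow(parts$nucleus),
      soma_area_px = nrow(parts$soma),
      process_area_px = nrow(parts$process),
      cell_area_px = nrow(cell_idx),
      process_perimeter_px = exposed_edge_count(pm))
  }
  if (length(collisions) > 0)
    stop("overlapping cell specs: cells ",
         paste(unlist(collisions), collapse = "; "))

  mk_channel <- function(level_map) {
    ch <- matrix(background, shape[1], shape[2])
    ch[level_map$idx] <- level_map$val
    ch
  }
  nuc_idx <- which(nuclei_lab > 0L)
  nuclei_ch <- matrix(background, shape[1], shape[2])
  gfap_ch <- matrix(background, shape[1], shape[2])
  vim_ch <- matrix(background, shape[1], shape[2])
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    nuclei_ch[nuclei_lab == i] <- sp$nucleus_mean
    ci <- cell_lab == i
    vim_ch[ci] <- sp$vimentin_mean
    if (sp$gfap_class == "positive") gfap_ch[ci] <- sp$gfap_mean
  }
  if (noise_sd > 0) {
    npx <- prod(shape)
    nuclei_ch <- pmax(nuclei_ch + stats::rnorm(npx, 0, noise_sd), 0)
    gfap_ch <- pmax(gfap_ch + stats::rnorm(npx, 0, noise_sd), 0)
    vim_ch <- pmax(vim_ch + stats::rnorm(npx, 0, noise_sd), 0)
  }

  channels <- structure(list(nuclei = nuclei_ch, gfap = gfap_ch,
                             vimentin = vim_ch, pixel_size_um = NULL),
                        class = "channel_stack")
  truth <- structure(list(nuclei_labels = nuclei_lab, cell_labels = cell_lab,
                          soma_labels = soma_lab, process_labels = proc_lab,
                          cell_table = do.call(rbind, tables) %||%
                            data.frame()),
                     class = "field_truth")
  list(channels = channels, truth = truth)
}

#' Generate synthetic bulk mixtures from a cell-type signature
#'
#' Each output sample is `signature %*% proportions[s, ]` multiplied
#' elementwise by lognormal noise with log-sd `noise_sd_log` (exact mixture
#' when zero).
#'
#' @param signature a `signature_matrix` (see [build_signature()]) or a plain
#'   genes x cell-types nonnegative matrix with dimnames.
#' @param proportions samples x cell-types matrix; rows must be nonnegative
#'   and sum to 1 within 1e-9.
#' @param noise_sd_log nonnegative sd of the log-scale noise.
#' @param seed integer seed.
#' @return genes x samples numeric matrix with dimnames.
#' @export
generate_bulk_mixtures <- function(signature, proportions, noise_sd_log = 0,
                                   seed) {
  S <- if (inherits(signature, "signature_matrix")) signature$mean_profile
       else as.matrix(signature)
  proportions <- as.matrix(proportions)
  if (ncol(proportions) != ncol(S))
    stop("proportions must have one column per signature cell type")
  if (any(proportions < 0))
    stop("proportions must be nonnegative")
  rs <- rowSums(proportions)
  if (any(abs(rs - 1) > 1e-9))
    stop("each proportion row must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  stopifnot(noise_sd_log >= 0)
  set.seed(as.integer(seed))
  clean <- S %*% t(proportions)
  if (noise_sd_log > 0)
    clean <- clean * exp(matrix(stats::rnorm(length(clean), 0, noise_sd_log),
                                nrow(clean)))
  colnames(clean) <- rownames(proportions) %||%
    paste0("mix", seq_len(nrow(proportions)))
  rownames(clean) <- rownames(S)
  clean
}

#' Write a synthetic field to disk as 16-bit TIFFs plus a truth table
#'
#' Channels go to `<prefix>_ch1.tif` (nuclei), `<prefix>_ch2.tif` (GFAP) and
#' `<prefix>_ch3.tif` (Vimentin); truth label maps to
#' `<prefix>_<mask>_labels.tif` and the truth table to
#' `<prefix>_truth.csv`. Intensities are rounded and clipped to `[0, 65535]`.
#'
#' @param field result of [generate_field()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the character vector of files written.
#' @export
write_field <- function(field, dir, prefix = "field") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w16 <- function(m, path) {
    q <- pmin(pmax(round(m), 0), 65535) / 65535
    tiff::writeTIFF(q, path, bits.per.sample = 16, compression = "none")
    path
  }
  files <- c(
    w16(field$channels$nuclei, file.path(dir, paste0(prefix, "_ch1.tif"))),
    w16(field$channels$gfap, file.path(dir, paste0(prefix, "_ch2.tif"))),
    w16(field$channels$vimentin, file.path(dir, paste0(prefix, "_ch3.tif"))))
  for (nm in c("nuclei_labels", "cell_labels", "soma_labels",
               "process_labels")) {
    files <- c(files, w16(field$truth[[nm]],
                          file.path(dir, paste0(prefix, "_", nm, ".tif"))))
  }
  tcsv <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(field$truth$cell_table, tcsv, row.names = FALSE)
  invisible(c(files, tcsv))
}

#' Read a 16-bit grayscale TIFF back to an integer-valued intensity matrix
#' @param path TIFF file path.
#' @return numeric matrix on the original 0..65535 scale.
#' @export
read_intensity_tiff <- function(path) {
  round(as_matrix(tiff::readTIFF(path)) * 65535)
}

#' Assemble a channel stack from per-channel TIFF files
#' @param nuclei,gfap paths to the nuclei and GFAP channel TIFFs.
#' @param vimentin optional path to the Vimentin channel TIFF.
#' @param pixel_size_um optional pixel size in micrometres.
#' @return a `channel_stack`.
#' @export
read_channel_stack <- function(nuclei, gfap, vimentin = NULL,
                               pixel_size_um = NULL) {
  stk <- list(nuclei = read_intensity_tiff(nuclei),
              gfap = read_intensity_tiff(gfap),
              vimentin = if (!is.null(vimentin))
                read_intensity_tiff(vimentin),
              pixel_size_um = pixel_size_um)
  d <- dim(stk$nuclei)
  if (!identical(dim(stk$gfap), d) ||
      (!is.null(stk$vimentin) && !identical(dim(stk$vimentin), d)))
    stop("channel shapes differ")
  structure(stk, class = "channel_stack")
}
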