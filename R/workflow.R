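#' @name workflows
#' @title Config-driven workflows
#'
#' @description Four workflows bind the package stages together, selected by
#' the `workflow` field of a YAML/JSON config: `synth` (generate fields with
#' ground truth), `imaging` (segmentation + morphometry on channel TIFFs),
#' `deconv` (signature building + proportion estimation) and `stats`
#' (expression-side statistics). Every run writes a `manifest.json` echoing
#' all effective parameters and an MD5 checksum for every output file;
#' identical config + seed reproduces byte-identical outputs.
NULL

.config_defaults <- list(
  synth = list(classes = list(stellate = 25L), fields = 1L,
               gfap_positive_fraction = 1.0, noise_sd = 0, background = 100,
               prefix = "field"),
  # Defaults match the synthetic image model (no PSF blur, known levels):
  # no smoothing, fixed thresholds halfway between background and the
  # channel foreground means.
  segment = list(smoothing_sigma_px = 0, threshold_mode = "fixed",
                 nuclei_threshold = 4050, cell_threshold = 1050,
                 min_nucleus_area_px = 30L, min_cell_area_px = 100L,
                 ring_width_px = 5L, exclude_border = TRUE),
  morpho = list(opening_radius_px = 4L, gfap_mode = "fixed",
                gfap_threshold = 2550, gfap_positive_only = TRUE),
  imaging = list(cell_marker = "vimentin", fields = NULL),
  deconv = list(weighted = TRUE, max_iter = 50L, tol = 1e-6,
                min_shared_genes = 50L, sc_counts = NULL,
                cell_annotations = NULL, signature_mean = NULL,
                signature_variance = NULL, n_subjects = 1L, bulk = NULL),
  stats = list(counts = NULL, design = NULL, cpm_cutoff = 1.0,
               min_samples = "auto", panel = NULL, qpcr = NULL,
               qpcr_targets = NULL, housekeeping = c("ACTB", "L27"),
               reference_group = NULL)
)

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  config
}

.viol <- function(key, message) data.frame(key = key, message = message,
                                           stringsAsFactors = FALSE)

#' Validate a workflow run config
#'
#' Checks the config against the documented schema: known keys only, a valid
#' `workflow`, a mandatory integer `seed` for the `synth` workflow, parameter
#' constraints (e.g. `ring_width_px >= 1`), and existence of referenced input
#' paths. Returns every violation found.
#'
#' @param config a config list or a path to a YAML/JSON file.
#' @return data frame with columns `key` and `message`; zero rows when the
#'   config is valid.
#' @export
validate_run_config <- function(config) {
  config <- .read_config(config)
  v <- .viol(character(0), character(0))
  top_allowed <- c("workflow", "seed", "output_dir", "synth", "segment",
                   "morpho", "imaging", "deconv", "stats")
  for (k in setdiff(names(config), top_allowed))
    v <- rbind(v, .viol(k, paste0("unknown key '", k, "'")))
  wf <- config$workflow
  if (is.null(wf) || !wf %in% c("synth", "imaging", "deconv", "stats")) {
    v <- rbind(v, .viol("workflow",
      "workflow must be one of: synth, imaging, deconv, stats"))
    return(v)
  }
  if (!is.null(config$seed) &&
      (length(config$seed) != 1 || !is.finite(config$seed) ||
       config$seed != round(config$seed)))
    v <- rbind(v, .viol("seed", "seed must be a single integer"))
  if (wf == "synth" && is.null(config$seed))
    v <- rbind(v, .viol("seed", "seed is mandatory for the synth workflow"))

  for (blk in c("synth", "segment", "morpho", "imaging", "deconv", "stats")) {
    given <- config[[blk]]
    if (is.null(given)) next
    for (k in setdiff(names(given), names(.config_defaults[[blk]])))
      v <- rbind(v, .viol(paste(blk, k, sep = "."),
                          paste0("unknown key '", k, "' in block '", blk, "'")))
  }
  num_ge <- function(blk, key, lo) {
    x <- config[[blk]][[key]]
    if (!is.null(x) && (!is.numeric(x) || x < lo))
      .viol(paste(blk, key, sep = "."),
            paste0(key, " must be >= ", lo))
    else NULL
  }
  v <- rbind(v, num_ge("segment", "ring_width_px", 1),
             num_ge("segment", "smoothing_sigma_px", 0),
             num_ge("segment", "min_nucleus_area_px", 1),
             num_ge("segment", "min_cell_area_px", 1),
             num_ge("synth", "noise_sd", 0),
             num_ge("synth", "background", 0),
             num_ge("synth", "fields", 1),
             num_ge("morpho", "opening_radius_px", 1))
  f <- config$synth$gfap_positive_fraction
  if (!is.null(f) && (!is.numeric(f) || f < 0 || f > 1))
    v <- rbind(v, .viol("synth.gfap_positive_fraction",
                        "gfap_positive_fraction must be in [0, 1]"))
  tm <- config$segment$threshold_mode
  if (!is.null(tm) && !tm %in% c("otsu", "fixed"))
    v <- rbind(v, .viol("segment.threshold_mode",
                        "threshold_mode must be 'otsu' or 'fixed'"))

  check_path <- function(key, path) {
    if (!is.null(path) && !file.exists(path))
      .viol(key, paste0("path does not exist: ", path)) else NULL
  }
  if (wf == "imaging") {
    flds <- config$imaging$fields
    if (is.null(flds) || length(flds) == 0) {
      v <- rbind(v, .viol("imaging.fields",
                          "imaging workflow requires at least one field"))
    } else {
      for (i in seq_along(flds)) {
        fl <- flds[[i]]
        for (ch in c("nuclei", "gfap")) {
          if (is.null(fl[[ch]]))
            v <- rbind(v, .viol(sprintf("imaging.fields[%d].%s", i, ch),
                                paste0("field is missing channel '", ch, "'")))
          else v <- rbind(v, check_path(
            sprintf("imaging.fields[%d].%s", i, ch), fl[[ch]]))
        }
        v <- rbind(v, check_path(sprintf("imaging.fields[%d].vimentin", i),
                                 fl$vimentin))
      }
    }
  }
  if (wf == "deconv") {
    dc <- config$deconv %||% list()
    if (is.null(dc$bulk))
      v <- rbind(v, .viol("deconv.bulk", "deconv workflow requires 'bulk'"))
    have_sc <- !is.null(dc$sc_counts) && !is.null(dc$cell_annotations)
    if (!have_sc && is.null(dc$signature_mean))
      v <- rbind(v, .viol("deconv",
        "provide sc_counts + cell_annotations, or signature_mean"))
    for (k in c("bulk", "sc_counts", "cell_annotations", "signature_mean",
                "signature_variance"))
      v <- rbind(v, check_path(paste0("deconv.", k), dc[[k]]))
  }
  if (wf == "stats") {
    st <- config$stats %||% list()
    for (k in c("counts", "design"))
      if (is.null(st[[k]]))
        v <- rbind(v, .viol(paste0("stats.", k),
                            paste0("stats workflow requires '", k, "'")))
    for (k in c("counts", "design", "panel", "qpcr"))
      v <- rbind(v, check_path(paste0("stats.", k), st[[k]]))
  }
  v
}

.fill_defaults <- function(config) {
  for (blk in names(.config_defaults)) {
    config[[blk]] <- utils::modifyList(.config_defaults[[blk]],
                                       config[[blk]] %||% list())
  }
  config
}

.seg_params <- function(sg, which = c("nuclei", "cells")) {
  which <- match.arg(which)
  thr <- if (sg$threshold_mode == "fixed") {
    if (which == "nuclei") sg$nuclei_threshold else sg$cell_threshold
  } else NULL
  segmentation_params(smoothing_sigma_px = sg$smoothing_sigma_px,
                      threshold_mode = sg$threshold_mode,
                      fixed_threshold = thr,
                      min_nucleus_area_px = sg$min_nucleus_area_px,
                      min_cell_area_px = sg$min_cell_area_px,
                      ring_width_px = sg$ring_width_px,
                      exclude_border = sg$exclude_border)
}

#' Read a genes-x-samples matrix from CSV (first column = gene identifiers)
#' @param path CSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a genes-x-samples matrix to CSV
#' @param m matrix with dimnames.
#' @param path output CSV path.
#' @param id_col name of the identifier column.
#' @export
write_matrix_csv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.csv(df, path, row.names = FALSE)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.run_synth <- function(config, out) {
  sy <- config$synth
  seed <- as.integer(config$seed)
  files <- character(0)
  i <- 0L
  for (cls in names(sy$classes)) {
    n <- sy$classes[[cls]]
    if (n < 1) next
    for (f in seq_len(sy$fields)) {
      i <- i + 1L
      t0 <- Sys.time()
      layout <- random_field_specs(n, cls, seed = seed + 1000L * i,
                                   gfap_positive_fraction =
                                     sy$gfap_positive_fraction)
      fld <- generate_field(layout$specs, shape = layout$shape,
                            noise_sd = sy$noise_sd,
                            background = sy$background,
                            seed = seed + 1000L * i + 1L)
      prefix <- sprintf("%s_%s_f%02d", sy$prefix, cls, f)
      files <- c(files, write_field(fld, out, prefix))
      .log_stage("synth", sprintf(
        "%s: %d cells, shape %dx%d (%.1fs)", prefix, n,
        layout$shape[1], layout$shape[2],
        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  files
}

#' Segment a channel stack and measure every cell
#'
#' Convenience wrapper chaining [segment_nuclei()], [segment_cells()],
#' optional [filter_border_cells()], [perinuclear_zones()] and
#' [measure_cells()].
#'
#' @param channels a `channel_stack`.
#' @param nuclei_params,cell_params [segmentation_params()] for the nucleus
#'   and cell stages (ring width and border handling are taken from
#'   `cell_params`).
#' @param cell_marker `"vimentin"` (fallback to GFAP when absent) or
#'   `"gfap"`: the channel defining cell territory.
#' @param opening_radius_px soma opening radius.
#' @return data frame of unclassified CellRecords (possibly zero rows).
#' @export
segment_and_measure <- function(channels, nuclei_params, cell_params,
                                cell_marker = c("vimentin", "gfap"),
                                opening_radius_px = 4L) {
  cell_marker <- match.arg(cell_marker)
  marker <- if (cell_marker == "vimentin" && !is.null(channels$vimentin))
    channels$vimentin else channels$gfap
  nuc <- segment_nuclei(channels$nuclei, nuclei_params)
  seg <- segment_cells(marker, nuc, cell_params)
  if (cell_params$exclude_border)
    seg <- filter_border_cells(seg$cell_labels, seg$nuclei_labels)
  if (max(seg$cell_labels) == 0L) return(data.frame())
  zones <- perinuclear_zones(seg$nuclei_labels, seg$cell_labels,
                             cell_params$ring_width_px)
  rec <- measure_cells(channels, seg$cell_labels, seg$nuclei_labels, zones,
                       opening_radius_px)
  attr(rec, "cell_labels") <- seg$cell_labels
  attr(rec, "nuclei_labels") <- seg$nuclei_labels
  rec
}

.run_imaging <- function(config, out) {
  sg <- config$segment
  mo <- config$morpho
  np <- .seg_params(sg, "nuclei")
  cp <- .seg_params(sg, "cells")
  all_records <- list()
  meta <- list()
  for (fl in config$imaging$fields) {
    t0 <- Sys.time()
    id <- fl$id %||% basename(fl$nuclei)
    stack <- read_channel_stack(fl$nuclei, fl$gfap, fl$vimentin)
    rec <- segment_and_measure(stack, np, cp,
                               cell_marker = config$imaging$cell_marker,
                               opening_radius_px = mo$opening_radius_px)
    if (nrow(rec) == 0) {
      .log_stage("imaging", id, ": no cells found")
      next
    }
    attr(rec, "cell_labels") <- attr(rec, "nuclei_labels") <- NULL
    rec <- cbind(data.frame(field = id), rec)
    rec$line <- fl$line %||% NA_character_
    rec$protocol <- fl$protocol %||% NA_character_
    rec$replicate <- fl$replicate %||% NA_integer_
    all_records[[id]] <- rec
    .log_stage("imaging", sprintf("%s: %d cells (%.1fs)", id, nrow(rec),
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  if (!length(all_records)) stop("imaging workflow produced no cells")
  records <- do.call(rbind, all_records)
  # GFAP+ calling on the pooled batch, not per field
  records <- if (mo$gfap_mode == "fixed")
    classify_gfap_positive(records, "fixed", mo$gfap_threshold)
  else classify_gfap_positive(records, "otsu")
  summaries <- do.call(rbind, lapply(split(records, records$field),
    function(r) cbind(data.frame(field = r$field[1], line = r$line[1],
                                 protocol = r$protocol[1],
                                 replicate = r$replicate[1]),
                      summarize_field(r, mo$gfap_positive_only))))
  rownames(records) <- rownames(summaries) <- NULL
  f1 <- file.path(out, "cell_records.csv")
  f2 <- file.path(out, "field_summary.csv")
  utils::write.csv(records, f1, row.names = FALSE)
  utils::write.csv(summaries, f2, row.names = FALSE)
  c(f1, f2)
}

.run_deconv <- function(config, out) {
  dc <- config$deconv
  files <- character(0)
  if (!is.null(dc$sc_counts)) {
    sc <- read_matrix_csv(dc$sc_counts)
    ann <- utils::read.csv(dc$cell_annotations)
    stopifnot(all(c("cell", "cell_type", "subject") %in% names(ann)))
    ann <- ann[match(colnames(sc), ann$cell), ]
    sig <- build_signature(sc, ann$cell_type, ann$subject)
    write_matrix_csv(sig$mean_profile, file.path(out, "signature_mean.csv"))
    write_matrix_csv(sig$cross_subject_variance,
                     file.path(out, "signature_variance.csv"))
    files <- c(files, file.path(out, "signature_mean.csv"),
               file.path(out, "signature_variance.csv"))
  } else {
    mp <- read_matrix_csv(dc$signature_mean)
    vp <- if (!is.null(dc$signature_variance))
      read_matrix_csv(dc$signature_variance)
    sig <- signature_matrix(mp, vp, n_subjects = dc$n_subjects)
  }
  bulk <- read_matrix_csv(dc$bulk)
  rows <- lapply(colnames(bulk), function(s) {
    est <- if (isTRUE(dc$weighted))
      estimate_proportions_weighted(bulk[, s], sig, max_iter = dc$max_iter,
                                    tol = dc$tol,
                                    min_shared_genes = dc$min_shared_genes)
    else estimate_proportions_nnls(bulk[, s], sig,
                                   min_shared_genes = dc$min_shared_genes)
    cbind(data.frame(sample = s), as.data.frame(t(est$proportions)),
          data.frame(residual_norm = est$residual_norm,
                     n_iterations = est$n_iterations,
                     converged = est$converged))
  })
  f <- file.path(out, "proportions.csv")
  utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
  .log_stage("deconv", sprintf("%d bulk samples deconvolved", ncol(bulk)))
  c(files, f)
}

.run_stats <- function(config, out) {
  st <- config$stats
  counts <- read_matrix_csv(st$counts)
  design <- utils::read.csv(st$design)
  files <- character(0)
  filtered <- filter_low_expression(counts, design, st$cpm_cutoff,
                                    st$min_samples)
  write_matrix_csv(filtered, file.path(out, "filtered_counts.csv"))
  z <- row_zscore(filtered)
  write_matrix_csv(z, file.path(out, "row_zscores.csv"))
  files <- c(files, file.path(out, "filtered_counts.csv"),
             file.path(out, "row_zscores.csv"))
  .log_stage("stats", sprintf("%d of %d genes pass the expression filter",
                              nrow(filtered), nrow(counts)))
  if (!is.null(st$panel)) {
    panel <- utils::read.csv(st$panel)
    sc <- marker_panel_score(filtered, panel)
    df <- data.frame(sample = names(sc$scores), score = unname(sc$scores))
    utils::write.csv(df, file.path(out, "panel_scores.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(out, "panel_scores.csv"))
  }
  if (!is.null(st$qpcr)) {
    ct <- utils::read.csv(st$qpcr)
    rq <- qpcr_relative_expression(ct, st$qpcr_targets,
                                   housekeeping = st$housekeeping,
                                   reference_group = st$reference_group,
                                   design = design)
    utils::write.csv(rq, file.path(out, "qpcr_relative_expression.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(out, "qpcr_relative_expression.csv"))
  }
  files
}

#' Run a configured workflow end-to-end
#'
#' Validates the config (stopping with all violations listed if any),
#' executes the selected workflow and writes a deterministic
#' `manifest.json` with the package version, the seed, every effective
#' parameter value and an MD5 checksum per output file.
#'
#' @param config config list or YAML/JSON path (see [validate_run_config()]).
#' @param out output directory; overrides the config's `output_dir`.
#' @param seed optional integer overriding the config's `seed`.
#' @return invisibly, the manifest list.
#' @export
run_workflow <- function(config, out = NULL, seed = NULL) {
  config <- .read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  v <- validate_run_config(config)
  if (nrow(v) > 0)
    stop(structure(class = c("astro_config_error", "error", "condition"),
                   list(message = paste0("invalid config:\n",
                          paste0("  ", v$key, ": ", v$message,
                                 collapse = "\n")),
                        call = sys.call(), violations = v)))
  config <- .fill_defaults(config)
  out <- out %||% config$output_dir
  if (is.null(out)) stop("no output directory: set output_dir or out=")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  runner <- switch(config$workflow, synth = .run_synth,
                   imaging = .run_imaging, deconv = .run_deconv,
                   stats = .run_stats)
  files <- tryCatch(runner(config, out), error = function(e) {
    stop("workflow stage '", config$workflow, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  files <- sort(unique(files))
  checks <- as.list(tools::md5sum(files))
  names(checks) <- basename(names(checks))
  manifest <- list(workflow = config$workflow,
                   package = "astromorph",
                   version = as.character(utils::packageVersion("astromorph")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("workflow", "seed"))],
                   outputs = checks)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
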