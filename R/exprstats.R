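#' Validate a sample-group design table
#'
#' @param design data frame with columns `sample`, `line`, `protocol` and
#'   optionally `replicate`.
#' @param samples optional sample identifiers that must each appear exactly
#'   once.
#' @return the validated design (invisibly usable).
#' @export
group_design <- function(design, samples = NULL) {
  req <- c("sample", "line", "protocol")
  if (!all(req %in% names(design)))
    stop("design must contain columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(design$sample))
    stop("duplicate sample identifiers in design")
  if (!is.null(samples)) {
    miss <- setdiff(samples, design$sample)
    if (length(miss))
      stop("samples missing from design: ", paste(miss, collapse = ", "))
  }
  design
}

#' Filter genes with low expression
#'
#' Keeps a gene iff its counts-per-million reach `cpm_cutoff` in at least `k`
#' samples, where `k` defaults to the smallest (line x protocol) group size —
#' an explicit, documented stand-in for the cited default count filter. Gene
#' order is preserved.
#'
#' @param counts genes x samples nonnegative count matrix with dimnames.
#' @param design a [group_design()] covering the matrix columns.
#' @param cpm_cutoff CPM threshold.
#' @param min_samples `"auto"` (smallest group size) or an integer.
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, design, cpm_cutoff = 1,
                                  min_samples = "auto") {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), all(is.finite(counts)))
  design <- group_design(design, colnames(counts))
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  if (identical(min_samples, "auto")) {
    d <- design[match(colnames(counts), design$sample), ]
    k <- min(table(interaction(d$line, d$protocol, drop = TRUE)))
  } else {
    k <- as.integer(min_samples)
    stopifnot(k >= 1)
  }
  counts[rowSums(cpm >= cpm_cutoff) >= k, , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR control: `q_(i) = min_{j >= i} p_(j) * m / j`, returned in the
#' input order and capped at 1.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Row Z-scores for heatmap display
#'
#' Each row is centred by its mean and scaled by its sample standard
#' deviation (n - 1 denominator); constant rows map to all-zeros.
#'
#' @param m genes x samples matrix with at least 2 columns.
#' @return matrix of the same shape and dimnames.
#' @export
row_zscore <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("row Z-scores need at least 2 samples")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- sweep(m, 1, mu)
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  z <- sweep(z, 1, sdv, "/")
  z[const, ] <- 0
  z
}

#' Score samples against a marker panel
#'
#' The panel score of a sample is the mean over the matched panel genes of
#' the row Z-scores, with down-direction genes sign-flipped. Genes absent
#' from the matrix are reported, not an error, unless none match.
#'
#' @param m genes x samples expression matrix.
#' @param panel data frame with column `gene` and optional `direction`
#'   (`"up"`/`"down"`, default up).
#' @return list with `scores` (named per-sample vector), `matched_genes`,
#'   `missing_genes`.
#' @export
marker_panel_score <- function(m, panel) {
  m <- as.matrix(m)
  stopifnot("gene" %in% names(panel), nrow(panel) >= 1,
            !anyDuplicated(panel$gene))
  dir <- if ("direction" %in% names(panel)) panel$direction
         else rep("up", nrow(panel))
  if (!all(dir %in% c("up", "down")))
    stop("panel direction must be 'up' or 'down'")
  present <- panel$gene %in% rownames(m)
  if (!any(present))
    stop("no panel gene present in the expression matrix")
  z <- row_zscore(m)[panel$gene[present], , drop = FALSE]
  sign <- ifelse(dir[present] == "down", -1, 1)
  scores <- colMeans(z * sign)
  list(scores = scores,
       matched_genes = panel$gene[present],
       missing_genes = panel$gene[!present])
}

#' Balanced two-way fixed-effects ANOVA
#'
#' Classical decomposition into factor A, factor B, interaction and residual
#' sums of squares, with `F = MS_effect / MS_resid` and p-values from the F
#' distribution. Restricted to balanced complete designs with at least 2
#' observations per cell, where all sums-of-squares types coincide.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b grouping labels, same length as `values`.
#' @return object of class `anova_result`: a list with per-term `F`, `p`,
#'   `df`, plus `residual_df` and `residual_ms`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b), all(is.finite(values)))
  A <- factor(factor_a); B <- factor(factor_b)
  tab <- table(A, B)
  if (any(tab == 0) || length(unique(as.vector(tab))) != 1)
    stop("unbalanced design: two_way_anova requires a complete balanced ",
         "design; rebalance the groups (equal n per cell)")
  if (tab[1, 1] < 2)
    stop("at least 2 observations per cell are required (no residual df)")
  fit <- stats::aov(values ~ A * B)
  sm <- summary(fit)[[1]]
  rn <- trimws(rownames(sm))
  term <- function(nm) {
    i <- which(rn == nm)
    list(F = sm[i, "F value"], p = sm[i, "Pr(>F)"], df = sm[i, "Df"])
  }
  ms_res <- sm[which(rn == "Residuals"), "Mean Sq"]
  # guard against exactly-replicated cells, where aov returns a residual
  # mean square at floating-point noise level rather than exact zero
  if (!is.finite(ms_res) ||
      ms_res <= 1e-10 * (mean(values^2) + .Machine$double.eps))
    stop("zero residual variance: F statistics undefined")
  structure(list(factor_a = term("A"),
                 factor_b = term("B"),
                 interaction = term("A:B"),
                 residual_df = sm[which(rn == "Residuals"), "Df"],
                 residual_ms = ms_res),
            class = "anova_result")
}

#' qPCR relative expression by the delta-delta-Ct method
#'
#' Per sample and target gene: `dCt = Ct_target - mean(Ct over housekeeping
#' genes)`; `ddCt = dCt - mean dCt of the reference group`; `RQ = 2^(-ddCt)`.
#' Amplification efficiency is assumed to be 100% (factor 2 per cycle);
#' housekeeping aggregation is the arithmetic mean of Ct, i.e. the geometric
#' mean in linear space.
#'
#' @param ct data frame with columns `sample`, `gene`, `ct`.
#' @param targets character vector of target genes.
#' @param housekeeping housekeeping gene pair, default `c("ACTB", "L27")`.
#' @param reference_group label of the reference group, matched against the
#'   design's `protocol` column, or against `line:protocol` if no protocol
#'   matches.
#' @param design a [group_design()] covering the Ct samples.
#' @return data frame with one row per (sample, target): `delta_ct`,
#'   `delta_delta_ct`, `rq`, plus the design columns.
#' @export
qpcr_relative_expression <- function(ct, targets,
                                     housekeeping = c("ACTB", "L27"),
                                     reference_group, design) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)),
            all(is.finite(ct$ct)))
  design <- group_design(design, unique(ct$sample))
  samples <- unique(ct$sample)
  hk_mean <- vapply(samples, function(s) {
    v <- vapply(housekeeping, function(g) {
      x <- ct$ct[ct$sample == s & ct$gene == g]
      if (length(x) != 1)
        stop("missing housekeeping Ct for sample ", s, ", gene ", g)
      x
    }, numeric(1))
    mean(v)
  }, numeric(1))
  names(hk_mean) <- samples

  d <- design[match(samples, design$sample), ]
  in_ref <- d$protocol == reference_group
  if (!any(in_ref))
    in_ref <- paste(d$line, d$protocol, sep = ":") == reference_group
  if (!any(in_ref))
    stop("reference_group '", reference_group, "' matches no sample")
  ref_samples <- samples[in_ref]

  out <- list()
  for (g in targets) {
    rows <- ct[ct$gene == g & ct$sample %in% samples, ]
    if (nrow(rows) == 0) stop("no Ct values for target gene ", g)
    dct <- rows$ct - hk_mean[rows$sample]
    ref_dct <- mean(dct[rows$sample %in% ref_samples])
    ddct <- dct - ref_dct
    out[[g]] <- data.frame(sample = rows$sample, gene = g,
                           delta_ct = dct, delta_delta_ct = ddct,
                           rq = 2^(-ddct))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  merge(res, design, by = "sample", sort = FALSE)
}
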