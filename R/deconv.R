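#' Construct a signature matrix object directly
#'
#' @param mean_profile genes x cell-types nonnegative matrix with dimnames;
#'   columns are renormalized to sum to 1.
#' @param cross_subject_variance same-shape nonnegative matrix (defaults to
#'   all zeros).
#' @param n_subjects number of reference subjects the profiles summarize.
#' @return object of class `signature_matrix`.
#' @export
signature_matrix <- function(mean_profile, cross_subject_variance = NULL,
                             n_subjects = 1L) {
  mean_profile <- as.matrix(mean_profile)
  stopifnot(all(mean_profile >= 0), n_subjects >= 1,
            !is.null(rownames(mean_profile)), !is.null(colnames(mean_profile)))
  if (is.null(cross_subject_variance))
    cross_subject_variance <- matrix(0, nrow(mean_profile),
                                     ncol(mean_profile),
                                     dimnames = dimnames(mean_profile))
  cross_subject_variance <- as.matrix(cross_subject_variance)
  stopifnot(identical(dim(cross_subject_variance), dim(mean_profile)),
            all(cross_subject_variance >= 0))
  if (n_subjects == 1L && any(cross_subject_variance > 0))
    stop("cross-subject variance must be zero with a single subject")
  cs <- colSums(mean_profile)
  if (any(cs <= 0)) stop("signature column sums must be positive")
  structure(list(genes = rownames(mean_profile),
                 cell_types = colnames(mean_profile),
                 mean_profile = sweep(mean_profile, 2, cs, "/"),
                 cross_subject_variance = cross_subject_variance,
                 n_subjects = as.integer(n_subjects)),
            class = "signature_matrix")
}

#' Build a cell-type signature from a labelled single-cell matrix
#'
#' Each cell's counts are normalized to relative abundance (column sum 1);
#' gene-wise means are taken per (subject, cell type); the signature mean is
#' the across-subject mean of those profiles and the cross-subject variance
#' the across-subject variance (n - 1 denominator; zero for types observed
#' in a single subject). Mean columns are renormalized to sum to 1.
#'
#' @param sc_matrix genes x cells nonnegative count matrix with dimnames.
#' @param cell_type_labels,subject_labels per-cell annotation vectors.
#' @return a [signature_matrix()].
#' @export
build_signature <- function(sc_matrix, cell_type_labels, subject_labels) {
  sc_matrix <- as.matrix(sc_matrix)
  stopifnot(ncol(sc_matrix) == length(cell_type_labels),
            ncol(sc_matrix) == length(subject_labels),
            all(sc_matrix >= 0))
  types <- as.factor(cell_type_labels)      # keeps declared-but-empty levels
  subjects <- as.factor(subject_labels)
  if (any(table(types) == 0))
    stop("cell type absent from all subjects: ",
         paste(levels(types)[table(types) == 0], collapse = ", "))
  cs <- colSums(sc_matrix)
  if (any(cs == 0)) stop("cells with zero total counts")
  rel <- sweep(sc_matrix, 2, cs, "/")

  mean_profile <- matrix(0, nrow(sc_matrix), nlevels(types),
                         dimnames = list(rownames(sc_matrix), levels(types)))
  var_profile <- mean_profile
  for (ty in levels(types)) {
    subj_means <- sapply(levels(subjects), function(s) {
      sel <- types == ty & subjects == s
      if (!any(sel)) return(rep(NA_real_, nrow(rel)))
      rowMeans(rel[, sel, drop = FALSE])
    })
    subj_means <- subj_means[, colSums(!is.na(subj_means)) > 0, drop = FALSE]
    if (ncol(subj_means) == 0)
      stop("cell type absent from all subjects: ", ty)
    mean_profile[, ty] <- rowMeans(subj_means)
    var_profile[, ty] <- if (ncol(subj_means) >= 2)
      apply(subj_means, 1, stats::var) else 0
  }
  signature_matrix(mean_profile, var_profile,
                   n_subjects = nlevels(droplevels(subjects)))
}

# Shared-gene intersection and normalization for the estimators.
.deconv_prepare <- function(bulk, signature, min_shared_genes) {
  stopifnot(inherits(signature, "signature_matrix"))
  if (is.null(names(bulk))) stop("bulk vector must be gene-named")
  shared <- intersect(names(bulk), signature$genes)
  if (length(shared) < min_shared_genes)
    stop("only ", length(shared), " genes shared with the signature (need >= ",
         min_shared_genes, ")")
  S <- signature$mean_profile[shared, , drop = FALSE]
  V <- signature$cross_subject_variance[shared, , drop = FALSE]
  dup <- which(duplicated(t(round(S, 12))))
  if (length(dup) > 0) {
    pairs <- vapply(dup, function(j) {
      i <- which(apply(S, 2, function(col)
        max(abs(col - S[, j])) < 1e-12))[1]
      paste(colnames(S)[i], colnames(S)[j], sep = " ~ ")
    }, character(1))
    stop("rank-deficient signature, collinear cell types: ",
         paste(pairs, collapse = ", "))
  }
  if (qr(S)$rank < ncol(S))
    stop("rank-deficient signature matrix on the shared gene set")
  b <- bulk[shared]
  if (sum(b) <= 0) stop("bulk vector sums to zero on the shared genes")
  list(S = S, V = V, b = b / sum(b))
}

.nnls_solve <- function(S, b) {
  fit <- pracma::lsqnonneg(S, as.numeric(b))
  x <- fit$x
  names(x) <- colnames(S)
  x
}

.as_estimate <- function(x, S, b, n_iterations, converged = TRUE) {
  if (sum(x) <= 0) stop("degenerate all-zero NNLS solution")
  structure(list(proportions = x / sum(x),
                 residual_norm = sqrt(sum((S %*% x - b)^2)),
                 n_iterations = as.integer(n_iterations),
                 converged = isTRUE(converged)),
            class = "proportion_estimate")
}

#' Estimate bulk cell-type proportions by non-negative least squares
#'
#' Solves `min ||S x - b||^2, x >= 0` on the gene set shared between the
#' bulk vector and the signature (both normalized to relative abundance),
#' then renormalizes `x` to sum to 1. Deterministic.
#'
#' @param bulk gene-named nonnegative expression vector.
#' @param signature a [signature_matrix()].
#' @param min_shared_genes minimum size of the shared gene set.
#' @return object of class `proportion_estimate`: named `proportions`
#'   (sum 1), `residual_norm`, `n_iterations`, `converged`.
#' @export
estimate_proportions_nnls <- function(bulk, signature,
                                      min_shared_genes = 50L) {
  prep <- .deconv_prepare(bulk, signature, min_shared_genes)
  x <- .nnls_solve(prep$S, prep$b)
  .as_estimate(x, prep$S, prep$b, n_iterations = 1L)
}

#' Cross-subject variance-weighted NNLS proportion estimate
#'
#' Iteratively reweighted NNLS in the spirit of multi-subject deconvolution:
#' gene `g` receives weight `w_g = 1 / (sum_k V_gk x_k^2 + r_g^2 + eps)`,
#' where `V` is the cross-subject variance of the signature, `r` the current
#' residual and `eps` a small stabilizer; each iteration solves NNLS on the
#' row-weighted system and stops when the maximum proportion change drops
#' below `tol`. With all-zero variance and homoscedastic residuals this
#' reduces to the unweighted estimator. This is deliberately a simplified
#' estimator: no multi-subject bulk model and no tree-guided recursion.
#'
#' @inheritParams estimate_proportions_nnls
#' @param max_iter maximum number of reweighting iterations.
#' @param tol convergence tolerance on the proportions.
#' @param eps weight stabilizer.
#' @return a `proportion_estimate`; `converged = FALSE` (with a warning)
#'   when `max_iter` is exhausted.
#' @export
estimate_proportions_weighted <- function(bulk, signature, max_iter = 50L,
                                          tol = 1e-6, eps = 1e-8,
                                          min_shared_genes = 50L) {
  prep <- .deconv_prepare(bulk, signature, min_shared_genes)
  S <- prep$S; V <- prep$V; b <- prep$b
  x <- .nnls_solve(S, b)
  p_old <- x / sum(x)
  converged <- FALSE
  iter <- 1L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- as.numeric(S %*% x - b)
    w <- 1 / (as.numeric(V %*% (x^2)) + r^2 + eps)
    sw <- sqrt(w)
    x <- .nnls_solve(S * sw, b * sw)
    p_new <- x / sum(x)
    if (max(abs(p_new - p_old)) < tol) { converged <- TRUE; break }
    p_old <- p_new
  }
  if (!converged)
    warning("weighted NNLS did not converge within ", max_iter, " iterations")
  .as_estimate(x, S, b, n_iterations = iter, converged = converged)
}
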