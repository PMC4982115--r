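#' Marker panel for olfactory vs respiratory tissue content
#'
#' Olfactory epithelium biopsies are routinely contaminated with adjacent
#' respiratory epithelium; a small marker panel discriminates the two.
#'
#' @param olfactory Symbols of olfactory-epithelium markers.
#' @param respiratory Symbols of respiratory-epithelium markers.
#' @return List of class `MarkerPanel`.
#' @export
marker_panel <- function(olfactory = c("OMP", "CNGA2", "GNAL", "RTP1"),
                         respiratory = c("KRT13", "TMPRSS11D")) {
  if (!length(olfactory) || !length(respiratory))
    stop("marker panels must be non-empty")
  if (length(intersect(olfactory, respiratory)))
    stop("marker panels must be disjoint")
  structure(list(olfactory = olfactory, respiratory = respiratory),
            class = "MarkerPanel")
}

#' Marker-based QC score for one sample
#'
#' FPKM analog of the qPCR delta-Ct biopsy QC: mean log10 FPKM over the
#' olfactory markers minus mean log10 FPKM over the respiratory markers.
#' A sample passes when the score is positive and every olfactory marker
#' is itself expressed at or above `min_marker_fpkm`.
#'
#' @param m Floored [ExpressionMatrix()].
#' @param panel A [marker_panel()].
#' @param sample Sample id.
#' @param min_marker_fpkm Per-marker expression requirement for a pass.
#' @param pass_threshold Score above which the sample passes (default 0).
#' @return List with `score` and logical `pass`.
#' @export
marker_qc_score <- function(m, panel, sample, min_marker_fpkm = 0.01,
                            pass_threshold = 0) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(panel, "MarkerPanel"))
  miss <- setdiff(c(panel$olfactory, panel$respiratory), rownames(m$values))
  if (length(miss))
    stop("marker gene(s) absent from matrix: ", paste(miss, collapse = ", "))
  olf <- m$values[panel$olfactory, sample]
  rsp <- m$values[panel$respiratory, sample]
  score <- mean(log10(olf)) - mean(log10(rsp))
  list(score = score,
       pass = score > pass_threshold && all(olf >= min_marker_fpkm))
}

#' Sample-by-sample expression correlation matrix
#'
#' Pearson correlation between every pair of samples on log10 of floored
#' FPKM, restricted to a gene subset (default: genes expressed at or
#' above `cutoff` in every sample, the set on which tissue signatures are
#' comparable). A zero-variance sample yields `NA` correlations rather
#' than 0.
#'
#' @param m Floored [ExpressionMatrix()].
#' @param gene_subset Gene ids, or `NULL` for the default subset.
#' @param cutoff Expression cutoff used for the default subset.
#' @return Symmetric sample-by-sample matrix of Pearson r (unit diagonal).
#' @export
tissue_correlation_matrix <- function(m, gene_subset = NULL, cutoff = 0.01) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 2) stop("need >= 2 samples")
  if (is.null(gene_subset)) {
    keep <- rowSums(m$values >= cutoff) == ncol(m$values)
    gene_subset <- rownames(m$values)[keep]
  }
  if (!length(gene_subset)) stop("empty gene subset")
  lx <- log10(m$values[gene_subset, , drop = FALSE])
  sds <- apply(lx, 2, stats::sd)
  r <- suppressWarnings(stats::cor(lx, method = "pearson"))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  r
}
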