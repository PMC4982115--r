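#' Screen configuration
#'
#' Thresholds of the olfactory overexpression screen. Defaults are the
#' study's rules: fold change >= 6 together with p < 0.001; removal of
#' genes whose respiratory-epithelium expression exceeds 0.1 of their
#' olfactory-epithelium expression; rescue of genes significantly
#' overexpressed in mouse provided their human fold change exceeds 6.
#'
#' @param fold_cutoff Minimum OE/control FPKM fold change.
#' @param p_cutoff Significance cutoff for the count-based test.
#' @param respiratory_ratio_cutoff Maximum allowed respiratory/OE FPKM ratio.
#' @param rescue_requires_mouse_significant Whether mouse rescue needs a
#'   significant mouse call (as opposed to any mouse overexpression flag).
#' @param rescue_human_fold_min Minimum human fold change for a mouse rescue.
#' @param adjust_p Multiple-testing adjustment passed to [stats::p.adjust()]
#'   applied before thresholding, or `"none"` (the default, mirroring the
#'   fixed p-cutoff rule).
#' @return List of class `ScreenConfig`.
#' @export
screen_config <- function(fold_cutoff = 6, p_cutoff = 0.001,
                          respiratory_ratio_cutoff = 0.1,
                          rescue_requires_mouse_significant = TRUE,
                          rescue_human_fold_min = 6,
                          adjust_p = "none") {
  stopifnot(fold_cutoff > 0, p_cutoff > 0, respiratory_ratio_cutoff > 0)
  structure(list(fold_cutoff = fold_cutoff, p_cutoff = p_cutoff,
                 respiratory_ratio_cutoff = respiratory_ratio_cutoff,
                 rescue_requires_mouse_significant = rescue_requires_mouse_significant,
                 rescue_human_fold_min = rescue_human_fold_min,
                 adjust_p = adjust_p),
            class = "ScreenConfig")
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: for each sample, the median over
#' genes (restricted to genes with nonzero counts in every sample) of the
#' ratio of its count to the gene's geometric mean across samples.
#' Factors are rescaled to geometric mean exactly 1.
#'
#' @param c A [CountMatrix()] or a plain counts matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(c) {
  counts <- if (inherits(c, "CountMatrix")) c$counts else as.matrix(c)
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no gene has nonzero counts in all samples; cannot estimate size factors")
  lg <- log(counts[all_pos, , drop = FALSE])
  geo <- rowMeans(lg)
  s <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  s <- s / exp(mean(log(s)))
  s
}

#' Method-of-moments dispersion estimates
#'
#' Per-gene negative-binomial dispersion alpha (variance = mu + alpha*mu^2
#' on the common scale) estimated by the method of moments on normalized
#' counts: within each group with >= 2 samples,
#' `alpha = (var(k/s) - qhat * mean(1/s)) / qhat^2` (the `mean(1/s)` term
#' is the shot-noise contribution; with unit size factors it reduces to
#' `(var - mean)/mean^2`), then averaged across groups and floored at 0.
#'
#' @param c A [CountMatrix()].
#' @param s Size factors from [estimate_size_factors()].
#' @param groups Named character vector (sample -> group); defaults to the
#'   matrix's own `sample_groups`.
#' @return List of class `DispersionModel` with elements `alpha` (named
#'   per-gene vector) and `size_factors`.
#' @export
estimate_dispersions <- function(c, s = estimate_size_factors(c), groups = NULL) {
  stopifnot(inherits(c, "CountMatrix"))
  if (is.null(groups)) groups <- c$sample_groups
  counts <- c$counts
  s <- s[colnames(counts)]
  grp <- split(colnames(counts), groups[colnames(counts)])
  grp <- grp[vapply(grp, length, 1L) >= 2]
  if (!length(grp)) stop("need at least one group with >= 2 samples")
  per_group <- vapply(grp, function(cols) {
    k <- counts[, cols, drop = FALSE]
    sv <- s[cols]
    norm <- sweep(k, 2, sv, "/")
    q <- rowMeans(norm)
    v <- apply(norm, 1, stats::var)
    a <- (v - q * mean(1 / sv)) / q^2
    a[q == 0] <- 0
    pmax(a, 0)
  }, numeric(nrow(counts)))
  alpha <- rowMeans(as.matrix(per_group))
  alpha[is.na(alpha)] <- 0
  structure(list(alpha = stats::setNames(alpha, rownames(counts)),
                 size_factors = s),
            class = "DispersionModel")
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Exact conditional two-sided p-value for one gene.
# ka, kb: group total counts; Sa, Sb: summed size factors; SSa, SSb: summed
# squared size factors; alpha: gene dispersion. Under the null both groups
# share the common abundance, so the split of the total between groups has
# the stated NB (alpha > 0) or Poisson (alpha = 0) conditional law.
nb_exact_pvalue <- function(ka, kb, Sa, Sb, SSa, SSb, alpha, q0) {
  ks <- ka + kb
  if (ks == 0) return(1)
  k <- 0:ks
  mu_a <- q0 * Sa
  mu_b <- q0 * Sb
  if (alpha <= 0) {
    lp <- stats::dpois(k, mu_a, log = TRUE) +
      stats::dpois(ks - k, mu_b, log = TRUE)
  } else {
    # group-sum NB: var = mu + alpha * q0^2 * sum(s_j^2)  =>  size = S^2/(alpha*SS)
    size_a <- Sa^2 / (alpha * SSa)
    size_b <- Sb^2 / (alpha * SSb)
    lp <- stats::dnbinom(k, mu = mu_a, size = size_a, log = TRUE) +
      stats::dnbinom(ks - k, mu = mu_b, size = size_b, log = TRUE)
  }
  lobs <- lp[ka + 1]
  tot <- log_sum_exp(lp)
  sel <- lp <= lobs + 1e-7
  p <- exp(log_sum_exp(lp[sel]) - tot)
  min(1, max(p, .Machine$double.xmin))
}

#' Exact conditional negative-binomial two-group test
#'
#' Tests a single gene for differential abundance between two sample
#' groups. Conditional on the total count of the gene, the probability of
#' every split of that total between the groups is computed from
#' negative-binomial group sums (Poisson when the gene's dispersion is 0)
#' with means proportional to the groups' summed size factors; the
#' two-sided p-value sums the probabilities of all splits no more likely
#' than the observed one. Computation is in log space; totals up to 1e6
#' are supported without overflow.
#'
#' @param c A [CountMatrix()].
#' @param s Size factors.
#' @param d A `DispersionModel` from [estimate_dispersions()], or a named
#'   per-gene alpha vector.
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @param gene Gene id.
#' @return p-value in (0, 1].
#' @export
nb_two_group_test <- function(c, s, d, group_a, group_b, gene) {
  stopifnot(inherits(c, "CountMatrix"))
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (!gene %in% rownames(c$counts)) stop("unknown gene: ", gene)
  alpha <- if (inherits(d, "DispersionModel")) d$alpha[[gene]] else d[[gene]]
  k <- c$counts[gene, ]
  sa <- s[group_a]; sb <- s[group_b]
  ka <- sum(k[group_a]); kb <- sum(k[group_b])
  q0 <- sum(k[c(group_a, group_b)]) / sum(c(sa, sb))
  nb_exact_pvalue(ka, kb, sum(sa), sum(sb), sum(sa^2), sum(sb^2), alpha, q0)
}

#' FPKM fold change between two sample groups
#'
#' Mean FPKM over `group_a` divided by mean FPKM over `group_b`, on
#' floored values (hence always finite).
#'
#' @param m A floored [ExpressionMatrix()].
#' @param gene Gene id.
#' @param group_a,group_b Non-empty character vectors of sample ids.
#' @return Positive real fold change.
#' @export
fpkm_fold_change <- function(m, gene, group_a, group_b) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!length(group_a) || !length(group_b)) stop("empty sample group")
  if (!gene %in% rownames(m$values)) stop("unknown gene: ", gene)
  mean(m$values[gene, group_a]) / mean(m$values[gene, group_b])
}

#' Sample ids belonging to a group
#' @param groups Named character vector (sample -> group label).
#' @param label Group label to select.
#' @return Character vector of sample ids.
#' @export
samples_in_group <- function(groups, label) names(groups)[groups == label]

#' Sample ids of all control tissues (groups named `control:*`)
#' @param groups Named character vector (sample -> group label).
#' @return Character vector of sample ids.
#' @export
control_samples <- function(groups) names(groups)[startsWith(groups, "control")]

#' Run the olfactory overexpression screen
#'
#' For every non-OR gene: compute the OE-vs-control FPKM fold change and
#' the exact conditional NB p-value on counts; retain genes passing
#' `fold >= fold_cutoff` and `p < p_cutoff`, or rescue genes whose mouse
#' ortholog is significantly overexpressed provided the human fold change
#' exceeds `rescue_human_fold_min`; finally remove retained genes whose
#' respiratory-epithelium FPKM exceeds `respiratory_ratio_cutoff` of their
#' mean OE FPKM (contamination filter). OR genes (per the catalog) are
#' excluded from the screen output.
#'
#' @param m Floored [ExpressionMatrix()] with `OE`, `respiratory` and
#'   `control:*` groups.
#' @param c Matching [CountMatrix()].
#' @param catalog [GeneCatalog()].
#' @param ortholog_map Optional [OrthologMap()] (needed for rescue).
#' @param mouse_screen Optional data frame with columns `gene_id` (mouse)
#'   and `significant` (logical), e.g. a thresholded screen of the mouse
#'   study.
#' @param cfg A [screen_config()].
#' @return Data frame of per-gene screen records: `gene_id`,
#'   `fold_change`, `p_value`, `respiratory_ratio`, `status` (one of
#'   `retained`, `rescued_by_mouse`, `failed_fold`, `failed_p`,
#'   `respiratory_filtered`), `evidence_class` (filled by
#'   [classify_evidence_class()]).
#' @export
run_screen <- function(m, c, catalog, ortholog_map = NULL, mouse_screen = NULL,
                       cfg = screen_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(c, "CountMatrix"))
  groups <- m$sample_groups
  oe <- samples_in_group(groups, "OE")
  resp <- samples_in_group(groups, "respiratory")
  ctrl <- control_samples(groups)
  if (!length(oe) || !length(ctrl))
    stop("screen requires OE and control samples")
  resp_filter_on <- length(resp) > 0
  if (!resp_filter_on)
    warning("no respiratory sample: contamination filter disabled")

  genes <- intersect(rownames(m$values),
                     catalog$gene_id[catalog$or_status == "non_OR"])
  genes <- intersect(genes, rownames(c$counts))

  s <- estimate_size_factors(c)
  # controls collapse to a single group for dispersion pooling
  disp_groups <- stats::setNames(
    ifelse(startsWith(groups, "control"), "control", groups), names(groups))
  d <- estimate_dispersions(c, s, disp_groups)

  oe_mean <- rowMeans(m$values[genes, oe, drop = FALSE])
  ctrl_mean <- rowMeans(m$values[genes, ctrl, drop = FALSE])
  fold <- oe_mean / ctrl_mean

  sa <- s[oe]; sb <- s[ctrl]
  Sa <- sum(sa); Sb <- sum(sb); SSa <- sum(sa^2); SSb <- sum(sb^2)
  ka <- rowSums(c$counts[genes, oe, drop = FALSE])
  kb <- rowSums(c$counts[genes, ctrl, drop = FALSE])
  q0 <- (ka + kb) / (Sa + Sb)
  pval <- vapply(seq_along(genes), function(i) {
    nb_exact_pvalue(ka[i], kb[i], Sa, Sb, SSa, SSb, d$alpha[[genes[i]]], q0[i])
  }, 1)
  p_use <- if (identical(cfg$adjust_p, "none")) pval else stats::p.adjust(pval, cfg$adjust_p)

  resp_ratio <- if (resp_filter_on) {
    rowMeans(m$values[genes, resp, drop = FALSE]) / oe_mean
  } else rep(NA_real_, length(genes))

  mouse_sig <- rep(FALSE, length(genes))
  if (!is.null(ortholog_map) && !is.null(mouse_screen)) {
    om <- ortholog_map[match(genes, ortholog_map$human_gene_id), "mouse_gene_id"]
    ms <- mouse_screen$significant[match(om, mouse_screen$gene_id)]
    mouse_sig <- !is.na(ms) & ms
  }

  pass_primary <- fold >= cfg$fold_cutoff & p_use < cfg$p_cutoff
  rescued <- !pass_primary & mouse_sig & fold > cfg$rescue_human_fold_min
  retained <- pass_primary | rescued

  status <- ifelse(pass_primary, "retained",
            ifelse(rescued, "rescued_by_mouse",
            ifelse(fold < cfg$fold_cutoff, "failed_fold", "failed_p")))
  filtered <- retained & resp_filter_on & resp_ratio > cfg$respiratory_ratio_cutoff
  status[filtered] <- "respiratory_filtered"

  data.frame(gene_id = genes, fold_change = unname(fold),
             p_value = unname(p_use), respiratory_ratio = unname(resp_ratio),
             status = status, evidence_class = NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign evidence classes A/B from literature-hit counts
#'
#' Genes surviving the screen are split into class A (documented olfactory
#' function: literature-hit count at or above the threshold) and class B
#' (little or no prior evidence). Genes without a hit count get `NA`.
#'
#' @param records Screen record data frame from [run_screen()].
#' @param catalog [GeneCatalog()] supplying `literature_hits`.
#' @param hit_threshold Minimum curated hit count for class A (default 1).
#' @return `records` with `evidence_class` filled for retained/rescued rows.
#' @export
classify_evidence_class <- function(records, catalog, hit_threshold = 1) {
  hits <- catalog$literature_hits[match(records$gene_id, catalog$gene_id)]
  keep <- records$status %in% c("retained", "rescued_by_mouse")
  cls <- ifelse(is.na(hits), NA_character_,
                ifelse(hits >= hit_threshold, "A", "B"))
  records$evidence_class <- ifelse(keep, cls, NA_character_)
  records
}

#' Fold change restricted to control tissues shared between two studies
#'
#' Cross-species expression comparisons (e.g. for the lipocalin family)
#' are only meaningful against the same control tissues; this computes
#' each species' OE/control fold change using only the named shared
#' control tissue groups.
#'
#' @param m_human,m_mouse Floored [ExpressionMatrix()] objects.
#' @param shared_tissues Character vector of tissue names; samples in
#'   groups `control:<tissue>` are used.
#' @param gene Human gene id.
#' @param ortholog_map [OrthologMap()] used to locate the mouse ortholog.
#' @return Named numeric vector `c(human = , mouse = )`; the mouse entry
#'   is `NA` when the gene has no ortholog.
#' @export
shared_tissue_fold_change <- function(m_human, m_mouse, shared_tissues, gene,
                                      ortholog_map) {
  shared_groups <- paste0("control:", shared_tissues)
  hs <- names(m_human$sample_groups)[m_human$sample_groups %in% shared_groups]
  ms <- names(m_mouse$sample_groups)[m_mouse$sample_groups %in% shared_groups]
  if (!length(hs) || !length(ms))
    stop("no shared control tissues present in both studies")
  h_oe <- samples_in_group(m_human$sample_groups, "OE")
  m_oe <- samples_in_group(m_mouse$sample_groups, "OE")
  human <- fpkm_fold_change(m_human, gene, h_oe, hs)
  mg <- ortholog_map$mouse_gene_id[match(gene, ortholog_map$human_gene_id)]
  mouse <- if (is.na(mg) || !mg %in% rownames(m_mouse$values)) NA_real_
           else fpkm_fold_change(m_mouse, mg, m_oe, ms)
  c(human = human, mouse = mouse)
}
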