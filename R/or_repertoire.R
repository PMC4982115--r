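#' Fraction of genes expressed above a cutoff
#'
#' A gene counts as expressed when its FPKM reaches the cutoff in at least
#' one of the listed samples (default cutoff 0.01).
#'
#' @param m [ExpressionMatrix()].
#' @param genes Non-empty character vector of gene ids.
#' @param cutoff Expression cutoff (FPKM).
#' @param samples Sample ids to consider; defaults to all samples.
#' @return Fraction in `[0, 1]`.
#' @export
expressed_fraction <- function(m, genes, cutoff = 0.01, samples = colnames(m$values)) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!length(genes)) stop("empty gene set")
  miss <- setdiff(genes, rownames(m$values))
  if (length(miss)) stop("unknown gene(s): ", paste(utils::head(miss, 5), collapse = ", "))
  v <- m$values[genes, samples, drop = FALSE]
  mean(apply(v >= cutoff, 1, any))
}

gene_mean_fpkm <- function(m, genes, samples) {
  rowMeans(m$values[genes, samples, drop = FALSE])
}

#' Intact-versus-pseudogene expression distribution test
#'
#' Compares the distributions of per-gene mean FPKM (across the listed
#' samples) between intact OR genes and OR pseudogenes with a two-sample
#' Kolmogorov-Smirnov test, and reports mean +/- SD per status.
#'
#' @param m [ExpressionMatrix()].
#' @param catalog [GeneCatalog()] with `or_status`.
#' @param samples Sample ids used for the per-gene mean.
#' @return List with `summary` (data frame: status, n, mean, sd),
#'   `ks_statistic`, `p_value`.
#' @export
status_distribution_test <- function(m, catalog, samples = colnames(m$values)) {
  genes_i <- intersect(catalog$gene_id[catalog$or_status == "intact"], rownames(m$values))
  genes_p <- intersect(catalog$gene_id[catalog$or_status == "pseudogene"], rownames(m$values))
  if (length(genes_i) < 2 || length(genes_p) < 2)
    stop("need >= 2 genes of each OR status")
  xi <- gene_mean_fpkm(m, genes_i, samples)
  xp <- gene_mean_fpkm(m, genes_p, samples)
  ks <- suppressWarnings(stats::ks.test(xi, xp))
  list(summary = data.frame(status = c("intact", "pseudogene"),
                            n = c(length(xi), length(xp)),
                            mean = c(mean(xi), mean(xp)),
                            sd = c(stats::sd(xi), stats::sd(xp))),
       ks_statistic = unname(ks$statistic),
       p_value = ks$p.value)
}

#' Rank and cumulative expression curves with the half-fraction skew
#'
#' Genes are ranked by mean FPKM (descending, FPKM ties broken by gene id
#' for determinism). The cumulative curve gives, for each rank fraction
#' k/n, the fraction of the set's summed expression contributed by the top
#' k genes. The half-fraction is the smallest k/n whose top-k sum reaches
#' half the total -- the skew statistic: strongly skewed repertoires have
#' small half-fractions.
#'
#' @param m [ExpressionMatrix()].
#' @param genes Gene ids (>= 1 with positive expression).
#' @param samples Sample ids used for the per-gene mean.
#' @return List with `rank_curve` (data frame: rank, gene_id, fpkm),
#'   `cumulative_curve` (data frame: rank_fraction, cumulative_fraction)
#'   and `half_fraction`.
#' @export
rank_and_cumulative <- function(m, genes, samples = colnames(m$values)) {
  x <- gene_mean_fpkm(m, genes, samples)
  tot <- sum(x)
  if (tot <= 0) stop("total expression of the gene set is zero")
  ord <- order(-x, names(x))
  x <- x[ord]
  cum <- cumsum(x) / tot
  n <- length(x)
  k <- unname(which(cum >= 0.5))[1]
  list(rank_curve = data.frame(rank = seq_len(n), gene_id = names(x),
                               fpkm = unname(x), row.names = NULL),
       cumulative_curve = data.frame(rank_fraction = seq_len(n) / n,
                                     cumulative_fraction = unname(cum)),
       half_fraction = k / n)
}

#' Class I versus class II OR comparison
#'
#' Two complementary tests of the observation that class II (mammalian
#' expanded) ORs are more strongly expressed than class I ("fish-like")
#' ORs: a 2x2 chi-square test on expressed/not-expressed counts by class,
#' and a two-sample KS test on the per-gene expression levels.
#'
#' @param m [ExpressionMatrix()].
#' @param catalog [GeneCatalog()] with `or_class`.
#' @param samples Sample ids.
#' @param cutoff Expression cutoff for the "expressed" call.
#' @return List with `table` (2x2 expressed counts), `chisq_p`,
#'   `chisq_unreliable` (TRUE when an expected cell < 1), `ks_p`.
#' @export
class_comparison <- function(m, catalog, samples = colnames(m$values), cutoff = 0.01) {
  g1 <- intersect(catalog$gene_id[!is.na(catalog$or_class) & catalog$or_class == "I"],
                  rownames(m$values))
  g2 <- intersect(catalog$gene_id[!is.na(catalog$or_class) & catalog$or_class == "II"],
                  rownames(m$values))
  if (!length(g1) || !length(g2)) stop("both OR classes must be present")
  expr1 <- apply(m$values[g1, samples, drop = FALSE] >= cutoff, 1, any)
  expr2 <- apply(m$values[g2, samples, drop = FALSE] >= cutoff, 1, any)
  tab <- rbind(I = c(expressed = sum(expr1), not_expressed = sum(!expr1)),
               II = c(expressed = sum(expr2), not_expressed = sum(!expr2)))
  chs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  ks <- suppressWarnings(stats::ks.test(gene_mean_fpkm(m, g1, samples),
                                        gene_mean_fpkm(m, g2, samples)))
  list(table = tab,
       chisq_p = chs$p.value,
       chisq_unreliable = any(chs$expected < 1),
       ks_p = ks$p.value)
}

#' Association between functionality score and expression
#'
#' Splits OR genes at the median functionality score (the predicted
#' probability that the locus encodes a functional receptor) and compares
#' the expression of the high-score and low-score halves with a
#' two-sample KS test.
#'
#' @param m [ExpressionMatrix()].
#' @param catalog [GeneCatalog()] with `functionality_score`.
#' @param samples Sample ids.
#' @return List with `ks_statistic`, `p_value`, `n_high`, `n_low`.
#' @export
score_expression_association <- function(m, catalog, samples = colnames(m$values)) {
  keep <- !is.na(catalog$functionality_score) & catalog$gene_id %in% rownames(m$values)
  cat2 <- catalog[keep, , drop = FALSE]
  if (length(unique(cat2$functionality_score)) < 2)
    stop("all functionality scores are equal; median split impossible")
  med <- stats::median(cat2$functionality_score)
  ord <- order(cat2$functionality_score, cat2$gene_id)
  n <- nrow(cat2)
  lo_idx <- ord[seq_len(floor(n / 2))]
  hi_idx <- ord[(floor(n / 2) + 1):n]
  if (length(lo_idx) < 2 || length(hi_idx) < 2)
    stop("need >= 2 genes on each side of the median split")
  x_hi <- gene_mean_fpkm(m, cat2$gene_id[hi_idx], samples)
  x_lo <- gene_mean_fpkm(m, cat2$gene_id[lo_idx], samples)
  ks <- suppressWarnings(stats::ks.test(x_hi, x_lo))
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       n_high = length(hi_idx), n_low = length(lo_idx), median_score = med)
}

#' Rerun an analysis excluding segregating-pseudogene loci
#'
#' Sensitivity rerun: OR loci that are intact in some individuals and
#' pseudogenized in others ("segregating pseudogenes") could distort
#' repertoire statistics. This helper evaluates any catalog-driven
#' analysis twice -- on the full catalog and on the catalog with flagged
#' loci removed -- and returns both results side by side.
#'
#' @param catalog [GeneCatalog()] with `segregating_pseudogene` flags.
#' @param fn Function of a single catalog argument returning the analysis
#'   result.
#' @return List with elements `full` and `excluded`.
#' @export
rerun_excluding_segregating <- function(catalog, fn) {
  if (anyNA(catalog$segregating_pseudogene))
    stop("segregating_pseudogene flags must be present (non-NA)")
  reduced <- catalog[!catalog$segregating_pseudogene, , drop = FALSE]
  list(full = fn(catalog), excluded = fn(reduced))
}
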