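# Independent brute-force oracles used to verify the package's statistics.
# Each is written from the definition, not from the implementation it checks.

# two-sample KS statistic as the maximal ECDF gap, scanning every data point
ks_stat_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  gaps <- vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), 1)
  max(gaps)
}

# exact conditional (binomial) two-sided test: total ka+kb split with
# success probability pr; sums P of all splits no more likely than observed
binom_exact_oracle <- function(ka, kb, pr) {
  ks <- ka + kb
  p_all <- stats::dbinom(0:ks, ks, pr)
  p_obs <- p_all[ka + 1]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]))
}

# smallest k/n whose top-k sum reaches half the total, by linear scan
half_fraction_oracle <- function(x) {
  x <- sort(x, decreasing = TRUE)
  tot <- sum(x)
  acc <- 0
  for (k in seq_along(x)) {
    acc <- acc + x[k]
    if (acc >= tot / 2) return(k / length(x))
  }
  1
}

# Pearson r from the raw covariance formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# enumerate every window on both strands and score it position by position
scan_pwm_oracle <- function(seq, p, threshold, both_strands = TRUE) {
  bases <- c("A", "C", "G", "T")
  lo <- log2(p$matrix / p$background)
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- p$length
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  if (n >= L) {
    for (s in 1:(n - L + 1)) {
      win <- chars[s:(s + L - 1)]
      sc_f <- 0; sc_r <- 0
      for (j in 1:L) {
        b <- win[j]
        sc_f <- sc_f + if (b %in% bases) lo[b, j] else 0
        rb <- if (win[L - j + 1] %in% bases) comp[[win[L - j + 1]]] else "N"
        sc_r <- sc_r + if (rb %in% bases) lo[rb, j] else 0
      }
      if (sc_f >= threshold)
        out[[length(out) + 1]] <- data.frame(start = s, strand = "+", score = sc_f)
      if (both_strands && sc_r >= threshold)
        out[[length(out) + 1]] <- data.frame(start = s, strand = "-", score = sc_r)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), strand = character(0), score = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided Fisher exact p by full hypergeometric enumeration of the 2x2
# tables with the observed margins
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  }, 1)
  p_obs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# ---- fixture builders ------------------------------------------------------

# small ExpressionMatrix from a named row list; floor = NA leaves values as-is
make_expr <- function(rows, groups, floor = 0.003) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  em <- ExpressionMatrix(m, groups)
  if (is.na(floor)) em else apply_fpkm_floor(em, floor)
}

# minimal catalog for a set of gene ids
make_catalog <- function(gene_id, or_status = "non_OR", or_class = NA_character_,
                         segregating = FALSE, ortholog = NA_character_,
                         hits = NA_integer_, score = NA_real_) {
  GeneCatalog(data.frame(
    gene_id = gene_id, symbol = gene_id,
    or_status = rep_len(or_status, length(gene_id)),
    or_class = rep_len(or_class, length(gene_id)),
    segregating_pseudogene = rep_len(segregating, length(gene_id)),
    ortholog_id = rep_len(ortholog, length(gene_id)),
    literature_hits = rep_len(hits, length(gene_id)),
    functionality_score = rep_len(score, length(gene_id)),
    stringsAsFactors = FALSE))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
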