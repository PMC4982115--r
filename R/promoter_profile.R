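BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param matrix 4-by-L numeric matrix of per-position base probabilities,
#'   rows in A, C, G, T order; columns must sum to 1 (within 1e-6).
#'   A count matrix is accepted and converted with `pseudocount`.
#' @param background Length-4 background base probabilities (sum 1).
#' @param pseudocount Added to every cell before normalizing when a count
#'   matrix is supplied.
#' @return Object of class `PWM` with elements `matrix`, `background`,
#'   `length`.
#' @export
pwm <- function(matrix, background = rep(0.25, 4), pseudocount = 0.01) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-6)) {            # counts -> probabilities
    matrix <- sweep(matrix + pseudocount, 2, cs + 4 * pseudocount, "/")
  }
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  rownames(matrix) <- BASES
  structure(list(matrix = matrix, background = background, length = ncol(matrix)),
            class = "PWM")
}

#' Read a PWM from a JASPAR-style text file
#'
#' Accepts the plain-text JASPAR layout: an optional `>name` header and
#' four lines `A [ 3 10 2 ... ]` (brackets optional) in A, C, G, T order.
#' Counts are converted to probabilities with the pseudocount.
#'
#' @param path File path.
#' @inheritParams pwm
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, ">") & nzchar(trimws(lines))]
  if (length(lines) != 4) stop("expected 4 base rows in PWM file")
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]", "", trimws(l))
    as.numeric(strsplit(trimws(gsub("[][]", "", l)), "[[:space:]]+")[[1]])
  })
  m <- do.call(rbind, rows)
  pwm(m, background = background, pseudocount = pseudocount)
}

#' Maximum attainable log-odds score of a PWM
#' @param p A [pwm()].
#' @return Sum over positions of the best per-position log2 odds.
#' @export
pwm_max_score <- function(p) {
  lo <- log2(p$matrix / p$background)
  sum(apply(lo, 2, max))
}

#' Consensus sequence of a PWM
#' @param p A [pwm()].
#' @export
pwm_consensus <- function(p) {
  paste(BASES[apply(p$matrix, 2, which.max)], collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

seq_to_index <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], BASES)  # N and others -> NA
}

scan_one_strand <- function(idx, lo, L) {
  n <- length(idx)
  if (n < L) return(data.frame(start = integer(0), score = numeric(0)))
  # N (NA index) contributes 0 log-odds
  score <- numeric(n - L + 1)
  for (j in seq_len(L)) {
    col <- lo[, j]
    contrib <- col[idx[j:(j + n - L)]]
    contrib[is.na(contrib)] <- 0
    score <- score + contrib
  }
  data.frame(start = seq_len(n - L + 1), score = score)
}

#' Scan a sequence with a PWM
#'
#' Slides the PWM over every window of the sequence and reports windows
#' whose summed log2(probability/background) score reaches the threshold.
#' `N` positions contribute 0 log-odds. With `both_strands`, the reverse
#' complement is scanned too and hits are reported on the input sequence's
#' coordinates by their 5'-most base.
#'
#' @param seq Character scalar over `A C G T N` (case-insensitive).
#' @param p A [pwm()].
#' @param threshold Log-odds threshold; default 80 percent of the PWM's
#'   maximal score.
#' @param both_strands Scan the reverse complement as well.
#' @return Data frame of hits: `start` (1-based position of the match's
#'   leftmost base in `seq`), `end`, `strand`, `score`.
#' @export
scan_pwm <- function(seq, p, threshold = 0.8 * pwm_max_score(p),
                     both_strands = TRUE) {
  stopifnot(inherits(p, "PWM"))
  L <- p$length
  lo <- log2(p$matrix / p$background)
  idx <- seq_to_index(seq)
  fwd <- scan_one_strand(idx, lo, L)
  fwd$strand <- rep("+", nrow(fwd))
  hits <- fwd
  if (both_strands && length(idx) >= L) {
    rev_idx <- rev(5 - idx)               # A<->T, C<->G on reversed sequence
    rv <- scan_one_strand(rev_idx, lo, L)
    n <- length(idx)
    rv$start <- n - L + 2 - rv$start      # map back to input coordinates
    rv$strand <- rep("-", nrow(rv))
    hits <- rbind(hits, rv)
  }
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  hits$end <- hits$start + L - 1
  hits <- hits[order(hits$start, hits$strand), c("start", "end", "strand", "score")]
  rownames(hits) <- NULL
  hits
}

#' Convert hit positions to TSS-relative offsets
#'
#' Offsets count upstream positive: a hit whose 5'-most base sits `d` bp
#' upstream of the TSS base has offset `d`.
#'
#' @param hits Data frame from [scan_pwm()].
#' @param tss_pos 1-based position of the TSS base within the scanned
#'   sequence (default: its last base, for purely upstream sequences).
#' @return `hits` with an added `offset` column.
#' @export
hits_to_offsets <- function(hits, tss_pos) {
  hits$offset <- tss_pos - hits$start
  hits
}

#' Select non-redundant promoter windows per gene
#'
#' Builds a window (default -750 bp to +250 bp) around every transcript's
#' TSS; within a gene, windows are retained greedily in descending
#' transcript-FPKM order and a candidate is dropped when it overlaps an
#' already-retained window of the same gene by at least `dedup_overlap`
#' bp, so near-identical TSSs contribute one window.
#'
#' @param tss Data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `pos` (TSS boundary coordinate, 0-based half-open convention),
#'   `strand`, `fpkm`.
#' @param window Length-2 integer vector, the window relative to the TSS
#'   in transcript orientation (`c(-750, 250)` spans 750 bp upstream and
#'   250 bp downstream).
#' @param dedup_overlap Overlap (bp) at or above which a window is
#'   considered redundant.
#' @return Data frame of retained windows: the `tss` columns plus
#'   genomic `start`, `end` (0-based half-open).
#' @export
select_promoter_windows <- function(tss, window = c(-750, 250),
                                    dedup_overlap = 500) {
  win <- lapply(seq_len(nrow(tss)), function(i) {
    p <- tss$pos[i]
    if (tss$strand[i] == "+") c(p + window[1], p + window[2])
    else c(p - window[2], p - window[1])
  })
  tss$start <- vapply(win, `[`, 1, 1)
  tss$end <- vapply(win, `[`, 1, 2)
  keep <- logical(nrow(tss))
  for (g in unique(tss$gene_id)) {
    idx <- which(tss$gene_id == g)
    idx <- idx[order(-tss$fpkm[idx], tss$transcript_id[idx])]
    kept <- integer(0)
    for (i in idx) {
      ov <- vapply(kept, function(k) {
        max(0, min(tss$end[i], tss$end[k]) - max(tss$start[i], tss$start[k]))
      }, 1)
      if (!length(ov) || all(ov < dedup_overlap)) {
        keep[i] <- TRUE
        kept <- c(kept, i)
      }
    }
  }
  out <- tss[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TSS-anchored positional profile of motif hits
#'
#' Sums motif hits across promoters into bins over `[0, window_bp)` bp
#' upstream of the TSS. Hits outside the window are excluded; the bin
#' counts always sum to the number of included hits.
#'
#' @param offsets Numeric vector of hit offsets (bp upstream of TSS,
#'   positive upstream), e.g. pooled from [hits_to_offsets()].
#' @param window_bp Profile extent upstream (must be divisible by
#'   `bin_bp`); default 4000.
#' @param bin_bp Bin width; default 100.
#' @return Data frame `bin_start`, `bin_end`, `count` (bins ordered from
#'   the TSS outward).
#' @export
positional_profile <- function(offsets, window_bp = 4000, bin_bp = 100) {
  if (window_bp %% bin_bp != 0) stop("window_bp must be divisible by bin_bp")
  offsets <- offsets[offsets >= 0 & offsets < window_bp]
  starts <- seq(0, window_bp - bin_bp, by = bin_bp)
  count <- vapply(starts, function(s) sum(offsets >= s & offsets < s + bin_bp), 1L)
  data.frame(bin_start = starts, bin_end = starts + bin_bp, count = count)
}

#' Motif enrichment in target versus background promoter windows
#'
#' Scans both window sets with the PWM and compares the proportions of
#' windows carrying at least one hit with Fisher's exact test (2x2:
#' with-hit / without-hit, target / background).
#'
#' @param target_windows,background_windows Character vectors of window
#'   sequences.
#' @param p A [pwm()].
#' @param threshold Log-odds threshold passed to [scan_pwm()].
#' @param both_strands Passed to [scan_pwm()].
#' @return List with `odds_ratio` (sample odds ratio; `NA` when
#'   undefined), `p_value`, `table`.
#' @export
motif_enrichment <- function(target_windows, background_windows, p,
                             threshold = 0.8 * pwm_max_score(p),
                             both_strands = TRUE) {
  if (!length(target_windows) || !length(background_windows))
    stop("both window sets must be non-empty")
  has_hit <- function(seqs) vapply(seqs, function(s) {
    nrow(scan_pwm(s, p, threshold, both_strands)) > 0
  }, TRUE, USE.NAMES = FALSE)
  t_hit <- has_hit(target_windows)
  b_hit <- has_hit(background_windows)
  tab <- rbind(target = c(hit = sum(t_hit), no_hit = sum(!t_hit)),
               background = c(hit = sum(b_hit), no_hit = sum(!b_hit)))
  if (all(tab[, 1] == 0) || all(tab[, 2] == 0))
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(or), p_value = ft$p.value, table = tab)
}
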