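#' Curation configuration for assembled transcripts
#'
#' @param min_transcript_fpkm Transcripts below this FPKM are excluded to
#'   avoid assembly inaccuracies (default 1.0).
#' @param min_isoform_fraction Isoforms whose FPKM is below this fraction
#'   of their gene's major isoform are removed (default 0.0015, i.e.
#'   0.15 percent).
#' @param drop_class_codes Assembler comparison class codes removed
#'   outright (default `x`, `s`, `p`: opposite-strand overlaps and
#'   suspected polymerase run-on fragments).
#' @return List of class `CurationConfig`.
#' @export
curation_config <- function(min_transcript_fpkm = 1.0,
                            min_isoform_fraction = 0.0015,
                            drop_class_codes = c("x", "s", "p")) {
  stopifnot(min_isoform_fraction >= 0, min_isoform_fraction <= 1)
  structure(list(min_transcript_fpkm = min_transcript_fpkm,
                 min_isoform_fraction = min_isoform_fraction,
                 drop_class_codes = drop_class_codes),
            class = "CurationConfig")
}

#' Curate assembled transcript models
#'
#' Applies the removal rules in fixed order: (1) dropped class codes;
#' (2) per-transcript FPKM below `min_transcript_fpkm`; (3) isoform FPKM
#' below `min_isoform_fraction` of the gene's major (highest-FPKM)
#' isoform. Each removed model carries the first rule that triggered.
#' The major isoform for rule 3 is determined before any removal, so the
#' result does not depend on input order.
#'
#' @param models List of [TranscriptModel()]s.
#' @param cfg A [curation_config()].
#' @return List with `kept` (transcript models) and `removed` (data frame
#'   `transcript_id`, `gene_id`, `reason`).
#' @export
curate_transcripts <- function(models, cfg = curation_config()) {
  if (!length(models)) return(list(kept = list(), removed = data.frame(
    transcript_id = character(0), gene_id = character(0), reason = character(0))))
  gid <- vapply(models, `[[`, "", "gene_id")
  fpkm <- vapply(models, `[[`, 1, "fpkm")
  cc <- vapply(models, function(x) ifelse(is.na(x$class_code), "", x$class_code), "")
  major <- tapply(fpkm, gid, max)
  reason <- rep(NA_character_, length(models))
  reason[cc %in% cfg$drop_class_codes] <- "class_code"
  sel <- is.na(reason) & fpkm < cfg$min_transcript_fpkm
  reason[sel] <- "min_transcript_fpkm"
  sel <- is.na(reason) & fpkm < cfg$min_isoform_fraction * major[gid]
  reason[sel] <- "isoform_fraction"
  removed_idx <- which(!is.na(reason))
  list(kept = models[is.na(reason)],
       removed = data.frame(
         transcript_id = vapply(models[removed_idx], `[[`, "", "transcript_id"),
         gene_id = gid[removed_idx],
         reason = reason[removed_idx],
         stringsAsFactors = FALSE, row.names = NULL))
}

#' Structure statistics of one transcript model
#'
#' Computes the transcript length (sum of exon lengths), genomic span,
#' CDS length (exonic overlap with the ORF), strand-aware 5' and 3' UTR
#' lengths, exon counts and the number of wholly non-coding 5' exons.
#' When the annotated ORF is not fully covered by the exon chain the
#' record is flagged (`cds_complete = FALSE`) and `cds_length` reports
#' the covered portion only.
#'
#' @param model A [TranscriptModel()] (a `cds` is required for the
#'   UTR/CDS split; without one only lengths/spans are reported).
#' @return One-row data frame (a StructureRecord): `transcript_id`,
#'   `gene_id`, `transcript_length`, `genomic_span`, `cds_length`,
#'   `utr5_length`, `utr3_length`, `n_5prime_noncoding_exons`, `n_exons`,
#'   `cds_complete`, `tss`, `strand`.
#' @export
structure_stats <- function(model) {
  ex <- model$exons
  tl <- sum(ex[, 2] - ex[, 1])
  span <- max(ex[, 2]) - min(ex[, 1])
  tss <- infer_tss(model)
  if (is.null(model$cds)) {
    return(data.frame(transcript_id = model$transcript_id, gene_id = model$gene_id,
                      transcript_length = tl, genomic_span = span,
                      cds_length = NA_real_, utr5_length = NA_real_,
                      utr3_length = NA_real_, n_5prime_noncoding_exons = NA_integer_,
                      n_exons = nrow(ex), cds_complete = NA,
                      tss = tss$pos, strand = model$strand,
                      stringsAsFactors = FALSE))
  }
  cds <- model$cds
  ov <- pmax(0, pmin(ex[, 2], cds[2]) - pmax(ex[, 1], cds[1]))
  cds_len <- sum(ov)
  cds_complete <- cds_len == (cds[2] - cds[1])
  # exonic bases genomically left / right of the ORF
  left <- sum(pmax(0, pmin(ex[, 2], cds[1]) - ex[, 1]))
  right <- sum(pmax(0, ex[, 2] - pmax(ex[, 1], cds[2])))
  if (model$strand == "+") {
    utr5 <- left; utr3 <- right
    n5 <- sum(ex[, 2] <= cds[1])
  } else {
    utr5 <- right; utr3 <- left
    n5 <- sum(ex[, 1] >= cds[2])
  }
  data.frame(transcript_id = model$transcript_id, gene_id = model$gene_id,
             transcript_length = tl, genomic_span = span,
             cds_length = cds_len, utr5_length = utr5, utr3_length = utr3,
             n_5prime_noncoding_exons = as.integer(n5), n_exons = nrow(ex),
             cds_complete = cds_complete, tss = tss$pos, strand = model$strand,
             stringsAsFactors = FALSE)
}

#' Structure records for a list of transcript models
#' @param models List of [TranscriptModel()]s.
#' @return Data frame, one [structure_stats()] row per model.
#' @export
structure_table <- function(models) {
  do.call(rbind, lapply(models, structure_stats))
}

#' Mean and population SD of structure statistics
#'
#' Descriptive summary of a structure table (lengths in bp). SDs are
#' population SDs (divisor n), matching descriptive use.
#'
#' @param records Data frame from [structure_table()].
#' @return Data frame with `statistic`, `mean`, `sd`, `n`.
#' @export
structure_summary <- function(records) {
  cols <- c("transcript_length", "genomic_span", "cds_length",
            "utr5_length", "utr3_length", "n_5prime_noncoding_exons", "n_exons")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  do.call(rbind, lapply(cols, function(cl) {
    x <- records[[cl]]
    x <- x[!is.na(x)]
    data.frame(statistic = cl, mean = mean(x), sd = pop_sd(x), n = length(x),
               stringsAsFactors = FALSE)
  }))
}

cds_start_position <- function(cds, strand) {
  # first base of the initiating codon in transcript orientation
  if (strand == "+") cds[1] else cds[2] - 1
}

#' Detect aberrant (start-codon-skipping) transcripts
#'
#' A transcript of a gene with an intact ORF is called aberrant when its
#' exon union does not contain the first base of the initiating codon --
#' splicing that skips the start codon pseudogenizes the transcript even
#' though the genomic ORF is intact. Transcripts that retain the start
#' but splice out part of the coding region are flagged separately as
#' `internal_disruption`. Genes are classified from their transcripts'
#' flags as `all_functional`, `mixed` or `all_aberrant`.
#'
#' @param models List of [TranscriptModel()]s.
#' @param cds_by_gene Optional named list giving each gene's ORF interval;
#'   defaults to the first non-NULL `cds` among the gene's models.
#' @return List with `transcripts` (data frame: `transcript_id`,
#'   `gene_id`, `functional`, `reason`) and `genes` (data frame:
#'   `gene_id`, `class`). Genes without a known ORF are skipped with a
#'   warning.
#' @export
detect_aberrant <- function(models, cds_by_gene = NULL) {
  gid <- vapply(models, `[[`, "", "gene_id")
  if (is.null(cds_by_gene)) {
    cds_by_gene <- list()
    for (m in models)
      if (!is.null(m$cds) && is.null(cds_by_gene[[m$gene_id]]))
        cds_by_gene[[m$gene_id]] <- m$cds
  }
  no_cds <- setdiff(unique(gid), names(cds_by_gene))
  if (length(no_cds))
    warning("gene(s) without a known ORF skipped: ", paste(no_cds, collapse = ", "))
  keep <- gid %in% names(cds_by_gene)
  rows <- lapply(models[keep], function(m) {
    cds <- cds_by_gene[[m$gene_id]]
    start <- cds_start_position(cds, m$strand)
    ex <- m$exons
    has_start <- any(ex[, 1] <= start & start < ex[, 2])
    ov <- sum(pmax(0, pmin(ex[, 2], cds[2]) - pmax(ex[, 1], cds[1])))
    full <- ov == cds[2] - cds[1]
    reason <- if (!has_start) "skips_start"
              else if (!full) "internal_disruption"
              else NA_character_
    data.frame(transcript_id = m$transcript_id, gene_id = m$gene_id,
               functional = is.na(reason), reason = reason,
               stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, rows)
  genes <- do.call(rbind, lapply(split(tr$functional, tr$gene_id), function(f) {
    cls <- if (all(f)) "all_functional" else if (any(f)) "mixed" else "all_aberrant"
    data.frame(class = cls, stringsAsFactors = FALSE)
  }))
  genes <- data.frame(gene_id = rownames(genes), class = genes$class,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(transcripts = tr, genes = genes)
}

#' Infer the transcription start site of a transcript
#'
#' The TSS is reported as the transcript's 5' boundary coordinate in the
#' 0-based half-open convention: the smallest exon start on the plus
#' strand, the largest exon end on the minus strand.
#'
#' @param model A [TranscriptModel()].
#' @return List with `chrom`, `pos`, `strand`.
#' @export
infer_tss <- function(model) {
  pos <- if (model$strand == "+") min(model$exons[, 1]) else max(model$exons[, 2])
  list(chrom = model$chrom, pos = pos, strand = model$strand)
}
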