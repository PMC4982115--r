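#' Construct an expression (FPKM) matrix
#'
#' The central container of the package: a genes-by-samples matrix of FPKM
#' values together with a sample-to-group map and, once
#' [apply_fpkm_floor()] has been called, the floor that was applied.
#'
#' Group labels are free-form but three conventions are used throughout:
#' `"OE"` for olfactory epithelium samples, `"respiratory"` for the
#' respiratory-epithelium control, and `"control:<tissue>"` for each body
#' control tissue.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values must be
#'   non-negative and non-missing.
#' @param sample_groups Named character vector mapping every sample id to a
#'   group label.
#' @param floor The expression floor already applied to `values`, or
#'   `NA` if no floor has been applied yet.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `sample_groups`, `floor`.
#' @export
ExpressionMatrix <- function(values, sample_groups, floor = NA_real_) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (any(values < 0)) stop("expression values must be non-negative")
  miss <- setdiff(colnames(values), names(sample_groups))
  if (length(miss))
    stop("samples without a group label: ", paste(miss, collapse = ", "))
  sample_groups <- sample_groups[colnames(values)]
  structure(list(values = values,
                 sample_groups = sample_groups,
                 floor = floor),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (floor: %s)\n",
              nrow(x$values), ncol(x$values),
              ifelse(is.na(x$floor), "none", format(x$floor))))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$sample_groups)),
                               table(x$sample_groups)), collapse = " "), "\n")
  invisible(x)
}

#' Construct a read-count matrix
#'
#' Integer companion of [ExpressionMatrix()], used by the overexpression
#' screen's count-based test.
#'
#' @param counts Integer-valued matrix, genes in rows, samples in columns.
#' @param sample_groups Named character vector mapping sample id to group.
#' @return An object of class `CountMatrix`.
#' @export
CountMatrix <- function(counts, sample_groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene rownames and sample colnames")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  miss <- setdiff(colnames(counts), names(sample_groups))
  if (length(miss))
    stop("samples without a group label: ", paste(miss, collapse = ", "))
  storage.mode(counts) <- "double"
  structure(list(counts = counts, sample_groups = sample_groups[colnames(counts)]),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

## ---- TSV readers/writers -------------------------------------------------

read_table_checked <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected gene-id column plus >=1 sample column in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated gene id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) | is.na(vals[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value in %s at gene '%s', sample '%s'",
                   path, ids[bad[1]], colnames(vals)[j]))
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Read an expression table from TSV
#'
#' Plain TSV with one header row of sample ids and gene ids in the first
#' column. The FPKM floor is deliberately NOT applied here; call
#' [apply_fpkm_floor()] once after loading.
#'
#' @param path Path to the TSV file.
#' @param group_map Named character vector mapping sample id to group label.
#' @return An [ExpressionMatrix()] with `floor = NA`.
#' @export
read_expression_table <- function(path, group_map) {
  ExpressionMatrix(read_table_checked(path), group_map)
}

#' Write an expression table as TSV
#' @param m An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path) {
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from TSV
#' @inheritParams read_expression_table
#' @return A [CountMatrix()].
#' @export
read_count_table <- function(path, group_map) {
  m <- read_table_checked(path)
  CountMatrix(m, group_map)
}

#' Write a count table as TSV
#' @param c A `CountMatrix`.
#' @param path Output path.
#' @export
write_count_table <- function(c, path) {
  df <- data.frame(gene_id = rownames(c$counts), c$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the FPKM expression floor
#'
#' Zero FPKM values break log transforms and ratio statistics; following
#' common practice for this assay every value below the floor is raised to
#' it (default 0.003). Applied once, immediately after loading, before any
#' log transform. Idempotent.
#'
#' @param m An `ExpressionMatrix`.
#' @param floor Positive real; values below it are set to it.
#' @return The floored `ExpressionMatrix` with its `floor` field set.
#' @export
apply_fpkm_floor <- function(m, floor = 0.003) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!is.numeric(floor) || length(floor) != 1 || is.na(floor) || floor <= 0)
    stop("floor must be a single positive number")
  m$values[m$values < floor] <- floor
  m$floor <- floor
  m
}

## ---- Gene catalog and ortholog map ---------------------------------------

#' Validate / construct a gene catalog
#'
#' Per-gene annotation table: olfactory-receptor status, OR class,
#' segregating-pseudogene flag, mouse ortholog, literature-hit count and a
#' functionality score (probability the locus encodes a functional
#' receptor protein).
#'
#' @param df Data frame with columns `gene_id`, `symbol`, `or_status`
#'   (one of `intact`, `pseudogene`, `non_OR`), `or_class` (`I`, `II` or
#'   `NA`), `segregating_pseudogene` (logical), `ortholog_id`,
#'   `literature_hits`, `functionality_score`.
#' @return The validated data frame with class `GeneCatalog` prepended.
#' @export
GeneCatalog <- function(df) {
  need <- c("gene_id", "symbol", "or_status", "or_class",
            "segregating_pseudogene", "ortholog_id", "literature_hits",
            "functionality_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene catalog missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in catalog: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (!all(df$or_status %in% c("intact", "pseudogene", "non_OR")))
    stop("or_status must be intact / pseudogene / non_OR")
  bad <- !is.na(df$or_class) & df$or_status == "non_OR"
  if (any(bad))
    stop("or_class set for non-OR gene(s): ",
         paste(df$gene_id[bad], collapse = ", "))
  df$segregating_pseudogene <- as.logical(df$segregating_pseudogene)
  class(df) <- c("GeneCatalog", class(df))
  df
}

#' Read a gene catalog TSV
#' @param path Path to TSV with the [GeneCatalog()] columns.
#' @export
read_gene_catalog <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  GeneCatalog(df)
}

#' Write a gene catalog TSV
#' @param catalog A `GeneCatalog`.
#' @param path Output path.
#' @export
write_gene_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a human-to-mouse ortholog map
#' @param df Data frame with columns `human_gene_id`, `mouse_gene_id`.
#'   Human keys must be unique; the map may be partial.
#' @export
OrthologMap <- function(df) {
  need <- c("human_gene_id", "mouse_gene_id")
  if (!all(need %in% names(df)))
    stop("ortholog map needs columns human_gene_id, mouse_gene_id")
  if (anyDuplicated(df$human_gene_id))
    stop("duplicate human gene keys in ortholog map")
  class(df) <- c("OrthologMap", class(df))
  df
}

#' Read an ortholog map TSV
#' @param path Path to a two-column TSV (`human_gene_id`, `mouse_gene_id`).
#' @export
read_ortholog_map <- function(path) {
  OrthologMap(utils::read.delim(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE))
}

## ---- Transcript models (GTF) ---------------------------------------------

#' Construct a transcript model
#'
#' Stranded exon chain plus the gene's annotated ORF interval and an
#' abundance estimate; the unit of transcript-structure analysis. All
#' internal genomic coordinates are 0-based half-open; GTF I/O converts at
#' the boundary.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of 0-based half-open `[start, end)`
#'   intervals; they are sorted and must not overlap.
#' @param cds Length-2 vector, the ORF interval (0-based half-open), or
#'   `NULL` for transcripts of genes without an annotated ORF.
#' @param fpkm Non-negative abundance.
#' @param class_code Single assembler-comparison class code character or `NA`.
#' @return Object of class `TranscriptModel`.
#' @export
TranscriptModel <- function(transcript_id, gene_id, chrom, strand, exons,
                            cds = NULL, fpkm = 0, class_code = NA_character_) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.null(cds)) {
    cds <- as.numeric(cds)
    if (length(cds) != 2 || cds[2] <= cds[1]) stop("cds must be a non-empty interval")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 fpkm = as.numeric(fpkm), class_code = class_code),
            class = "TranscriptModel")
}

#' Read transcript models from a GTF file
#'
#' Exon rows (1-based, closed intervals) are converted to the internal
#' 0-based half-open convention. Per-transcript FPKM is taken from the
#' attribute named by `fpkm_attr`; the gene ORF from optional `CDS` rows.
#'
#' @param path GTF file.
#' @param fpkm_attr Name of the GTF attribute holding the FPKM (default
#'   `"FPKM"`).
#' @return List of [TranscriptModel()] objects.
#' @export
read_transcript_models <- function(path, fpkm_attr = "FPKM") {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!all(c("transcript_id", "gene_id") %in% names(df)))
    stop("GTF lacks transcript_id/gene_id attributes")
  ex <- df[df$type == "exon", , drop = FALSE]
  cdsr <- df[df$type == "CDS", , drop = FALSE]
  models <- lapply(split(ex, ex$transcript_id), function(d) {
    if (length(unique(as.character(d$strand))) != 1)
      stop("inconsistent strand within transcript ", d$transcript_id[1])
    fp <- if (fpkm_attr %in% names(d)) suppressWarnings(as.numeric(d[[fpkm_attr]][1])) else NA_real_
    cc <- if ("class_code" %in% names(d)) as.character(d$class_code[1]) else NA_character_
    cd <- NULL
    ci <- cdsr[cdsr$transcript_id == d$transcript_id[1], , drop = FALSE]
    if (nrow(ci))
      cd <- c(min(ci$start) - 1, max(ci$end))  # GTF 1-based closed -> 0-based half-open
    TranscriptModel(
      transcript_id = as.character(d$transcript_id[1]),
      gene_id = as.character(d$gene_id[1]),
      chrom = as.character(d$seqnames[1]),
      strand = as.character(d$strand[1]),
      exons = cbind(d$start - 1, d$end),
      cds = cd,
      fpkm = ifelse(is.na(fp), 0, fp),
      class_code = cc)
  })
  unname(models)
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_transcript_models()]: internal 0-based half-open
#' intervals become GTF 1-based closed intervals.
#'
#' @param models List of `TranscriptModel`s.
#' @param path Output GTF path.
#' @param fpkm_attr Attribute name used for the FPKM value.
#' @export
write_transcript_models <- function(models, path, fpkm_attr = "FPKM") {
  rows <- lapply(models, function(m) {
    ex <- data.frame(chrom = m$chrom, start = m$exons[, 1] + 1, end = m$exons[, 2],
                     type = "exon", strand = m$strand,
                     gene_id = m$gene_id, transcript_id = m$transcript_id,
                     fpkm = m$fpkm,
                     class_code = ifelse(is.na(m$class_code), ".", m$class_code),
                     stringsAsFactors = FALSE)
    if (!is.null(m$cds))
      ex <- rbind(ex, data.frame(chrom = m$chrom, start = m$cds[1] + 1,
                                 end = m$cds[2], type = "CDS", strand = m$strand,
                                 gene_id = m$gene_id, transcript_id = m$transcript_id,
                                 fpkm = m$fpkm,
                                 class_code = ifelse(is.na(m$class_code), ".", m$class_code),
                                 stringsAsFactors = FALSE))
    ex
  })
  df <- do.call(rbind, rows)
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; %s "%s"; class_code "%s";',
                      df$gene_id, df$transcript_id, fpkm_attr,
                      sprintf("%.12g", df$fpkm), df$class_code)
  lines <- sprintf("%s\tolfscreen\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   df$chrom, df$type, as.integer(df$start), as.integer(df$end),
                   df$strand, attr_str)
  writeLines(lines, path)
  invisible(path)
}
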