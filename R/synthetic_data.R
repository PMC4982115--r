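#' Simulation configuration for a synthetic olfactory expression study
#'
#' Parameters of the synthetic study emulated by
#' [simulate_expression_study()]: 4 olfactory-epithelium (OE) samples,
#' one respiratory sample and 16 single-sample control tissues for the
#' human arm; a smaller mouse arm sharing ortholog ids. Olfactory
#' receptor (OR) per-gene expression is log-normal with an exponential
#' right tail (the `skew_shape` knob) so that a minority of receptors
#' dominates the summed repertoire expression; pseudogene means sit
#' `log10(4)` below intact means by default.
#'
#' @param seed Master seed; every draw is reproducible under it.
#' @param n_genes Number of non-OR genes.
#' @param n_or_intact,n_or_pseudo OR repertoire sizes (defaults 391/466).
#' @param n_oe_samples,n_control_tissues Human design (defaults 4/16).
#' @param intact_logmean,pseudo_logmean,logsd Log10-FPKM location/scale of
#'   OR per-gene means.
#' @param skew_shape Scale of the exponential tail added to OR log-means;
#'   larger values give a more skewed rank curve.
#' @param nonor_logmean,nonor_logsd Log10-FPKM distribution of non-OR genes.
#' @param noise_sd Within-group log10 noise across samples.
#' @param n_planted_overexpressed Number of non-OR genes overexpressed in
#'   OE by `planted_fold`.
#' @param planted_fold True OE/control FPKM ratio of planted genes (> 1).
#' @param n_planted_contaminants Number of planted respiratory
#'   contaminants: respiratory-specific genes whose apparent OE
#'   expression is `respiratory_leak_fraction` of their respiratory
#'   level (tissue carry-over in the biopsy).
#' @param respiratory_leak_fraction Fraction of a contaminant's
#'   respiratory expression that appears in the OE samples (in `[0, 1]`).
#' @param contaminant_resp_logfold Log10 overexpression of contaminants
#'   in the respiratory sample relative to baseline (default 2).
#' @param nb_dispersion Negative-binomial dispersion of simulated counts.
#' @param library_sizes Per-sample expected counts per FPKM unit (scalar
#'   recycled over samples).
#' @param or_control_shift_intact,or_control_shift_pseudo Log10 shift of
#'   OR expression in non-olfactory tissues (ectopic repression).
#' @param seg_pseudo_fraction Fraction of OR loci flagged as segregating
#'   pseudogenes (independent of expression).
#' @param class1_fraction Fraction of ORs assigned to class I.
#' @param ortholog_fraction Fraction of human genes given a mouse ortholog.
#' @param mouse_overlap Fraction of human planted genes also planted in
#'   mouse (exercises the cross-species rescue rule).
#' @param mouse_logmean_shift Log10 shift of mouse OR expression (tissue
#'   purity: mouse OE is cleaner, expression reads higher).
#' @param mouse_logsd,mouse_skew_shape Mouse OR spread and tail scale
#'   (smaller than the human values: the mouse rank curve is flatter, so
#'   a larger fraction of receptors is needed to reach half the summed
#'   expression).
#' @param mouse_n_oe Mouse OE sample count.
#' @return List of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1,
                              n_genes = 2000,
                              n_or_intact = 391, n_or_pseudo = 466,
                              n_oe_samples = 4, n_control_tissues = 16,
                              intact_logmean = -1.5,
                              pseudo_logmean = -1.5 - log10(4),
                              logsd = 0.55, skew_shape = 0.2,
                              nonor_logmean = 0, nonor_logsd = 0.7,
                              noise_sd = 0.1,
                              n_planted_overexpressed = 50, planted_fold = 8,
                              n_planted_contaminants = 10,
                              respiratory_leak_fraction = 0.1,
                              contaminant_resp_logfold = 2,
                              nb_dispersion = 0.1, library_sizes = 30,
                              or_control_shift_intact = -0.85,
                              or_control_shift_pseudo = -0.2,
                              seg_pseudo_fraction = 0.33,
                              class1_fraction = 0.13,
                              ortholog_fraction = 0.8,
                              mouse_overlap = 0.7,
                              mouse_logmean_shift = 0.8,
                              mouse_logsd = 0.33, mouse_skew_shape = 0.08,
                              mouse_n_oe = 3) {
  if (n_planted_overexpressed + n_planted_contaminants > n_genes)
    stop("more planted genes than available non-OR genes")
  if (planted_fold <= 1) stop("planted_fold must exceed 1")
  if (respiratory_leak_fraction < 0 || respiratory_leak_fraction > 1)
    stop("respiratory_leak_fraction must be in [0, 1]")
  cfg <- as.list(environment())
  structure(cfg, class = "SimulationConfig")
}

MARKER_OLF <- c("OMP", "CNGA2", "GNAL", "RTP1")
MARKER_RESP <- c("KRT13", "TMPRSS11D")

CONTROL_TISSUES_HUMAN <- c("adipose", "adrenal", "blood", "brain", "breast",
                           "colon", "heart", "kidney", "liver", "lung",
                           "lymph", "ovary", "prostate", "skeletal_muscle",
                           "testis", "thyroid")
CONTROL_TISSUES_MOUSE <- c("adipose", "brain", "heart", "kidney", "liver",
                           "lung", "testis", "spleen", "thymus", "intestine",
                           "bone_marrow")

# one arm (human or mouse) of the study; returns floored FPKM + NB counts
simulate_arm <- function(gene_mu_base, oe_shift, resp_shift, ctrl_shift,
                         n_oe, ctrl_tissues, noise_sd, nb_dispersion,
                         library_sizes, prefix, with_respiratory = TRUE) {
  genes <- names(gene_mu_base)
  oe_ids <- paste0(prefix, "OE_", seq_len(n_oe))
  ctrl_ids <- paste0(prefix, "CTRL_", ctrl_tissues)
  samples <- c(oe_ids, if (with_respiratory) paste0(prefix, "RESP"), ctrl_ids)
  groups <- c(rep("OE", n_oe), if (with_respiratory) "respiratory",
              paste0("control:", ctrl_tissues))
  names(groups) <- samples
  mu <- matrix(gene_mu_base, nrow = length(genes), ncol = length(samples),
               dimnames = list(genes, samples))
  mu[, oe_ids] <- mu[, oe_ids] + oe_shift
  if (with_respiratory) mu[, paste0(prefix, "RESP")] <- mu[, paste0(prefix, "RESP")] + resp_shift
  mu[, ctrl_ids] <- mu[, ctrl_ids] + ctrl_shift
  fpkm <- 10^(mu + matrix(stats::rnorm(length(mu), 0, noise_sd), nrow = nrow(mu)))
  lib <- rep_len(library_sizes, length(samples))
  lambda <- sweep(fpkm, 2, lib, "*")
  counts <- matrix(stats::rnbinom(length(lambda), mu = lambda,
                                  size = 1 / max(nb_dispersion, 1e-8)),
                   nrow = nrow(lambda), dimnames = dimnames(lambda))
  m <- apply_fpkm_floor(ExpressionMatrix(fpkm, groups), 0.003)
  list(fpkm = m, counts = CountMatrix(counts, groups))
}

#' Simulate a complete olfactory expression study with planted truth
#'
#' Generates the human arm (FPKM + counts over OE, respiratory and
#' control samples), an independent mouse arm sharing ortholog ids, a
#' gene catalog, an ortholog map and the planted truth: which non-OR
#' genes are truly overexpressed in OE, which are respiratory
#' contaminants, and the true per-gene group means.
#'
#' Planted overexpressed genes have true OE/control FPKM ratio
#' `planted_fold`; contaminants are respiratory-specific genes whose OE
#' signal is biopsy carry-over (`respiratory_leak_fraction` of their
#' respiratory level), so their respiratory/OE ratio far exceeds any
#' sensible contamination cutoff. A
#' `mouse_overlap` fraction of the human planted set is planted in mouse
#' as well (through the ortholog map), the remainder only in human.
#'
#' @param cfg A [simulation_config()].
#' @return List with `human` (list `fpkm`, `counts`), `mouse` (idem),
#'   `catalog`, `mouse_catalog`, `ortholog_map`, `truth`, `config`.
#' @export
simulate_expression_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)

  ## ---- gene universe -----------------------------------------------------
  or_i <- sprintf("ORI%04d", seq_len(cfg$n_or_intact))
  or_p <- sprintf("ORP%04d", seq_len(cfg$n_or_pseudo))
  markers <- c(MARKER_OLF, MARKER_RESP)
  n_plain <- cfg$n_genes - length(markers)
  plain <- sprintf("GENE%05d", seq_len(n_plain))
  nonor <- c(markers, plain)

  ## ---- per-gene base log10 means ----------------------------------------
  mu_or_i <- cfg$intact_logmean + cfg$logsd * stats::rnorm(cfg$n_or_intact) +
    cfg$skew_shape * stats::rexp(cfg$n_or_intact)
  mu_or_p <- cfg$pseudo_logmean + cfg$logsd * stats::rnorm(cfg$n_or_pseudo) +
    cfg$skew_shape * stats::rexp(cfg$n_or_pseudo)
  mu_nonor <- cfg$nonor_logmean + cfg$nonor_logsd * stats::rnorm(length(nonor))
  names(mu_nonor) <- nonor
  mu_nonor[markers] <- 1   # all markers well expressed in their home tissue

  ## ---- planted sets ------------------------------------------------------
  eligible <- plain
  planted <- sample(eligible, cfg$n_planted_overexpressed)
  contam <- sample(setdiff(eligible, planted), cfg$n_planted_contaminants)
  # contaminants model abundant respiratory secretory genes
  mu_nonor[contam] <- stats::rnorm(length(contam), 0.5, 0.3)

  genes <- c(or_i, or_p, nonor)
  mu_base <- c(mu_or_i, mu_or_p, mu_nonor)
  names(mu_base) <- genes

  lf <- log10(cfg$planted_fold)
  oe_shift <- stats::setNames(rep(0, length(genes)), genes)
  resp_shift <- oe_shift
  ctrl_shift <- oe_shift
  oe_shift[planted] <- lf
  oe_shift[MARKER_OLF] <- lf                       # olfactory markers
  resp_shift[MARKER_RESP] <- lf                    # respiratory markers
  # genuinely OE-specific genes are near-silent in respiratory epithelium
  resp_shift[planted] <- -1
  resp_shift[MARKER_OLF] <- -1
  # contaminants: respiratory-specific, carried into OE by tissue leak
  oe_shift[contam] <- cfg$contaminant_resp_logfold +
    log10(cfg$respiratory_leak_fraction)
  resp_shift[contam] <- cfg$contaminant_resp_logfold
  ctrl_shift[or_i] <- cfg$or_control_shift_intact
  ctrl_shift[or_p] <- cfg$or_control_shift_pseudo

  human <- simulate_arm(mu_base, oe_shift, resp_shift, ctrl_shift,
                        cfg$n_oe_samples,
                        CONTROL_TISSUES_HUMAN[seq_len(cfg$n_control_tissues)],
                        cfg$noise_sd, cfg$nb_dispersion, cfg$library_sizes,
                        prefix = "")

  ## ---- catalog -----------------------------------------------------------
  n_or <- length(c(or_i, or_p))
  or_class <- sample(c("I", "II"), n_or, replace = TRUE,
                     prob = c(cfg$class1_fraction, 1 - cfg$class1_fraction))
  seg <- stats::runif(n_or) < cfg$seg_pseudo_fraction
  mu_or <- c(mu_or_i, mu_or_p)
  score <- stats::plogis((mu_or - mean(mu_or)) / stats::sd(mu_or) +
                           c(rep(1, cfg$n_or_intact), rep(-1, cfg$n_or_pseudo)) +
                           stats::rnorm(n_or, 0, 0.5))
  hits <- stats::rpois(length(nonor), 0.2)
  catalog <- GeneCatalog(data.frame(
    gene_id = genes, symbol = genes,
    or_status = c(rep("intact", cfg$n_or_intact),
                  rep("pseudogene", cfg$n_or_pseudo),
                  rep("non_OR", length(nonor))),
    or_class = c(or_class, rep(NA_character_, length(nonor))),
    segregating_pseudogene = c(seg, rep(FALSE, length(nonor))),
    ortholog_id = NA_character_,
    literature_hits = c(rep(NA_integer_, n_or), hits),
    functionality_score = c(score, rep(NA_real_, length(nonor))),
    stringsAsFactors = FALSE))

  ## ---- ortholog map and mouse arm ---------------------------------------
  has_orth <- stats::runif(length(genes)) < cfg$ortholog_fraction
  orth_human <- genes[has_orth]
  orth_mouse <- paste0("m", orth_human)
  ortholog_map <- OrthologMap(data.frame(human_gene_id = orth_human,
                                         mouse_gene_id = orth_mouse,
                                         stringsAsFactors = FALSE))
  catalog$ortholog_id[match(orth_human, catalog$gene_id)] <- orth_mouse

  m_or_i <- paste0("m", or_i)
  m_or_p <- paste0("m", or_p)
  m_genes <- paste0("m", genes)
  m_mu_or_i <- cfg$intact_logmean + cfg$mouse_logmean_shift +
    cfg$mouse_logsd * stats::rnorm(cfg$n_or_intact) +
    cfg$mouse_skew_shape * stats::rexp(cfg$n_or_intact)
  m_mu_or_p <- cfg$pseudo_logmean + cfg$mouse_logmean_shift - 0.4 +
    cfg$mouse_logsd * stats::rnorm(cfg$n_or_pseudo) +
    cfg$mouse_skew_shape * stats::rexp(cfg$n_or_pseudo)
  m_mu_nonor <- cfg$nonor_logmean + cfg$nonor_logsd * stats::rnorm(length(nonor))
  m_mu <- c(m_mu_or_i, m_mu_or_p, m_mu_nonor)
  names(m_mu) <- m_genes

  # mouse planted set: overlap fraction of the human planted genes that have
  # orthologs, plus the human-only remainder left unplanted in mouse
  planted_with_orth <- intersect(planted, orth_human)
  n_over <- round(cfg$mouse_overlap * length(planted_with_orth))
  mouse_planted <- paste0("m", sample(planted_with_orth, n_over))
  m_oe_shift <- stats::setNames(rep(0, length(m_genes)), m_genes)
  m_oe_shift[mouse_planted] <- lf
  m_oe_shift[paste0("m", MARKER_OLF)] <- lf
  m_ctrl_shift <- stats::setNames(rep(0, length(m_genes)), m_genes)
  m_ctrl_shift[m_or_i] <- cfg$or_control_shift_intact
  m_ctrl_shift[m_or_p] <- cfg$or_control_shift_pseudo
  m_resp_shift <- stats::setNames(rep(0, length(m_genes)), m_genes)

  mouse <- simulate_arm(m_mu, m_oe_shift, m_resp_shift, m_ctrl_shift,
                        cfg$mouse_n_oe, CONTROL_TISSUES_MOUSE,
                        cfg$noise_sd, cfg$nb_dispersion, cfg$library_sizes,
                        prefix = "m", with_respiratory = FALSE)

  mouse_catalog <- GeneCatalog(data.frame(
    gene_id = m_genes, symbol = m_genes,
    or_status = c(rep("intact", cfg$n_or_intact),
                  rep("pseudogene", cfg$n_or_pseudo),
                  rep("non_OR", length(nonor))),
    or_class = c(or_class, rep(NA_character_, length(nonor))),
    segregating_pseudogene = FALSE,
    ortholog_id = NA_character_,
    literature_hits = NA_integer_,
    functionality_score = NA_real_,
    stringsAsFactors = FALSE))

  truth <- list(
    planted_overexpressed_gene_ids = planted,
    planted_respiratory_contaminant_ids = contam,
    mouse_planted_gene_ids = mouse_planted,
    or_intact_ids = or_i, or_pseudo_ids = or_p,
    mouse_or_intact_ids = m_or_i, mouse_or_pseudo_ids = m_or_p,
    base_logmean = mu_base,
    oe_shift = oe_shift, resp_shift = resp_shift, ctrl_shift = ctrl_shift)

  list(human = human, mouse = mouse, catalog = catalog,
       mouse_catalog = mouse_catalog, ortholog_map = ortholog_map,
       truth = truth, config = cfg)
}

#' Simulate a two-sample study with a decorrelated target gene set
#'
#' Generator for the inter-individual resampling test: every gene's
#' log10-FPKM in the two samples is bivariate normal around a per-gene
#' mean drawn from a common distribution, with the between-sample
#' correlation chosen so that the expected observed Pearson r over a gene
#' set equals `r_or` for the target (OR) set and `r_pool` for the control
#' pool. Under `r_or = r_pool` the target set is exchangeable with
#' matched control sets (the null).
#'
#' @param n_or,n_pool Set sizes.
#' @param r_or,r_pool Target observed between-sample correlations.
#' @param logmean,tau Location and between-gene SD of per-gene log10 means.
#' @param sigma Within-gene between-sample SD.
#' @param seed Optional seed.
#' @return List with `m` (floored two-sample [ExpressionMatrix()]),
#'   `or_genes`, `pool_genes`, `samples`.
#' @export
simulate_interindividual_pair <- function(n_or = 264, n_pool = 2000,
                                          r_or = 0.35, r_pool = 0.9,
                                          logmean = -0.5, tau = 0.5,
                                          sigma = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  noise_corr <- function(r_total) {
    rho <- (r_total * (tau^2 + sigma^2) - tau^2) / sigma^2
    if (rho < -1 || rho > 1)
      stop("target correlation unreachable with this tau/sigma")
    rho
  }
  draw <- function(n, rho, ids) {
    mu <- stats::rnorm(n, logmean, tau)
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    x <- cbind(A = mu + sigma * z1, B = mu + sigma * z2)
    rownames(x) <- ids
    x
  }
  or_ids <- sprintf("OR%04d", seq_len(n_or))
  pool_ids <- sprintf("CTL%05d", seq_len(n_pool))
  x <- rbind(draw(n_or, noise_corr(r_or), or_ids),
             draw(n_pool, noise_corr(r_pool), pool_ids))
  m <- apply_fpkm_floor(ExpressionMatrix(10^x, c(A = "OE", B = "OE")), 0.003)
  list(m = m, or_genes = or_ids, pool_genes = pool_ids, samples = c("A", "B"))
}

reflect_interval <- function(iv, pivot) {
  cbind(pivot - iv[, 2], pivot - iv[, 1])
}

#' Simulate transcript models with planted aberrant isoforms
#'
#' Emulates the architecture of olfactory receptor transcripts: 0-3 short
#' 5' non-coding exons, a long last exon containing the entire ORF
#' (default 940 bp) plus a variable 3' UTR, and 1-5 isoforms per gene
#' sharing the coding exon. A fraction of genes additionally carries an
#' aberrant isoform whose exon chain starts downstream of the ORF start
#' (skipping the initiating codon); these are the planted truth for the
#' aberrant-transcript detector.
#'
#' @param n_genes Number of genes.
#' @param aberrant_fraction Fraction of genes given one aberrant isoform.
#' @param orf_length ORF length in bp (constant across genes).
#' @param seed Optional seed.
#' @return List with `models` (list of [TranscriptModel()]s) and `truth`
#'   (list: `aberrant_transcript_ids`, `cds_by_gene`).
#' @export
simulate_transcript_models <- function(n_genes = 100, aberrant_fraction = 0.1,
                                       orf_length = 940, seed = NULL) {
  if (aberrant_fraction < 0 || aberrant_fraction > 1)
    stop("aberrant_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  models <- list()
  aberrant_ids <- character(0)
  cds_by_gene <- list()
  offset <- 10000
  n_aberrant <- round(aberrant_fraction * n_genes)
  aberrant_genes <- if (n_aberrant > 0) sample(n_genes, n_aberrant) else integer(0)
  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("ORG%04d", g)
    strand <- sample(c("+", "-"), 1)
    n5 <- sample(0:3, 1)
    exon5_len <- if (n5) sample(50:200, n5, replace = TRUE) else integer(0)
    introns <- if (n5) sample(500:3000, n5, replace = TRUE) else integer(0)
    u5_last <- sample(20:120, 1)          # 5' UTR portion inside the coding exon
    utr3 <- round(stats::rlnorm(1, log(2000), 0.6))
    # plus-strand layout starting at 0, shifted to the gene locus later
    pos <- 0
    ex5 <- matrix(0, nrow = n5, ncol = 2)
    for (i in seq_len(n5)) {
      ex5[i, ] <- c(pos, pos + exon5_len[i])
      pos <- pos + exon5_len[i] + introns[i]
    }
    last_start <- pos
    cds <- c(last_start + u5_last, last_start + u5_last + orf_length)
    last_end <- cds[2] + utr3
    span <- last_end
    canonical <- rbind(ex5, c(last_start, last_end))

    n_iso <- sample(1:5, 1)
    iso_exons <- list(canonical)
    if (n_iso > 1) {
      for (k in seq_len(n_iso - 1)) {
        keep5 <- if (n5) sort(sample(seq_len(n5), sample(0:n5, 1))) else integer(0)
        iso_exons[[k + 1]] <- rbind(ex5[keep5, , drop = FALSE],
                                    c(last_start, last_end))
      }
      iso_exons <- unique(iso_exons)
    }
    aberrant_local <- NULL
    if (g %in% aberrant_genes) {
      skip <- sample(30:200, 1)           # first exon starts inside the ORF
      aberrant_local <- matrix(c(cds[1] + skip, last_end), ncol = 2)
    }

    shift_and_emit <- function(ex, tid, aberrant) {
      if (strand == "-") {
        ex <- reflect_interval(ex, span)
        ex <- ex[order(ex[, 1]), , drop = FALSE]
        cds_g <- rev(span - cds)
      } else cds_g <- cds
      ex <- ex + offset
      cds_g <- cds_g + offset
      list(model = TranscriptModel(tid, gene_id, "chrS", strand, ex,
                                   cds = cds_g,
                                   fpkm = stats::rlnorm(1, log(5), 1)),
           cds = cds_g, aberrant = aberrant)
    }
    for (k in seq_along(iso_exons)) {
      tid <- sprintf("%s.%d", gene_id, k)
      r <- shift_and_emit(iso_exons[[k]], tid, FALSE)
      models[[length(models) + 1]] <- r$model
      cds_by_gene[[gene_id]] <- r$cds
    }
    if (!is.null(aberrant_local)) {
      tid <- sprintf("%s.ab", gene_id)
      r <- shift_and_emit(aberrant_local, tid, TRUE)
      models[[length(models) + 1]] <- r$model
      aberrant_ids <- c(aberrant_ids, tid)
    }
    offset <- offset + span + sample(20000:50000, 1)
  }
  list(models = models,
       truth = list(aberrant_transcript_ids = aberrant_ids,
                    cds_by_gene = cds_by_gene))
}

#' Simulate promoter sequences with planted motif instances
#'
#' Background bases are i.i.d. with the stated GC content; each promoter
#' receives one motif instance (sampled from the PWM's per-position base
#' probabilities) whose 5'-most base lies a uniform-random offset inside
#' `offset_range` bp upstream of the TSS, which is the last base of each
#' sequence.
#'
#' @param n_promoters Number of sequences.
#' @param p A [pwm()].
#' @param offset_range Length-2 integer vector of allowed planted offsets
#'   (bp upstream of the TSS); use `c(k, k)` to plant at exactly `k`.
#' @param background_gc GC fraction of the background.
#' @param seq_length Promoter length in bp (TSS at its 3' end).
#' @param plant Set to `FALSE` for background-only sequences.
#' @param seed Optional seed.
#' @return List with `sequences` (named character vector) and `truth`
#'   (data frame `promoter`, `offset`).
#' @export
simulate_promoters <- function(n_promoters, p, offset_range = c(100, 300),
                               background_gc = 0.4, seq_length = 4000,
                               plant = TRUE, seed = NULL) {
  stopifnot(inherits(p, "PWM"))
  if (p$length > seq_length) stop("motif longer than promoter sequence")
  if (plant && (max(offset_range) > seq_length - 1 || min(offset_range) < p$length - 1))
    stop("offset_range outside the sequence")
  if (!is.null(seed)) set.seed(seed)
  probs <- c((1 - background_gc) / 2, background_gc / 2,
             background_gc / 2, (1 - background_gc) / 2)
  seqs <- character(n_promoters)
  offs <- rep(NA_integer_, n_promoters)
  for (i in seq_len(n_promoters)) {
    s <- sample(BASES, seq_length, replace = TRUE, prob = probs)
    if (plant) {
      d <- if (offset_range[1] == offset_range[2]) offset_range[1]
           else sample(offset_range[1]:offset_range[2], 1)
      inst <- vapply(seq_len(p$length),
                     function(j) sample(BASES, 1, prob = p$matrix[, j]), "")
      start <- seq_length - d
      s[start:(start + p$length - 1)] <- inst
      offs[i] <- d
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- sprintf("prom%04d", seq_len(n_promoters))
  list(sequences = seqs,
       truth = data.frame(promoter = names(seqs), offset = offs,
                          stringsAsFactors = FALSE))
}
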