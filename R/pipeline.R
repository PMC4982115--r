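#' Pipeline configuration
#'
#' Bundles every stage's configuration and the master seed. All
#' thresholds of the analysis appear here as named defaults: fold 6,
#' p 0.001, respiratory ratio 0.1, expressed-call FPKM 0.01, floor 0.003,
#' transcript FPKM 1.0, isoform fraction 0.0015, promoter window
#' -750/+250, dedup overlap 500, profile 4000 bp, 10,000 resampling
#' iterations.
#'
#' @param seed Master seed; per-stage substreams are derived from it.
#' @param sim A [simulation_config()] for the `simulate` stage.
#' @param screen A [screen_config()].
#' @param resampling A [resampling_config()].
#' @param curation A [curation_config()].
#' @param expressed_cutoff FPKM cutoff for expressed calls.
#' @param fpkm_floor Expression floor.
#' @param promoter_window,promoter_dedup_overlap,profile_window_bp,profile_bin_bp
#'   Promoter-stage parameters.
#' @param n_promoter_genes Number of transcript-model genes simulated for
#'   the structure/promoter stages.
#' @param resampling_n_or Size of the target set in the inter-individual
#'   stage.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1,
                            sim = simulation_config(seed = seed),
                            screen = screen_config(),
                            resampling = resampling_config(n_iterations = 1000),
                            curation = curation_config(),
                            expressed_cutoff = 0.01,
                            fpkm_floor = 0.003,
                            promoter_window = c(-750, 250),
                            promoter_dedup_overlap = 500,
                            profile_window_bp = 4000,
                            profile_bin_bp = 100,
                            n_promoter_genes = 100,
                            resampling_n_or = 264) {
  structure(as.list(environment()), class = "PipelineConfig")
}

write_stage_tsv <- function(df, out_dir, name, seed) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  con <- file(path, "w")
  writeLines(sprintf("# olfscreen seed=%d", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over simulated (or, stage by stage, supplied)
#' data: `simulate`, `qc`, `screen`, `repertoire`, `interindividual`,
#' `structure`, `promoter`. Each stage writes TSV outputs into `out_dir`
#' and the run ends with a JSON manifest (config hash, seed, package
#' version, per-stage files) from which the run is reconstructible.
#' Reruns with the same configuration produce identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Ordered subset of the stage names above.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("simulate", "qc", "screen", "repertoire"),
                         out_dir = tempfile("olfscreen_run_")) {
  known <- c("simulate", "qc", "screen", "repertoire", "interindividual",
             "structure", "promoter")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  files <- list()
  need <- function(what, stage) {
    if (!exists(what, envir = state))
      stop(sprintf("stage '%s' requires '%s'; run the 'simulate' stage first",
                   stage, what))
    get(what, envir = state)
  }
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    out <- switch(stage,
      simulate = {
        study <- simulate_expression_study(cfg$sim)
        assign("study", study, envir = state)
        f1 <- file.path(out_dir, "human_fpkm.tsv")
        write_expression_table(study$human$fpkm, f1)
        f2 <- file.path(out_dir, "human_counts.tsv")
        write_count_table(study$human$counts, f2)
        f3 <- file.path(out_dir, "catalog.tsv")
        write_gene_catalog(study$catalog, f3)
        c(f1, f2, f3)
      },
      qc = {
        study <- need("study", "qc")
        r <- tissue_correlation_matrix(study$human$fpkm)
        df <- data.frame(sample = rownames(r), r, check.names = FALSE)
        write_stage_tsv(df, out_dir, "qc_correlation", cfg$seed)
      },
      screen = {
        study <- need("study", "screen")
        mouse_recs <- run_screen(study$mouse$fpkm, study$mouse$counts,
                                 study$mouse_catalog, cfg = cfg$screen)
        mouse_sig <- data.frame(
          gene_id = mouse_recs$gene_id,
          significant = mouse_recs$status %in% c("retained", "rescued_by_mouse"))
        recs <- run_screen(study$human$fpkm, study$human$counts, study$catalog,
                           study$ortholog_map, mouse_sig, cfg$screen)
        recs <- classify_evidence_class(recs, study$catalog)
        assign("screen_records", recs, envir = state)
        write_stage_tsv(recs, out_dir, "screen", cfg$seed)
      },
      repertoire = {
        study <- need("study", "repertoire")
        oe <- samples_in_group(study$human$fpkm$sample_groups, "OE")
        ors <- study$catalog$gene_id[study$catalog$or_status != "non_OR"]
        st <- status_distribution_test(study$human$fpkm, study$catalog, oe)
        rc <- rank_and_cumulative(study$human$fpkm, ors, oe)
        ef_i <- expressed_fraction(study$human$fpkm, study$truth$or_intact_ids,
                                   cfg$expressed_cutoff, oe)
        ef_p <- expressed_fraction(study$human$fpkm, study$truth$or_pseudo_ids,
                                   cfg$expressed_cutoff, oe)
        summ <- data.frame(
          metric = c("expressed_fraction_intact", "expressed_fraction_pseudo",
                     "mean_fpkm_intact", "mean_fpkm_pseudo",
                     "ks_p_intact_vs_pseudo", "half_fraction"),
          value = c(ef_i, ef_p, st$summary$mean, st$p_value, rc$half_fraction))
        assign("repertoire_summary", summ, envir = state)
        f1 <- write_stage_tsv(summ, out_dir, "repertoire_summary", cfg$seed)
        f2 <- write_stage_tsv(rc$rank_curve, out_dir, "rank_curve", cfg$seed)
        f3 <- write_stage_tsv(rc$cumulative_curve, out_dir, "cumulative_curve",
                              cfg$seed)
        c(f1, f2, f3)
      },
      interindividual = {
        study <- need("study", "interindividual")
        m <- study$human$fpkm
        oe <- samples_in_group(m$sample_groups, "OE")
        ors <- intersect(study$catalog$gene_id[study$catalog$or_status != "non_OR"],
                         rownames(m$values))
        expressed_both <- function(g, a, b)
          g[m$values[g, a] >= cfg$expressed_cutoff &
            m$values[g, b] >= cfg$expressed_cutoff]
        a <- oe[1]; b <- oe[2]
        or_use <- expressed_both(ors, a, b)
        if (length(or_use) > cfg$resampling_n_or)
          or_use <- or_use[order(-rowMeans(m$values[or_use, c(a, b)]))][
            seq_len(cfg$resampling_n_or)]
        res <- resampling_test(m, or_use, NULL, a, b, cfg$resampling)
        df <- data.frame(sample_a = a, sample_b = b,
                         observed_r = res$observed_r,
                         null_mean_r = mean(res$null_rs),
                         empirical_p = res$empirical_p, p_label = res$p_label,
                         n_matched_genes = res$n_matched_genes)
        assign("interindividual", res, envir = state)
        f1 <- write_stage_tsv(df, out_dir, "interindividual", cfg$seed)
        f2 <- write_stage_tsv(data.frame(null_r = res$null_rs), out_dir,
                              "interindividual_null", cfg$seed)
        c(f1, f2)
      },
      structure = {
        sim <- simulate_transcript_models(cfg$n_promoter_genes,
                                          seed = cfg$seed + 1L)
        assign("transcripts", sim, envir = state)
        cur <- curate_transcripts(sim$models, cfg$curation)
        tab <- structure_table(cur$kept)
        ab <- detect_aberrant(sim$models, sim$truth$cds_by_gene)
        assign("aberrant", ab, envir = state)
        f1 <- write_stage_tsv(tab, out_dir, "structure_records", cfg$seed)
        f2 <- write_stage_tsv(cur$removed, out_dir, "curation_audit", cfg$seed)
        f3 <- write_stage_tsv(ab$transcripts, out_dir, "aberrant_calls", cfg$seed)
        c(f1, f2, f3)
      },
      promoter = {
        p <- ebf_like_pwm()
        sim <- simulate_promoters(cfg$n_promoter_genes, p,
                                  seq_length = cfg$profile_window_bp,
                                  seed = cfg$seed + 2L)
        offs <- unlist(lapply(sim$sequences, function(s) {
          h <- scan_pwm(s, p)
          hits_to_offsets(h, nchar(s))$offset
        }))
        prof <- positional_profile(offs, cfg$profile_window_bp, cfg$profile_bin_bp)
        assign("promoter_profile", prof, envir = state)
        write_stage_tsv(prof, out_dir, "promoter_profile", cfg$seed)
      })
    files[[stage]] <- list(files = as.character(out),
                           seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(seed = cfg$seed, stages = stages,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package_version = as.character(utils::packageVersion("olfscreen")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   outputs = files)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(list(state = as.list(state), manifest = manifest, out_dir = out_dir))
}

#' A small EBF/Olf-like position weight matrix
#'
#' Built-in 10-bp palindromic-core motif resembling the binding
#' preference of early B-cell factor (EBF/Olf) transcription factors,
#' used as the default motif of the promoter stage and in examples.
#' @return A [pwm()].
#' @export
ebf_like_pwm <- function() {
  # consensus TCCCNNGGGA with degenerate center
  counts <- matrix(c(
    # T    C    C    C    N    N    G    G    G    A
     5,   2,   1,   2,  25,  25,   2,   1,   2,  70,
    10,  85,  90,  80,  25,  25,   6,   4,   5,  10,
     5,   3,   4,   8,  25,  25,  86,  90,  88,  10,
    80,  10,   5,  10,  25,  25,   6,   5,   5,  10), nrow = 4, byrow = TRUE)
  rownames(counts) <- c("T", "C", "G", "A")
  pwm(counts[c("A", "C", "G", "T"), ] / 100)
}
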