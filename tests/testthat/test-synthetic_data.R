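test_that("the study generator is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 5, n_genes = 300, n_or_intact = 50,
                           n_or_pseudo = 60, n_planted_overexpressed = 10,
                           n_planted_contaminants = 3)
  a <- simulate_expression_study(cfg)
  b <- simulate_expression_study(cfg)
  expect_identical(a$human$fpkm$values, b$human$fpkm$values)
  expect_identical(a$human$counts$counts, b$human$counts$counts)
  expect_identical(a$mouse$fpkm$values, b$mouse$fpkm$values)
  expect_identical(a$truth$planted_overexpressed_gene_ids,
                   b$truth$planted_overexpressed_gene_ids)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_genes = 10, n_planted_overexpressed = 20),
               "planted")
  expect_error(simulation_config(planted_fold = 1), "planted_fold")
  expect_error(simulation_config(respiratory_leak_fraction = 2), "leak")
})

test_that("planted genes realize the configured OE/control fold", {
  cfg <- simulation_config(seed = 21, n_genes = 5000, planted_fold = 8,
                           n_planted_contaminants = 0)
  st <- simulate_expression_study(cfg)
  m <- st$human$fpkm
  oe <- samples_in_group(m$sample_groups, "OE")
  ctrl <- control_samples(m$sample_groups)
  folds <- vapply(st$truth$planted_overexpressed_gene_ids,
                  function(g) fpkm_fold_change(m, g, oe, ctrl), 1)
  expect_equal(mean(folds), 8, tolerance = 0.1)
})

test_that("the intact/pseudogene log-mean gap realizes a 4-fold mean ratio", {
  cfg <- simulation_config(seed = 9, n_genes = 200, n_or_intact = 4000,
                           n_or_pseudo = 4000,
                           intact_logmean = -1.5,
                           pseudo_logmean = -1.5 - log10(4))
  st <- simulate_expression_study(cfg)
  oe <- samples_in_group(st$human$fpkm$sample_groups, "OE")
  mi <- mean(rowMeans(st$human$fpkm$values[st$truth$or_intact_ids, oe]))
  mp <- mean(rowMeans(st$human$fpkm$values[st$truth$or_pseudo_ids, oe]))
  expect_equal(mi / mp, 4, tolerance = 0.2)
})

test_that("generator expressed fractions match the closed-form expectation", {
  # with no tail (skew 0): P(expressed) = E_Z[1 - Phi((c - mu)/sd_noise)^k],
  # mu ~ N(logmean, logsd), evaluated by numeric integration
  oracle <- function(logmean, logsd, noise_sd, cutoff, k) {
    f <- function(z) {
      mu <- logmean + logsd * z
      (1 - stats::pnorm((log10(cutoff) - mu) / noise_sd)^k) * stats::dnorm(z)
    }
    stats::integrate(f, -8, 8)$value
  }
  cfg <- simulation_config(seed = 13, n_genes = 200,
                           n_or_intact = 2000, n_or_pseudo = 2000,
                           intact_logmean = -1.3,
                           pseudo_logmean = -1.3 - log10(4),
                           logsd = 0.55, skew_shape = 0, noise_sd = 0.1)
  st <- simulate_expression_study(cfg)
  oe <- samples_in_group(st$human$fpkm$sample_groups, "OE")
  for (status in c("intact", "pseudo")) {
    ids <- if (status == "intact") st$truth$or_intact_ids else st$truth$or_pseudo_ids
    lm <- if (status == "intact") -1.3 else -1.3 - log10(4)
    expected <- oracle(lm, 0.55, 0.1, 0.01, length(oe))
    got <- expressed_fraction(st$human$fpkm, ids, 0.01, oe)
    tol <- 3 * sqrt(expected * (1 - expected) / length(ids))
    expect_lt(abs(got - expected), tol + 0.01)
  }
})

test_that("transcript generator honors the aberrant fraction and ORF length", {
  sim0 <- simulate_transcript_models(30, aberrant_fraction = 0, seed = 3)
  ab0 <- detect_aberrant(sim0$models, sim0$truth$cds_by_gene)
  expect_true(all(ab0$transcripts$functional))
  expect_length(sim0$truth$aberrant_transcript_ids, 0)

  sim <- simulate_transcript_models(30, aberrant_fraction = 0.3,
                                    orf_length = 940, seed = 4)
  tab <- structure_table(sim$models)
  functional <- !(tab$transcript_id %in% sim$truth$aberrant_transcript_ids)
  expect_true(all(tab$cds_length[functional] == 940))
  # planted aberrant chains start strictly inside the ORF
  for (tid in sim$truth$aberrant_transcript_ids) {
    m <- sim$models[[which(vapply(sim$models, `[[`, "", "transcript_id") == tid)]]
    cds <- sim$truth$cds_by_gene[[m$gene_id]]
    start <- if (m$strand == "+") cds[1] else cds[2] - 1
    covered <- any(m$exons[, 1] <= start & start < m$exons[, 2])
    expect_false(covered)
  }
})

test_that("promoter generator plants instances at the requested offsets", {
  # degenerate PWM: planted instances are always the consensus
  pm <- pwm(matrix(rep(c(1, 0, 0, 0), 6), nrow = 4))
  sim <- simulate_promoters(15, pm, offset_range = c(150, 150),
                            seq_length = 400, seed = 8)
  expect_true(all(sim$truth$offset == 150))
  for (s in sim$sequences) {
    hits <- hits_to_offsets(scan_pwm(s, pm, threshold = pwm_max_score(pm)),
                            tss_pos = nchar(s))
    expect_true(150 %in% hits$offset)
  }
  again <- simulate_promoters(15, pm, offset_range = c(150, 150),
                              seq_length = 400, seed = 8)
  expect_identical(sim$sequences, again$sequences)
  expect_error(simulate_promoters(5, pm, seq_length = 4), "longer")
})

test_that("background-only promoters hit at the analytic false-positive rate", {
  # all-or-nothing motif AAAC at maximal threshold: a window hits iff it
  # equals the consensus (either strand), so the expected count is
  # 2 * P(window) * n_windows under the i.i.d. background
  pm <- pwm(matrix(c(1, 0, 0, 0,  1, 0, 0, 0,  1, 0, 0, 0,  0, 1, 0, 0),
                   nrow = 4))
  gc <- 0.4
  len <- 500
  nseq <- 400
  sim <- simulate_promoters(nseq, pm, plant = FALSE, background_gc = gc,
                            seq_length = len, seed = 12)
  nhits <- sum(vapply(sim$sequences, function(s)
    nrow(scan_pwm(s, pm, threshold = pwm_max_score(pm))), 1))
  p_win <- (0.3^3 * 0.2)                 # P(AAAC) = P(revcomp match) here
  lambda <- 2 * p_win * (len - 3) * nseq
  expect_lt(abs(nhits - lambda), 4 * sqrt(lambda) + 1)
})
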