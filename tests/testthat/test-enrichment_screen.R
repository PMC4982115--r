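count_matrix <- function(counts, groups) {
  CountMatrix(counts, groups)
}

test_that("median-of-ratios size factors satisfy the defining identities", {
  k <- matrix(c(5, 10, 20, 5, 10, 20), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(estimate_size_factors(count_matrix(k, c(a = "OE", b = "OE")))),
               c(1, 1))

  k2 <- k; k2[, "b"] <- 2 * k2[, "a"]
  s <- estimate_size_factors(count_matrix(k2, c(a = "OE", b = "OE")))
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)))

  k1 <- k[, "a", drop = FALSE]
  expect_equal(unname(estimate_size_factors(count_matrix(k1, c(a = "OE")))), 1)

  set.seed(3)
  kr <- matrix(rpois(500, 20), nrow = 100,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:5)))
  sr <- estimate_size_factors(count_matrix(kr, setNames(rep("OE", 5), paste0("s", 1:5))))
  expect_equal(exp(mean(log(sr))), 1)

  k0 <- matrix(c(1, 0, 0, 1), nrow = 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(estimate_size_factors(count_matrix(k0, c(a = "OE", b = "OE"))),
               "nonzero")
})

test_that("method-of-moments dispersion recovers truth and vanishes for Poisson", {
  set.seed(7)
  grp <- setNames(rep("X", 200), paste0("s", 1:200))
  one <- setNames(rep(1, 200), paste0("s", 1:200))

  kp <- matrix(rpois(400 * 200, 25), nrow = 400,
               dimnames = list(paste0("g", 1:400), names(grp)))
  dp <- estimate_dispersions(count_matrix(kp, grp), one, grp)
  expect_lt(mean(dp$alpha), 0.02)

  kn <- matrix(rnbinom(400 * 200, mu = 25, size = 10), nrow = 400,
               dimnames = list(paste0("g", 1:400), names(grp)))
  dn <- estimate_dispersions(count_matrix(kn, grp), one, grp)
  expect_lt(abs(mean(dn$alpha) - 0.1), 0.03)

  kc <- matrix(7, nrow = 2, ncol = 200,
               dimnames = list(c("g1", "g2"), names(grp)))
  dc <- estimate_dispersions(count_matrix(kc, grp), one, grp)
  expect_equal(unname(dc$alpha), c(0, 0))

  k0 <- kc; k0[1, ] <- 0
  d0 <- estimate_dispersions(count_matrix(k0, grp), one, grp)
  expect_equal(unname(d0$alpha[1]), 0)
})

test_that("the NB exact test reduces to the binomial oracle at zero dispersion", {
  for (srat in list(c(A = 1, B = 1), c(A = 1, B = 3))) {
    pr <- srat[["A"]] / sum(srat)
    for (ks in 0:20) {
      for (ka in 0:ks) {
        k <- matrix(c(ka, ks - ka), nrow = 1,
                    dimnames = list("g", c("A", "B")))
        cm <- count_matrix(k, c(A = "OE", B = "control"))
        p_pkg <- nb_two_group_test(cm, srat, c(g = 0), "A", "B", "g")
        expect_equal(p_pkg, binom_exact_oracle(ka, ks - ka, pr),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("the observed split at the mode gives p = 1", {
  k <- matrix(c(30, 30), nrow = 1, dimnames = list("g", c("A", "B")))
  cm <- count_matrix(k, c(A = "OE", B = "control"))
  expect_equal(nb_two_group_test(cm, c(A = 1, B = 1), c(g = 0.1), "A", "B", "g"), 1)
  expect_error(nb_two_group_test(cm, c(A = 1, B = 1), c(g = 0.1), "A", "A", "g"),
               "disjoint")
})

test_that("FPKM fold change follows its arithmetic definition", {
  m <- make_expr(list(g1 = c(a = 0.6, b = 0.6, x = 0.1, y = 0.1),
                      g2 = c(a = 0.003, b = 0.003, x = 0.003, y = 0.003)),
                 c(a = "OE", b = "OE", x = "control:liver", y = "control:lung"))
  expect_equal(fpkm_fold_change(m, "g1", c("a", "b"), c("x", "y")), 6)
  expect_equal(fpkm_fold_change(m, "g2", c("a", "b"), c("x", "y")), 1)
  expect_error(fpkm_fold_change(m, "g1", character(0), c("x", "y")), "empty")
})

make_screen_fixture <- function() {
  # 4 OE, 1 respiratory, 2 controls; counts chosen so the NB test is
  # decisive where intended
  groups <- c(OE1 = "OE", OE2 = "OE", OE3 = "OE", OE4 = "OE",
              RESP = "respiratory", C1 = "control:liver", C2 = "control:lung")
  fpkm <- rbind(
    g_ret    = c(10, 10, 10, 10, 0.05, 1, 1),     # clean overexpression
    g_resp   = c(1, 1, 1, 1, 0.15, 0.1, 0.1),     # contaminated (ratio 0.15)
    g_rescue = c(7, 7, 7, 7, 0.05, 1, 1),         # fold 7, counts flat
    g_failp  = c(7, 7, 7, 7, 0.05, 1, 1),         # same but no mouse rescue
    g_flat   = c(1, 1, 1, 1, 1, 1, 1))
  colnames(fpkm) <- names(groups)
  counts <- rbind(
    g_ret    = c(500, 500, 500, 500, 10, 50, 50),
    g_resp   = c(300, 300, 300, 300, 45, 30, 30),
    g_rescue = c(100, 100, 100, 100, 100, 100, 100),
    g_failp  = c(100, 100, 100, 100, 100, 100, 100),
    g_flat   = c(80, 80, 80, 80, 80, 80, 80))
  colnames(counts) <- names(groups)
  m <- apply_fpkm_floor(ExpressionMatrix(fpkm, groups), 0.003)
  cm <- CountMatrix(counts, groups)
  catalog <- make_catalog(rownames(fpkm),
                          ortholog = paste0("m", rownames(fpkm)),
                          hits = c(3L, 0L, 0L, 0L, 0L))
  om <- OrthologMap(data.frame(human_gene_id = rownames(fpkm),
                               mouse_gene_id = paste0("m", rownames(fpkm))))
  mouse <- data.frame(gene_id = "mg_rescue", significant = TRUE)
  list(m = m, cm = cm, catalog = catalog, om = om, mouse = mouse)
}

test_that("the screen applies fold, p, rescue and respiratory rules in order", {
  fx <- make_screen_fixture()
  recs <- run_screen(fx$m, fx$cm, fx$catalog, fx$om, fx$mouse, screen_config())
  status <- setNames(recs$status, recs$gene_id)
  expect_equal(unname(status["g_ret"]), "retained")
  expect_equal(unname(status["g_resp"]), "respiratory_filtered")
  expect_equal(unname(status["g_rescue"]), "rescued_by_mouse")
  expect_equal(unname(status["g_failp"]), "failed_p")
  expect_equal(unname(status["g_flat"]), "failed_fold")
  expect_equal(unname(recs$respiratory_ratio[recs$gene_id == "g_resp"]), 0.15)
})

test_that("the screen is monotone in its thresholds", {
  fx <- make_screen_fixture()
  retained_at <- function(cfg) {
    r <- run_screen(fx$m, fx$cm, fx$catalog, fx$om, fx$mouse, cfg)
    r$gene_id[r$status %in% c("retained", "rescued_by_mouse")]
  }
  base <- retained_at(screen_config())
  stricter_fold <- retained_at(screen_config(fold_cutoff = 9,
                                             rescue_human_fold_min = 9))
  stricter_p <- retained_at(screen_config(p_cutoff = 1e-8))
  expect_true(all(stricter_fold %in% base))
  expect_true(all(stricter_p %in% base))
})

test_that("a missing respiratory sample disables the filter with a warning", {
  fx <- make_screen_fixture()
  keep <- names(fx$m$sample_groups) != "RESP"
  m2 <- ExpressionMatrix(fx$m$values[, keep], fx$m$sample_groups[keep],
                         floor = fx$m$floor)
  cm2 <- CountMatrix(fx$cm$counts[, keep], fx$cm$sample_groups[keep])
  expect_warning(recs <- run_screen(m2, cm2, fx$catalog, fx$om, fx$mouse),
                 "respiratory")
  expect_equal(recs$status[recs$gene_id == "g_resp"], "retained")
  expect_true(all(is.na(recs$respiratory_ratio)))
})

test_that("evidence classes follow the literature-hit threshold exactly", {
  set.seed(99)
  genes <- sprintf("g%03d", 1:194)
  hits <- rep(0L, 194)
  class_a <- sample(194, 36)
  hits[class_a] <- sample(1:20, 36, replace = TRUE)
  records <- data.frame(gene_id = genes, fold_change = 10, p_value = 1e-6,
                        respiratory_ratio = 0.01, status = "retained",
                        evidence_class = NA_character_)
  catalog <- make_catalog(genes, hits = hits)
  out <- classify_evidence_class(records, catalog, hit_threshold = 1)
  expect_identical(which(out$evidence_class == "A"), sort(class_a))
  expect_equal(sum(out$evidence_class == "B"), 194 - 36)

  catalog$literature_hits[1] <- NA
  out2 <- classify_evidence_class(records, catalog)
  expect_true(is.na(out2$evidence_class[1]))
})

test_that("shared-tissue fold change is consistent and species-resolved", {
  st <- simulate_expression_study(simulation_config(seed = 31, n_genes = 800,
                                                    n_or_intact = 30,
                                                    n_or_pseudo = 30))
  shared <- c("adipose", "brain", "heart", "kidney", "liver", "lung", "testis")
  # human-only planted gene with an ortholog, unplanted in mouse
  hp <- setdiff(intersect(st$truth$planted_overexpressed_gene_ids,
                          st$ortholog_map$human_gene_id),
                sub("^m", "", st$truth$mouse_planted_gene_ids))
  g <- hp[1]
  fc <- shared_tissue_fold_change(st$human$fpkm, st$mouse$fpkm, shared, g,
                                  st$ortholog_map)
  expect_gt(fc[["human"]], 6)
  expect_lt(fc[["mouse"]], 2.5)

  # restricting the controls to the complete control set reproduces the
  # plain fold change
  all_h <- sub("^control:", "",
               grep("^control:", st$human$fpkm$sample_groups, value = TRUE))
  oe <- samples_in_group(st$human$fpkm$sample_groups, "OE")
  ctrl <- control_samples(st$human$fpkm$sample_groups)
  fc2 <- shared_tissue_fold_change(st$human$fpkm, st$mouse$fpkm, all_h, g,
                                   st$ortholog_map)
  expect_equal(fc2[["human"]], fpkm_fold_change(st$human$fpkm, g, oe, ctrl))
  expect_error(shared_tissue_fold_change(st$human$fpkm, st$mouse$fpkm,
                                         "no_such_tissue", g, st$ortholog_map),
               "shared")
})
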