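test_that("expressed fraction counts genes above cutoff in any listed sample", {
  m <- make_expr(list(g1 = c(a = 1, b = 0.003), g2 = c(a = 0.02, b = 0.003),
                      g3 = c(a = 0.003, b = 0.05), g4 = c(a = 0.003, b = 0.003)),
                 c(a = "OE", b = "OE"))
  expect_equal(expressed_fraction(m, paste0("g", 1:4), 0.01), 0.75)
  floor_only <- make_expr(list(g1 = c(a = 0.003), g2 = c(a = 0.003)),
                          c(a = "OE"))
  expect_equal(expressed_fraction(floor_only, c("g1", "g2"), 0.01), 0)
  expect_error(expressed_fraction(m, character(0)), "empty")
})

test_that("expressed fraction is monotone non-increasing in the cutoff", {
  set.seed(8)
  vals <- matrix(10^rnorm(200), ncol = 2,
                 dimnames = list(paste0("g", 1:100), c("a", "b")))
  m <- apply_fpkm_floor(ExpressionMatrix(vals, c(a = "OE", b = "OE")), 0.003)
  cuts <- sort(10^runif(20, -2, 1))
  fr <- vapply(cuts, function(cc) expressed_fraction(m, rownames(vals), cc), 1)
  expect_true(all(diff(fr) <= 0))
})

test_that("the KS statistic equals the brute-force ECDF oracle", {
  set.seed(15)
  for (i in 1:50) {
    nx <- sample(5:50, 1); ny <- sample(5:50, 1)
    x <- 10^rnorm(nx); y <- 10^rnorm(ny, sample(c(0, 1), 1))
    ks <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(unname(ks$statistic), ks_stat_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("intact-vs-pseudogene distribution test behaves at both extremes", {
  vals <- 10^seq(-2, 1, length.out = 20)
  rows <- c(setNames(lapply(vals, function(v) c(a = v)), paste0("i", 1:20)),
            setNames(lapply(vals, function(v) c(a = v)), paste0("p", 1:20)))
  m <- make_expr(rows, c(a = "OE"))
  catalog <- make_catalog(names(rows),
                          or_status = rep(c("intact", "pseudogene"), each = 20))
  res <- status_distribution_test(m, catalog)
  expect_equal(res$ks_statistic, 0, tolerance = 1e-12)
  expect_gt(res$p_value, 0.99)

  st <- simulate_expression_study(simulation_config(seed = 12, n_genes = 100,
                                                    n_or_intact = 400,
                                                    n_or_pseudo = 400))
  oe <- samples_in_group(st$human$fpkm$sample_groups, "OE")
  res2 <- status_distribution_test(st$human$fpkm, st$catalog, oe)
  expect_lt(res2$p_value, 1e-6)
  expect_gt(res2$summary$mean[1], res2$summary$mean[2])
  expect_error(status_distribution_test(m, make_catalog(names(rows))), "status")
})

test_that("rank and cumulative curves give the documented half-fractions", {
  uni <- make_expr(setNames(lapply(1:10, function(i) c(a = 2)),
                            paste0("g", 1:10)), c(a = "OE"))
  expect_equal(rank_and_cumulative(uni, paste0("g", 1:10))$half_fraction, 0.5)

  v <- make_expr(list(g1 = c(a = 8), g2 = c(a = 4), g3 = c(a = 2),
                      g4 = c(a = 1)), c(a = "OE"))
  expect_equal(rank_and_cumulative(v, paste0("g", 1:4))$half_fraction, 0.25)

  w <- make_expr(c(setNames(lapply(1:4, function(i) c(a = 1)), paste0("g", 1:4)),
                   setNames(lapply(1:4, function(i) c(a = 0)), paste0("h", 1:4))),
                 c(a = "OE"), floor = NA)
  expect_equal(rank_and_cumulative(w, c(paste0("g", 1:4), paste0("h", 1:4)))$half_fraction,
               0.25, tolerance = 1e-6)
})

test_that("half-fraction and the cumulative curve match the scan oracle", {
  set.seed(22)
  for (i in 1:30) {
    n <- sample(5:1000, 1)
    x <- 10^rnorm(n, 0, runif(1, 0.2, 1.5))
    rows <- setNames(lapply(x, function(v) c(a = v)), sprintf("g%06d", 1:n))
    m <- make_expr(rows, c(a = "OE"), floor = NA)
    rc <- rank_and_cumulative(m, names(rows))
    expect_equal(rc$half_fraction, half_fraction_oracle(x))
    cc <- rc$cumulative_curve$cumulative_fraction
    expect_true(all(diff(cc) >= -1e-12))
    expect_equal(cc[length(cc)], 1, tolerance = 1e-12)
  }
})

test_that("class comparison reproduces the 2x2 chi-square by hand", {
  # expressed counts I: 30/40, II: 10/40 -> chi-square 20 by the 2x2 formula
  rows <- c(setNames(lapply(1:40, function(i) c(a = if (i <= 30) 1 else 0.003)),
                     paste0("c1_", 1:40)),
            setNames(lapply(1:40, function(i) c(a = if (i <= 10) 1 else 0.003)),
                     paste0("c2_", 1:40)))
  m <- make_expr(rows, c(a = "OE"))
  catalog <- make_catalog(names(rows), or_status = "intact",
                          or_class = rep(c("I", "II"), each = 40))
  res <- class_comparison(m, catalog)
  chi_hand <- 80 * (30 * 30 - 10 * 10)^2 / (40 * 40 * 40 * 40)
  expect_equal(res$chisq_p, stats::pchisq(chi_hand, 1, lower.tail = FALSE))
  expect_false(res$chisq_unreliable)

  same <- make_catalog(names(rows), or_status = "intact",
                       or_class = rep(c("I", "II"), 40))
  res_same <- class_comparison(m, same)
  expect_gt(res_same$chisq_p, 0.2)
})

test_that("score-expression association splits at the median and detects signal", {
  set.seed(30)
  n <- 41
  expr <- sort(10^rnorm(n))
  rows <- setNames(lapply(expr, function(v) c(a = v)), sprintf("g%03d", 1:n))
  m <- make_expr(rows, c(a = "OE"))
  catalog <- make_catalog(names(rows), or_status = "intact",
                          score = seq(0, 1, length.out = n))  # monotone in expr
  res <- score_expression_association(m, catalog)
  expect_equal(res$n_low, 20)
  expect_equal(res$n_high, 21)
  expect_lt(res$p_value, 1e-4)

  flat <- make_catalog(names(rows), or_status = "intact", score = 0.5)
  expect_error(score_expression_association(m, flat), "equal")
})

test_that("segregating-pseudogene rerun reports both versions and is robust", {
  st <- simulate_expression_study(simulation_config(seed = 17, n_genes = 100,
                                                    n_or_intact = 400,
                                                    n_or_pseudo = 400))
  m <- st$human$fpkm
  oe <- samples_in_group(m$sample_groups, "OE")
  half_of <- function(cat) {
    ors <- cat$gene_id[cat$or_status != "non_OR"]
    rank_and_cumulative(m, ors, oe)$half_fraction
  }
  res <- rerun_excluding_segregating(st$catalog, half_of)
  expect_lt(abs(res$full - res$excluded), 0.05)

  none <- st$catalog
  none$segregating_pseudogene <- FALSE
  res2 <- rerun_excluding_segregating(none, half_of)
  expect_identical(res2$full, res2$excluded)

  all_flagged <- st$catalog
  all_flagged$segregating_pseudogene <- all_flagged$or_status != "non_OR"
  expect_error(rerun_excluding_segregating(all_flagged, function(cat) {
    status_distribution_test(m, cat, oe)
  }), "status")
})
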