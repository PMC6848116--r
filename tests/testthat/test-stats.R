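# Correlation t-test, hypergeometric tail, BH adjustment, enrichment, DE.

test_that("pearson_r matches the covariance formula and flags degeneracy", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  set.seed(3)
  for (rep in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_r(x, y), direct, tolerance = 1e-12)
  }
  expect_warning(r <- pearson_r(rep(1, 6), rnorm(6)), "zero-variance")
  expect_true(is.na(r))
})

test_that("correlation t statistic follows its closed form", {
  res <- corr_t_test(0, 6)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # r = 0.9, N = 6: t = 0.9 / sqrt(0.19 / 4)
  res <- corr_t_test(0.9, 6)
  expect_equal(res$t, 0.9 / sqrt((1 - 0.81) / 4), tolerance = 1e-12)
  expect_equal(res$t, 4.129483, tolerance = 1e-6)
  expect_equal(corr_t_test(1, 10)$p, 0)
  expect_error(corr_t_test(0.5, 2), "N must be")
})

test_that("correlation test is antisymmetric in r", {
  set.seed(5)
  for (rep in 1:50) {
    r <- runif(1, -0.999, 0.999); N <- sample(3:20, 1)
    a <- corr_t_test(r, N); b <- corr_t_test(-r, N)
    expect_equal(a$t, -b$t, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})

test_that("hypergeometric tail matches exact enumeration on small cases", {
  # n=5, m=15, N=4, i=3: (C(5,3)C(15,1) + C(5,4)C(15,0)) / C(20,4) = 155/4845
  expect_equal(hypergeom_tail(5, 15, 4, 3), 155 / 4845, tolerance = 1e-12)
  expect_equal(hypergeom_tail(5, 15, 4, 3),
               oracle_hyper_tail_enum(5, 15, 4, 3), tolerance = 1e-12)
  expect_equal(hypergeom_tail(5, 15, 4, 0), 1)   # whole support
  expect_equal(hypergeom_tail(0, 10, 3, 0), 1)   # degenerate, no successes
  expect_error(hypergeom_tail(5, 15, 30, 2), "N must satisfy")
  expect_error(hypergeom_tail(5, 15, 4, 5), "i must satisfy")
})

test_that("hypergeometric pmf sums to 1 and agrees with stats::dhyper", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(0:25, 1); m <- sample(0:25, 1); N <- sample(0:(n + m), 1)
    ks <- max(0, N - m):min(n, N)
    pm <- vapply(ks, function(k) hypergeom_pmf(n, m, N, k), numeric(1))
    expect_equal(sum(pm), 1, tolerance = 1e-12)
    expect_equal(pm, stats::dhyper(ks, n, m, N), tolerance = 1e-12)
  }
})

test_that("correlation classification applies the r and q thresholds", {
  expect_equal(classify_correlation(0.95, 0.005), "positive")
  expect_equal(classify_correlation(-0.95, 0.005), "negative")
  expect_equal(classify_correlation(0.95, 0.02), "none")   # q fails
  expect_equal(classify_correlation(0.85, 0.001), "none")  # r fails
  expect_equal(classify_correlation(NA, 0.001), "none")
})

test_that("BH adjustment equals the literal step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(9)
  for (rep in 1:25) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  # monotone non-decreasing on sorted input; q >= p elementwise
  p <- sort(runif(20))
  q <- bh_adjust(p)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q >= p))
})

test_that("term enrichment: universal terms are never enriched, plants win", {
  universe <- sprintf("g%03d", 1:100)
  query <- universe[1:10]
  tm <- rbind(
    data.frame(gene_id = universe, term_id = "T_all"),
    data.frame(gene_id = c(query, universe[11:15]), term_id = "T_plant"),
    data.frame(gene_id = universe[seq(1, 100, 7)], term_id = "T_bg"))
  res <- enrich_terms(query, tm, universe)
  expect_equal(res$p[res$term_id == "T_all"], 1)
  # planted term: all 10 query genes vs 15/100 in the universe
  expect_equal(res$term_id[1], "T_plant")
  expect_equal(res$i[res$term_id == "T_plant"], 10L)
  expect_equal(res$n[res$term_id == "T_plant"], 15L)
  expect_equal(res$p[res$term_id == "T_plant"],
               oracle_hyper_tail_pascal(15, 85, 10, 10), tolerance = 1e-12)
  expect_equal(res$q, oracle_bh(res$p)[order(order(res$q, res$p))],
               tolerance = 1e-12)
  expect_equal(nrow(enrich_terms(character(0), tm, universe)), 0)
  expect_error(enrich_terms("not_here", tm, universe), "absent from universe")
})

test_that("differential expression recovers a planted extreme and flags
           degenerate profiles", {
  sm <- c(M1 = "M", M2 = "M", P1 = "P", P2 = "P", FB1 = "FB", FB2 = "FB")
  vals <- rbind(c1 = c(100, 110, 1, 2, 1, 3),
                c2 = c(5, 5, 5, 5, 5, 5),
                c3 = c(2, 3, 2.5, 3.5, 2.2, 3.1))
  colnames(vals) <- names(sm)
  res <- de_test(expr_table(vals, sm))
  expect_equal(res$highest_stage[1], "M")
  expect_lt(res$p[1], 0.05)
  expect_true(res$degenerate[2])
  expect_true(is.na(res$q[2]))
  expect_false(res$degenerate[3])
  expect_gt(res$p[3], 0.1)
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  expect_error(de_test(expr_table(vals[, -1], sm[-1])), "fewer than 2")
})

test_that("correlate_pairs classifies planted signs in one BH family", {
  sm <- c(M1 = "M", M2 = "M", P1 = "P", P2 = "P", FB1 = "FB", FB2 = "FB")
  set.seed(21)
  g <- matrix(exp(rnorm(5 * 6, log(50), 0.8)), 5,
              dimnames = list(paste0("g", 1:5), names(sm)))
  circ <- rbind(cp = 2 * g[1, ] + rnorm(6, 0, 0.01),
                cn = max(g[2, ]) * 1.2 - g[2, ] + rnorm(6, 0, 0.01),
                cflat = 30 * exp(rnorm(6, 0, 0.02)),
                czero = rep(3, 6))
  colnames(circ) <- names(sm)
  pairs <- data.frame(circ_id = c("cp", "cn", "cflat", "czero"),
                      partner_id = c("g1", "g2", "g3", "g4"))
  res <- correlate_pairs(expr_table(circ, sm), expr_table(g, sm), pairs)
  expect_equal(res$corr_class[res$circ_id == "cp"], "positive")
  expect_equal(res$corr_class[res$circ_id == "cn"], "negative")
  expect_equal(res$corr_class[res$circ_id == "cflat"], "none")
  expect_true(res$undefined[res$circ_id == "czero"])
  expect_true(is.na(res$q[res$circ_id == "czero"]))
})
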