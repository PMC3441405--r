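# craft matrices whose per-pairing fold changes are exactly `fc` columns
set_from_fc <- function(fc) {
  n <- nrow(fc)
  ctrl <- matrix(0, n, ncol(fc), dimnames = list(rownames(fc), NULL))
  list(control = ctrl, treated = fc)
}

test_that("rank product is the geometric mean of per-pairing ranks", {
  # gene ranked 1 in both pairings -> RP = 1
  fc <- cbind(c(10, 3, 2, 1, 0), c(9, 2, 3, 1, 0))
  rownames(fc) <- paste0("g", 1:5)
  g <- set_from_fc(fc)
  rp <- rank_product_statistic(g$control, g$treated, "up")
  expect_equal(unname(rp$rp["g1"]), 1)
  # gene with ranks (2, 3) -> sqrt(6)
  expect_equal(unname(rp$ranks["g2", ]), c(2, 3))
  expect_equal(unname(rp$rp["g2"]), sqrt(6))
})

test_that("reversing direction mirrors the ranking", {
  set.seed(4)
  g <- make_groups(50, 3, effects = 0)
  up_on_negated <- rank_product_statistic(-g$control, -g$treated, "up")
  down <- rank_product_statistic(g$control, g$treated, "down")
  # negating expression flips every fold change, so up on negated == down
  expect_equal(up_on_negated$rp, down$rp)
})

test_that("rank product is invariant under increasing affine transforms", {
  set.seed(5)
  g <- make_groups(40, 3, effects = 0)
  a <- rank_product_statistic(g$control, g$treated, "up")
  b <- rank_product_statistic(3 * g$control + 2, 3 * g$treated + 2, "up")
  expect_equal(a$rp, b$rp)
})

test_that("pfp matches exhaustive permutation enumeration on a tiny instance", {
  fc <- cbind(c(2.0, 1.2, -0.3, 0.5, -1.5), c(1.8, 0.9, 0.1, -0.2, -1.1))
  rownames(fc) <- paste0("g", 1:5)
  g <- set_from_fc(fc)
  rp <- rank_product_statistic(g$control, g$treated, "up")
  exact <- oracle_pfp_exhaustive(rp$ranks, rp$rp)
  est <- estimate_pfp(rp, n_permutations = 40000L, seed = 1)
  # Monte-Carlo SE of the expected count is well below this tolerance at 4e4
  expect_equal(unname(est), unname(exact), tolerance = 0.02)
})

test_that("pfp is monotone in rank order and nonnegative", {
  set.seed(6)
  g <- make_groups(100, 3, effects = c(rep(2, 10), rep(0, 90)))
  rp <- rank_product_statistic(g$control, g$treated, "up")
  pfp <- estimate_pfp(rp, 200, seed = 2)
  ord <- order(rp$rp)
  expect_true(all(diff(pfp[ord]) >= 0))
  expect_true(all(pfp >= 0))
  expect_warning(estimate_pfp(rp, 50, seed = 1), "unstable")
})

test_that("null data yields almost no calls at pfp < 0.2", {
  set.seed(7)
  called <- vapply(1:60, function(i) {
    g <- make_groups(150, 3, effects = 0, seed = 1000L + i)
    tab <- rank_product_table(g$control, g$treated, n_permutations = 100,
                              seed = i)
    sum(call_degs(tab, 0.2)$significant)
  }, numeric(1))
  # a calibrated pfp admits ~no false predictions without true ones
  expect_lt(mean(called) / 150, 0.02)
})

test_that("planted DEGs are recovered with high recall at pfp < 0.2", {
  cfg <- synthetic_config(n_genes = 1000, effect_size = 2, noise_sd = 0.3,
                          n_replicates = 3,
                          class_fractions = c(coupled = 0,
                                              antidirectional = 0,
                                              transcriptome_only = 0,
                                              translatome_only = 0.05,
                                              unchanged = 0.95),
                          seed = 17)
  d <- generate_paired_dataset(cfg)
  tab <- rank_product_table(d$set$matrices$translatome_control,
                            d$set$matrices$translatome_treated,
                            n_permutations = 500, seed = 3)
  called <- attr(call_degs(tab, 0.2), "degs")
  planted <- d$truth$gene_id[d$truth$effect_translatome != 0]
  expect_gte(mean(planted %in% called), 0.9)
})

test_that("noiseless planted data is called exactly at any threshold below 1", {
  # planted genes share one exact fold change, so they tie at one average
  # rank; the permutation null then gives them a small pfp floor of about
  # n_genes * (n_tied / n_genes)^K, which must sit below the thresholds used
  cfg <- synthetic_config(n_genes = 200, noise_sd = 0, effect_size = 2,
                          class_fractions = c(coupled = 0,
                                              antidirectional = 0,
                                              transcriptome_only = 0,
                                              translatome_only = 0.05,
                                              unchanged = 0.95),
                          seed = 23)
  d <- generate_paired_dataset(cfg)
  tab <- rank_product_table(d$set$matrices$translatome_control,
                            d$set$matrices$translatome_treated,
                            n_permutations = 500, seed = 5)
  planted <- d$truth$gene_id[d$truth$effect_translatome != 0]
  for (th in c(0.05, 0.2, 0.5)) {
    called <- attr(call_degs(tab, th), "degs")
    expect_setequal(called, planted)
  }
  expect_length(attr(call_degs(tab, 0), "degs"), 0L)
})

test_that("t statistics and BH adjustment match stats::t.test and hand step-up", {
  set.seed(8)
  g <- make_groups(20, 4, effects = 0)
  res <- ttest_bh_caller(g$control, g$treated)
  for (i in c(1L, 7L, 20L)) {
    ref <- stats::t.test(g$treated[i, ], g$control[i, ], var.equal = TRUE)
    expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
  }
  expect_equal(res$padj, stats::p.adjust(res$p, "BH"))

  # hand BH on three p-values: sorted p * 3 / rank, cumulative min from top
  p3 <- c(0.01, 0.04, 0.02)
  hand <- pmin(1, rev(cummin(rev(sort(p3) * 3 / 1:3))))[rank(p3)]
  expect_equal(stats::p.adjust(p3, "BH"), hand)
})

test_that("identical groups give no t-test calls and zero-variance is handled", {
  m <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  res <- ttest_bh_caller(m, m)
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
  trt <- m; trt[1, ] <- 7         # constant but shifted: variance floored
  res2 <- ttest_bh_caller(m, trt)
  expect_lt(res2$p[1], 0.05)
  expect_equal(attr(res2, "n_variance_floored"), 1L)
})

test_that("t-test type-I error at raw p < 0.05 is near nominal", {
  set.seed(9)
  hits <- 0; total <- 0
  for (i in 1:200) {
    g <- make_groups(50, 3, effects = 0, seed = 2000L + i)
    res <- ttest_bh_caller(g$control, g$treated)
    hits <- hits + sum(res$p < 0.05)
    total <- total + 50
  }
  expect_lt(abs(hits / total - 0.05), 0.01)
})
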