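test_that("likelihood ratio test matches the dbinom oracle", {
  eq <- likelihood_ratio_test(80, 80, 1000)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)

  r <- likelihood_ratio_test(50, 100, 1000)
  expect_equal(r$statistic, oracle_lrt_g(50, 100, 1000), tolerance = 1e-10)
  expect_equal(r$statistic, 18.34, tolerance = 0.01)
  expect_lt(r$p, 1e-4)

  # grid oracle check + consistency: doubling all counts increases G
  set.seed(14)
  for (i in 1:10) {
    N <- sample(200:2000, 1)
    n1 <- sample.int(N %/% 2, 1); n2 <- sample.int(N %/% 2, 1)
    g1 <- likelihood_ratio_test(n1, n2, N)$statistic
    expect_equal(g1, oracle_lrt_g(n1, n2, N), tolerance = 1e-8)
    if (n1 != n2)
      expect_gt(likelihood_ratio_test(2 * n1, 2 * n2, 2 * N)$statistic, g1)
  }
  expect_error(likelihood_ratio_test(5, 5, 0), "positive")
})

test_that("exact overlap tail matches enumeration and is symmetric", {
  expect_equal(hypergeometric_overlap_pvalue(5, 4, 10, 0), 1)
  expect_equal(hypergeometric_overlap_pvalue(5, 4, 10, 4), 5 / 210,
               tolerance = 1e-12)
  expect_equal(hypergeometric_overlap_pvalue(5, 4, 10, 4),
               oracle_overlap_tail(5, 4, 10, 4), tolerance = 1e-12)
  set.seed(15)
  for (i in 1:10) {
    N <- sample(8:14, 1)
    n1 <- sample.int(N - 1, 1); n2 <- sample.int(N - 1, 1)
    k <- sample.int(min(n1, n2), 1)
    expect_equal(hypergeometric_overlap_pvalue(n1, n2, N, k),
                 hypergeometric_overlap_pvalue(n2, n1, N, k),
                 tolerance = 1e-12)
    expect_equal(hypergeometric_overlap_pvalue(n1, n2, N, k),
                 oracle_overlap_tail(n1, n2, N, k), tolerance = 1e-12)
  }
  expect_error(hypergeometric_overlap_pvalue(5, 4, 10, 5), "invalid")
})

test_that("random overlap bootstrap agrees with the exact tail", {
  ov <- random_overlap_test(5, 4, 10, 4, n_iter = 20000L, seed = 6)
  exact <- 5 / 210
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(ov$p - exact), 3 * se + 2 / 20001)

  # k = 0 -> p = 1 up to the add-one correction
  expect_gte(random_overlap_test(5, 4, 20, 0, n_iter = 500, seed = 1)$p,
             500 / 501)
  # n1 = N: every draw overlaps in exactly n2 genes
  full <- random_overlap_test(10, 4, 10, 4, n_iter = 500, seed = 1)
  expect_equal(full$p, 1)
  expect_equal(full$null_sd, 0)
  expect_error(random_overlap_test(5, 4, 10, 5, 100, 1), "exceed")
})

test_that("binary mutual information matches the plug-in formula", {
  # exact product-form table -> MI = 0
  x <- rep(c(1, 1, 0, 0), 25)
  y <- rep(c(1, 0, 1, 0), 25)
  expect_equal(mutual_information_binary(x, y), 0)
  # x = y -> marginal entropy
  z <- c(rep(1, 20), rep(0, 80))
  h <- -(0.2 * log2(0.2) + 0.8 * log2(0.8))
  expect_equal(mutual_information_binary(z, z), h, tolerance = 1e-12)
  # zero-overlap 20/20 lists in 100 genes: table (0, 20, 20, 60)
  x2 <- rep(c(1, 0, 0), c(20, 20, 60))
  y2 <- rep(c(0, 1, 0), c(20, 20, 60))
  expect_equal(mutual_information_binary(x2, y2),
               oracle_mi(0, 20, 20, 60), tolerance = 1e-12)
  expect_equal(mutual_information_binary(x2, y2), 0.0729, tolerance = 1e-4)
  expect_error(mutual_information_binary(1:3, 1:4), "mismatch")
})

test_that("MI is zero only for product-form tables", {
  set.seed(16)
  for (i in 1:20) {
    x <- stats::runif(60) < 0.3
    y <- stats::runif(60) < 0.4
    mi <- mutual_information_binary(x, y)
    expect_gte(mi, 0)
    tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE))) / 60
    product_form <- all(abs(tab - outer(rowSums(tab), colSums(tab))) < 1e-12)
    expect_equal(mi == 0, product_form)
  }
})

test_that("MI feasibility bounds match their closed forms", {
  zero <- mi_bounds(0, 0, 50)
  expect_equal(zero$mi_min, 0)
  expect_equal(zero$mi_max, 0)
  b <- mi_bounds(20, 20, 100)
  h02 <- -(0.2 * log2(0.2) + 0.8 * log2(0.8))
  expect_equal(b$mi_max, h02, tolerance = 1e-12)
  expect_equal(b$mi_min, oracle_mi(0, 20, 20, 60), tolerance = 1e-12)

  # overlap forced when lists cannot be disjoint
  bf <- mi_bounds(60, 70, 100)
  expect_equal(bf$forced_overlap, 30)
  expect_equal(bf$mi_min, oracle_mi(30, 30, 40, 0), tolerance = 1e-12)

  set.seed(17)
  for (i in 1:25) {
    N <- sample(50:500, 1)
    n1 <- sample.int(N, 1); n2 <- sample.int(N, 1)
    b <- mi_bounds(n1, n2, N)
    expect_lte(b$mi_min, b$mi_max + 1e-12)
    expect_equal(b$mi_max,
                 oracle_mi(floor((n1 + n2) / 2), 0, 0,
                           N - floor((n1 + n2) / 2)), tolerance = 1e-12)
  }
})

test_that("MI test reports feasible values and boundary midrange positions", {
  z <- rep(c(TRUE, FALSE), c(30, 70))
  full <- mi_test(z, z, n_iter = 300, seed = 2)
  expect_equal(full$midrange_position, 1, tolerance = 1e-12)
  expect_lt(full$p, 0.05)

  set.seed(18)
  for (i in 1:5) {
    # positively associated labels: a shared core plus private DEGs
    core <- stats::runif(80) < 0.15
    x <- core | (stats::runif(80) < 0.05)
    y <- core | (stats::runif(80) < 0.1)
    r <- mi_test(x, y, n_iter = 200, seed = i)
    expect_gte(r$mi_observed, r$mi_min - 1e-12)
    expect_lte(r$mi_observed, r$mi_max + 1e-12)
  }
  degenerate <- mi_test(logical(10), logical(10), n_iter = 50, seed = 1)
  expect_true(is.na(degenerate$midrange_position))
})

test_that("the combined independence result is internally consistent", {
  set.seed(19)
  universe <- sprintf("g%04d", 1:800)
  degs1 <- sample(universe, 60)
  degs2 <- sample(universe, 90)
  res <- independence_tests(degs1, degs2, universe, n_iter = 2000, seed = 4)
  expect_equal(res$N, 800)
  expect_equal(res$k, length(intersect(degs1, degs2)))
  expect_lte(res$k, min(res$n1, res$n2))
  expect_gte(res$mi_observed, 0)
  expect_lte(res$mi_observed, res$mi_max + 1e-12)
  se <- sqrt(res$overlap_p_exact * (1 - res$overlap_p_exact) / 2000)
  expect_lt(abs(res$overlap_p - res$overlap_p_exact), 4 * se + 2 / 2001)
  expect_error(independence_tests("zz", degs2, universe, 100, 1), "subset")
})

test_that("planted-independent DEG labels are rarely called dependent", {
  set.seed(20)
  sig <- 0L
  for (i in 1:40) {
    x <- stats::runif(500) < 0.1
    y <- stats::runif(500) < 0.15
    if (mi_test(x, y, n_iter = 500, seed = 100L + i)$p < 0.01)
      sig <- sig + 1L
    }
  expect_lte(sig / 40, 0.05)
})
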