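test_that("CPM normalization is exact and scale-invariant", {
  counts <- matrix(c(10, 0, 5, 20, 0, 5), nrow = 3,
                   dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  m <- cpm_normalize(counts, c(s1 = 100, s2 = 200))
  expect_equal(m["f1", "s1"], 100000)
  expect_equal(unname(m["f2", ]), c(0, 0))
  m2 <- cpm_normalize(2 * counts, c(s1 = 200, s2 = 400))
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
  expect_error(cpm_normalize(counts, c(s1 = 100, s2 = 0)), "s2")
})

test_that("log2(CPM + c) transform is exact and monotone", {
  m <- cpm_normalize(matrix(c(0, 3), nrow = 2), 1e6)
  lg <- log_transform(m, c = 1)
  expect_equal(unname(lg[, 1]), c(0, 2))            # log2(1), log2(4)
  expect_error(log_transform(m, c = 0), "c must be > 0")
  expect_error(log_transform(lg), "CPM")
  set.seed(1)
  cpm <- cpm_normalize(matrix(rpois(100, 50), ncol = 2), c(1e5, 1e5))
  expect_true(all(diff(order(log_transform(cpm)[, 1])) ==
                  diff(order(cpm[, 1]))))
})

test_that("sample correlation separates conditions under a planted treatment effect", {
  dup <- matrix(c(1, 2, 3, 1, 2, 3, 3, 2, 1), ncol = 3)
  r <- sample_correlation(dup)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_true(isSymmetric(r))
  expect_warning(sample_correlation(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "zero-variance")

  # 2 control + 2 treated replicates; half the features enriched 50x:
  # within-condition correlation exceeds between-condition correlation
  set.seed(8)
  mu <- rexp(200, 1 / 50)
  enrich <- c(rep(50, 100), rep(1, 100))
  counts <- cbind(c1 = rpois(200, mu), c2 = rpois(200, mu),
                  t1 = rpois(200, mu * enrich), t2 = rpois(200, mu * enrich))
  lg <- log_transform(cpm_normalize(counts, colSums(counts)))
  r <- sample_correlation(lg)
  within <- c(r["c1", "c2"], r["t1", "t2"])
  between <- c(r["c1", "t1"], r["c1", "t2"], r["c2", "t1"], r["c2", "t2"])
  expect_gt(min(within), max(between))
})

test_that("common dispersion: Poisson ~ 0, NB recovered, constants give 0", {
  set.seed(15)
  grp <- rep(c("a", "b"), each = 10)
  lib <- rep(1e6, 20)
  mu <- rexp(2000, 1 / 100)
  pois <- sapply(1:20, function(i) rpois(2000, mu))
  expect_lte(estimate_common_dispersion(pois, lib, grp), 0.05)

  nb <- sapply(1:20, function(i) rnbinom(2000, mu = mu, size = 1 / 0.2))
  phi_hat <- estimate_common_dispersion(nb, lib, grp)
  expect_gte(phi_hat, 0.1); expect_lte(phi_hat, 0.3)

  const <- matrix(7, nrow = 10, ncol = 4)
  expect_identical(estimate_common_dispersion(const, rep(1e6, 4),
                                              rep(c("a", "b"), 2)), 0)
  expect_warning(
    phi1 <- estimate_common_dispersion(const[, 1:2], rep(1e6, 2), c("a", "b")),
    "Poisson fallback")
  expect_identical(phi1, 0)
})

test_that("exact conditional binomial test matches closed forms and enumeration", {
  grp <- factor(c("control", "treated"), levels = c("control", "treated"))
  # symmetric data: p = 1
  et <- enrichment_test(matrix(c(25, 25), nrow = 1), c(1e5, 1e5), grp)
  expect_equal(et$p, 1)
  # 0 control vs 40 treated, equal libraries: doubled binomial tail
  et <- enrichment_test(matrix(c(0, 40), nrow = 1), c(1e5, 1e5), grp)
  expect_equal(et$p, 2 * 0.5^40)
  # zero-total feature
  et0 <- enrichment_test(matrix(c(0, 0), nrow = 1), c(1e5, 2e5), grp)
  expect_equal(et0$p, 1); expect_equal(et0$log2fc, 0)

  # oracle: brute-force enumeration of the doubled binomial tail for a grid
  # of totals <= 200 and unequal library shares
  set.seed(91)
  cases <- data.frame(a = c(0, 3, 17, 100, 120, 60),
                      b = c(40, 80, 17, 100, 80, 3))
  libs <- c(2e5, 1e5)               # treated share = 1/3
  p1 <- libs[2] / sum(libs)
  for (i in seq_len(nrow(cases))) {
    a <- cases$a[i]; b <- cases$b[i]; n <- a + b
    pmf <- vapply(0:n, function(x)
      choose(n, x) * p1^x * (1 - p1)^(n - x), numeric(1))
    oracle <- min(1, 2 * min(sum(pmf[seq_len(a + 1)]), sum(pmf[(a + 1):(n + 1)])))
    got <- enrichment_test(matrix(c(b, a), nrow = 1), libs, grp)$p
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("beta-binomial p-values reduce to binomial as phi -> 0 and widen with phi", {
  grp <- factor(c("control", "treated"), levels = c("control", "treated"))
  cnt <- matrix(c(10, 40), nrow = 1)
  p0 <- enrichment_test(cnt, c(1e5, 1e5), grp, phi = 0)$p
  p_small <- enrichment_test(cnt, c(1e5, 1e5), grp, phi = 1e-6)$p
  p_big <- enrichment_test(cnt, c(1e5, 1e5), grp, phi = 0.5)$p
  expect_equal(p_small, p0, tolerance = 1e-3)
  expect_gt(p_big, p0)
})

test_that("BH step-up matches the hand-computed example and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(6)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm])
})

test_that("enrichment calls use FC 2.0 and FDR 0.05 with inclusive boundary", {
  tab <- data.frame(feature = c("a", "b", "c"),
                    log2fc = c(1.0, 3, -2), q = c(0.01, 0.2, 0.001))
  out <- call_enriched(tab)
  expect_identical(out$call, c("enriched", "ns", "depleted"))
})

test_that("2^-ddCt returns the expected relative expression", {
  # ddCt = 0, 1, -2 for target/reference Ct combinations
  expect_equal(ddct(20, 15, 22, 17), 1)
  expect_equal(ddct(21, 15, 22, 17), 0.5)
  expect_equal(ddct(18, 15, 22, 17), 4)
  expect_error(ddct(NA, 15, 22, 17), "missing")
})

test_that("null binomial test is calibrated near the nominal level", {
  set.seed(77)
  grp <- factor(c("control", "treated"), levels = c("control", "treated"))
  counts <- cbind(rpois(2000, 400), rpois(2000, 400))
  et <- enrichment_test(counts, c(1e6, 1e6), grp)
  rej <- mean(et$p < 0.05)
  expect_gte(rej, 0.035); expect_lte(rej, 0.065)
})
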