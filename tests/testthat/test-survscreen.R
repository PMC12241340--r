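test_that("median split sends ties to low and flags constant vectors", {
  g <- median_split(c(1, 2, 3, 4))
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  g2 <- median_split(c(1, 2, 2, 3))
  expect_identical(as.character(g2), c("low", "low", "low", "high"))
  expect_identical(attr(g2, "n_low"), 3L)
  expect_true(attr(median_split(rep(5, 10)), "degenerate"))
  expect_false(attr(g, "degenerate"))
})

test_that("Kaplan-Meier product-limit matches exact rational arithmetic", {
  km <- km_curve(1:5, rep(1, 5))
  # after the third event: 4/5 * 3/4 * 2/3 = 2/5
  expect_equal(km$surv[3], 0.4)
  expect_equal(km$surv, c(4/5, 3/5, 2/5, 1/5, 0))
  expect_equal(km$n_risk, 5:1)
  # all censored: flat at 1
  kmc <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(kmc$surv == 1))
  # single patient with an event
  km1 <- km_curve(6, 1)
  expect_equal(km1$surv, 0)
  expect_error(km_curve(numeric(0), numeric(0)))
})

test_that("log-rank is zero on identical groups and matches a permutation null", {
  t2 <- rep(c(3, 5, 8, 12, 15), 2)
  e2 <- rep(c(1, 0, 1, 1, 0), 2)
  g2 <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(t2, e2, g2)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_warning(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")

  # 20-patient fixture: chi-square p vs an independent permutation null
  set.seed(12)
  tm <- c(rexp(10, 0.1), rexp(10, 0.25))
  ev <- rbinom(20, 1, 0.8)
  gr <- rep(c("lo", "hi"), each = 10)
  obs <- logrank_test(tm, ev, gr)
  perm <- replicate(5000, {
    logrank_test(tm, ev, sample(gr))$chisq
  })
  p_perm <- mean(perm >= obs$chisq)
  expect_lt(abs(p_perm - obs$p), 0.05)
})

test_that("Cox fit recovers a four-patient partial-likelihood optimum", {
  # no ties; events alternate between arms so the likelihood has a finite
  # maximum, located here by direct numeric optimization of the closed-form
  # partial log-likelihood
  tm <- c(1, 2, 3, 4); ev <- rep(1, 4); x <- c(1, 0, 1, 0)
  pll <- function(b)
    (b - log(2 * exp(b) + 2)) + (0 - log(exp(b) + 2)) +
    (b - log(exp(b) + 1)) + 0
  b_opt <- optimize(pll, c(-5, 5), maximum = TRUE)$maximum
  fit <- cox_fit(tm, ev, x)
  expect_equal(fit$beta, b_opt, tolerance = 1e-4)
  expect_false(fit$unbounded)

  # two patients with the event in the exposed arm first: monotone
  # likelihood, flagged as unbounded
  expect_warning(sep <- cox_fit(c(1, 2), c(1, 1), c(1, 0)), "unbounded")
  expect_true(sep$unbounded)
  expect_identical(sep$hr, Inf)
})

test_that("Cox score test at beta = 0 equals the log-rank statistic without ties", {
  set.seed(5)
  tm <- sort(runif(40, 1, 100))            # distinct times, no ties
  ev <- rbinom(40, 1, 0.7)
  x <- rbinom(40, 1, 0.5)
  lr <- logrank_test(tm, ev, factor(x))
  cx <- cox_fit(tm, ev, x)
  expect_equal(cx$score_chisq, lr$chisq, tolerance = 1e-6)
})

test_that("Cox null calibration rejects near the nominal rate", {
  set.seed(30)
  rej <- replicate(60, {
    tm <- rexp(100, 0.02); ev <- rep(1, 100); x <- rbinom(100, 1, 0.5)
    cox_fit(tm, ev, x)$p < 0.05
  })
  expect_lte(mean(rej), 0.15)
  expect_gte(mean(rej), 0.0)
})

test_that("survival screen recovers planted effects with the right sign", {
  eff <- c(feat_0005 = log(2.2), feat_0010 = -log(2.2))
  co <- simulate_cohort(cohort_config(n_patients = 400, n_features = 30,
                                      effect = eff, censor_rate = 0.003,
                                      seed = 64))
  st <- survival_screen(co$expr, co$clinical)
  expect_identical(st$class[st$feature == "feat_0005"], "worse")
  expect_identical(st$class[st$feature == "feat_0010"], "better")
  expect_true(all(st$q >= st$p, na.rm = TRUE))
  # classification invariants
  worse <- st[st$class == "worse", ]
  expect_true(all(worse$hr > 1 & worse$p < 0.05))
  better <- st[st$class == "better", ]
  expect_true(all(better$hr < 1 & better$p < 0.05))
})

test_that("screen is invariant to strictly monotone transforms of expression", {
  co <- simulate_cohort(cohort_config(n_patients = 150, n_features = 12,
                                      effect = c(feat_0002 = log(2)),
                                      seed = 11))
  st1 <- survival_screen(co$expr, co$clinical)
  st2 <- survival_screen(exp(co$expr / 3) + 2, co$clinical)
  expect_identical(st1$class, st2$class)
  expect_equal(st1$hr, st2$hr)
})

test_that("screen errors on orphan sample ids and applies the ten-year cap", {
  co <- simulate_cohort(cohort_config(n_patients = 40, n_features = 4,
                                      seed = 3))
  clin_bad <- co$clinical
  clin_bad$sample_id[1] <- "ghost"
  expect_error(survival_screen(co$expr, clin_bad), "ghost")

  # events beyond the cap must be censored at the cap; a fixture with two
  # late events (so the earlier one has a non-trivial risk set uncapped)
  set.seed(44)
  n <- 12
  expr <- matrix(rnorm(2 * n, 5, 2), nrow = 2,
                 dimnames = list(c("fA", "fB"), sprintf("P%02d", 1:n)))
  clin <- data.frame(sample_id = sprintf("P%02d", 1:n),
                     time_months = c(seq(10, 100, by = 10), 130, 150),
                     event = 1L)
  st_capped <- survival_screen(expr, clin, truncate_months = 120)
  st_raw <- survival_screen(expr, clin, truncate_months = 1000)
  expect_false(isTRUE(all.equal(st_capped$p, st_raw$p)))
  expect_false(isTRUE(all.equal(st_capped$hr, st_raw$hr)))
})

test_that("adjusted Cox columns appear when confounders are requested", {
  co <- simulate_cohort(cohort_config(n_patients = 120, n_features = 6,
                                      effect = c(feat_0001 = log(2)),
                                      seed = 21))
  st <- survival_screen(co$expr, co$clinical,
                        adjust = c("age", "grade", "subtype"))
  expect_true(all(c("hr_adj", "p_adj") %in% names(st)))
  expect_true(is.finite(st$hr_adj[st$feature == "feat_0001"]))
  expect_error(survival_screen(co$expr, co$clinical, adjust = "bmi"), "bmi")
})
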