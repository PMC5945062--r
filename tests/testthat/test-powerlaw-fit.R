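test_that("closed-form exponent estimator reproduces hand-computed values", {
  # all ones, kmin = 1: 1 + 1/log 2
  expect_equal(mle_exponent(rep(1, 100), kmin = 1, method = "hill"),
               1 + 1 / log(2), tolerance = 1e-12)
  expect_equal(round(mle_exponent(rep(1, 100), kmin = 1, method = "hill"), 4),
               2.4427)
  # {1,1,2,3,5}: 1 + 5 / log(2*2*4*6*10)
  expect_equal(mle_exponent(c(1, 1, 2, 3, 5), kmin = 1, method = "hill"),
               1 + 5 / log(960), tolerance = 1e-12)
  expect_equal(round(mle_exponent(c(1, 1, 2, 3, 5), kmin = 1,
                                  method = "hill"), 3), 1.728)
})

test_that("closed-form and exact zeta MLE converge for larger kmin", {
  # the closed form's error scales with (alpha - 1); it is inside 0.01 by
  # kmin = 6 for alpha = 2 and by kmin = 10 for alpha = 3, shrinking in kmin
  for (cs in list(c(2, 6), c(3, 10))) {
    k <- rpowerlaw(5000, powerlaw_model(cs[1], kmin = cs[2]),
                   seed = cs[1] * 10 + cs[2])
    expect_lt(abs(mle_exponent(k, kmin = cs[2], method = "hill") -
                    mle_exponent(k, kmin = cs[2], method = "exact")), 0.01)
  }
  diffs <- vapply(c(3, 6, 12, 24), function(km) {
    k <- rpowerlaw(5000, powerlaw_model(3, kmin = km), seed = km)
    abs(mle_exponent(k, kmin = km, method = "hill") -
          mle_exponent(k, kmin = km, method = "exact"))
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))
  # at kmin = 1 the two estimators differ visibly (the closed form is an
  # approximation) but both sit near the truth
  k1 <- pl_sample(5000, 2.5, seed = 3)
  expect_lt(abs(mle_exponent(k1, 1, method = "exact") - 2.5), 0.1)
})

test_that("exact MLE agrees with igraph's independent plfit implementation", {
  k <- pl_sample(5000, 2.3, seed = 5)
  f <- fit_power_law(k)
  ig <- igraph::fit_power_law(k, implementation = "plfit")
  expect_equal(f$alpha, ig$alpha, tolerance = 0.02)
  expect_equal(f$kmin, ig$xmin)
})

test_that("KS distance matches closed forms and a brute-force scan", {
  # single-point support: empirical == model, D = 0
  m1 <- powerlaw_model(2, kmin = 3, kmax = 3)
  expect_equal(ks_distance(rep(3, 10), m1), 0)
  # one-point data at kmin vs a spread-out model: D = 1 - pmf(kmin)
  m2 <- powerlaw_model(2.5, kmin = 2)
  expect_equal(ks_distance(rep(2, 7), m2), 1 - dpowerlaw(2, m2),
               tolerance = 1e-12)
  # brute force over the full enumerated support
  m3 <- powerlaw_model(2.2, kmin = 1, kmax = 10000)
  k <- pl_sample(400, 2.2, seed = 11, kmax = 10000)
  ks_all <- seq_len(10000)
  s <- findInterval(ks_all, sort(k)) / length(k)
  d_brute <- max(abs(s - ppowerlaw(ks_all, m3)))
  expect_equal(ks_distance(k, m3), d_brute, tolerance = 1e-12)
})

test_that("kmin selection minimizes D, recovers true kmin, finds splices", {
  k <- pl_sample(2000, 2.5, seed = 21)
  f <- fit_power_law(k)
  # argmin property: no scanned candidate beats the returned D
  expect_true(all(f$ks_D <= f$profile$ks_D + 1e-15))
  # pure power-law data with kmin = 1: recovery in >= 90% of replicates
  set.seed(77)
  hits <- vapply(1:40, function(i) {
    fit_power_law(sample(k, 2000, replace = TRUE))$kmin == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # uniform noise below 20 spliced with a power-law tail above
  set.seed(13)
  spliced <- c(sample(1:19, 3000, replace = TRUE),
               pl_sample(2000, 2.5, seed = 8, kmin = 20))
  fs <- fit_power_law(spliced)
  expect_lt(abs(fs$kmin - 20), 6)
  # degenerate input falls back with a warning
  expect_warning(f1 <- fit_power_law(rep(4, 50)), "distinct")
  expect_identical(f1$kmin, 4L)
})

test_that("truncated alternatives match a grid-search oracle", {
  k <- c(1, 1, 1, 2)
  fa <- fit_alternative(k, "poisson", kmin = 1)
  grid <- seq(0.01, 3, by = 1e-4)
  ll <- vapply(grid, function(lam) {
    sum(dpois(k, lam, log = TRUE)) -
      length(k) * ppois(0, lam, lower.tail = FALSE, log.p = TRUE)
  }, numeric(1))
  expect_equal(unname(fa$parameters["lambda"]), grid[which.max(ll)],
               tolerance = 1e-3)
  expect_equal(fa$loglik, max(ll), tolerance = 1e-6)

  # geometric-tailed data: the exponential family wins the likelihood
  set.seed(5)
  kg <- rgeom(2000, 0.3) + 1
  fe <- fit_alternative(kg, "exponential", kmin = 1)
  fp <- fit_power_law(kg, kmin = 1)
  expect_gt(fe$loglik, fp$loglik)

  # all-equal data: boundary handled with finite log-likelihood
  fd <- fit_alternative(rep(2, 30), "exponential", kmin = 2)
  expect_true(is.finite(fd$loglik))
})

test_that("Vuong test is antisymmetric with a fixed point at self", {
  k <- pl_sample(500, 2.5, seed = 31)
  f <- fit_power_law(k, kmin = 1)
  fp <- fit_alternative(k, "poisson", kmin = 1)
  self <- vuong_test(f, f, k)
  expect_equal(self$statistic, 0)
  expect_equal(self$pvalue, 1)
  expect_identical(self$favored, "undecided")
  ab <- vuong_test(f, fp, k)
  ba <- vuong_test(fp, f, k)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$pvalue, ba$pvalue)
})

test_that("Vuong favors the generating family on simulated data", {
  # Exponent 4.12 (the steepest observed in real GRNs): the pointwise
  # log-likelihood ratio against Poisson then has finite variance, the
  # premise of Vuong's normal approximation. At exponents <= 3 the ratio is
  # dominated by the largest degree and the test loses power even when the
  # evidence is overwhelming.
  set.seed(41)
  seeds <- sample.int(1e6, 40)
  res <- vapply(seeds, function(s) {
    k <- pl_sample(5000, 4.12, seed = s)
    f <- fit_power_law(k, kmin = 1)
    fp <- fit_alternative(k, "poisson", kmin = 1)
    vuong_test(f, fp, k)$favored == "power_law"
  }, logical(1))
  expect_gte(mean(res), 0.95)
  # and the reverse: geometric data against the exponential family
  res2 <- vapply(seeds[1:10], function(s) {
    set.seed(s)
    kg <- rgeom(5000, 0.4) + 1
    f <- suppressWarnings(fit_power_law(kg, kmin = 1))
    fe <- fit_alternative(kg, "exponential", kmin = 1)
    vuong_test(f, fe, kg)$favored == "alternative"
  }, logical(1))
  expect_gte(mean(res2), 0.95)
})

test_that("two-sample KS handles identity, separation and discrete ties", {
  a <- c(1, 1, 2, 3, 8)
  same <- two_sample_ks(a, a)
  expect_equal(same$D, 0)
  expect_equal(same$pvalue, 1)
  apart <- two_sample_ks(1:10, 100:110)
  expect_equal(apart$D, 1)
  expect_lt(apart$pvalue, 0.01)
  expect_true(same$ties)
  # tie-free data: agrees with stats::ks.test (independent implementation)
  set.seed(9)
  x <- rnorm(80)
  y <- rnorm(120, 0.3)
  ours <- two_sample_ks(x, y)
  ref <- stats::ks.test(x, y, exact = FALSE)
  expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$pvalue, ref$p.value, tolerance = 0.01)
})
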