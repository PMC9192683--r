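test_that("rarefied richness obeys its identities", {
  f <- toy_freq()
  expect_equal(rarefy_richness(f, f$T), f$S_obs)       # S(T) = S_obs
  expect_equal(rarefy_richness(f, 1), f$U / f$T)       # S(1) = U/T = 2
  expect_error(rarefy_richness(f, 5), "1 <= t <= T")

  set.seed(21)
  for (i in 1:10) {
    f <- random_freq(S = 25, T = 12)
    expect_equal(rarefy_richness(f, f$T), f$S_obs)
    expect_equal(rarefy_richness(f, 1), f$U / f$T)
    if (f$Q1 > 0)
      expect_true(all(diff(rarefy_richness(f, 1:f$T)) > 0))
  }
})

test_that("rarefaction equals the exhaustive subset oracle for T <= 8", {
  set.seed(31)
  for (T in c(4, 6, 8)) {
    m <- matrix(rbinom(10 * T, 1, 0.35), 10, T)
    if (all(rowSums(m) == 0)) m[1, 1] <- 1
    m <- m[rowSums(m) > 0, , drop = FALSE]
    f <- incidence_frequencies(m)
    for (t in 1:T) {
      subsets <- utils::combn(T, t)
      oracle <- mean(apply(subsets, 2, function(idx)
        sum(rowSums(m[, idx, drop = FALSE]) > 0)))
      expect_equal(rarefy_richness(f, t), oracle, tolerance = 1e-10)
    }
  }
})

test_that("extrapolated richness runs from S_obs to the Chao2 asymptote", {
  f <- toy_freq()
  expect_equal(extrapolate_richness(f, 0), f$S_obs)
  expect_equal(extrapolate_richness(f, 4), 4 + 1.5 * (1 - (1 - 2 / 8)^4))
  expect_equal(extrapolate_richness(f, 1e6), chao2_richness(f),
               tolerance = 1e-6)
  # no singletons: flat at S_obs
  f0 <- incfreq(c(3, 2), 4)
  expect_equal(extrapolate_richness(f0, c(0, 5, 100)), rep(2, 3))
})

test_that("size-based curves pass through the empirical value at t = T", {
  set.seed(41)
  for (i in 1:8) {
    f <- random_freq(S = 30, T = 10)
    for (q in c(0, 1, 2)) {
      cv <- re_curve(f, q, knots = 15)
      expect_equal(cv$estimate[cv$t == f$T], empirical_hill(f, q),
                   tolerance = 1e-9)
      expect_identical(cv$extrapolated, cv$t > f$T)
    }
  }
})

test_that("q = 2 curves asymptote within 2T while q = 0 curves keep climbing", {
  # heavy-tailed detection: many rare phenotypes, so richness is far from
  # its asymptote at 2T but Simpson diversity has levelled out
  set.seed(51)
  w <- random_world(S = 400, T = 12, meanlog = -4, sdlog = 1.5)
  rel_slope <- function(q) {
    v <- incidiv:::re_curve_at(w$f, q, c(2 * w$f$T - 1, 2 * w$f$T))
    (v[2] - v[1]) / v[2]
  }
  expect_lt(rel_slope(2), 0.01)
  expect_gt(rel_slope(0), 0.01)
})

test_that("expected coverage is monotone in t and anchored at the reference", {
  f <- toy_freq()
  expect_equal(coverage_at_size(f, f$T), sample_coverage(f))  # 0.8125
  set.seed(61)
  for (i in 1:10) {
    f <- random_freq(S = 25, T = 12)
    cv <- coverage_at_size(f, 1:(2 * f$T))
    expect_true(all(diff(cv) >= -1e-12))
    expect_equal(cv[f$T], sample_coverage(f), tolerance = 1e-12)
  }
  full <- incfreq(rep(5, 6), 5)
  expect_equal(coverage_at_size(full, c(1, 5, 10)), rep(1, 3))
})

test_that("C_max is the minimum doubled-size coverage across habitats", {
  f1 <- toy_freq()
  expect_equal(cmax(list(f1)), coverage_at_size(f1, 8))
  set.seed(71)
  f2 <- random_freq(S = 40, T = 20)
  expect_equal(cmax(list(a = f1, b = f2)),
               min(coverage_at_size(f1, 8), coverage_at_size(f2, 40)))
})

test_that("coverage standardization inverts the size-coverage relationship", {
  set.seed(81)
  for (i in 1:6) {
    f <- random_freq(S = 30, T = 12)
    # anchor: standardizing at the reference coverage returns empirical values
    for (q in c(0, 1, 2)) {
      st <- estimate_at_coverage(f, q, sample_coverage(f))
      expect_equal(st$estimate, empirical_hill(f, q), tolerance = 1e-9)
    }
    # consistency at integer sizes
    for (t in c(3, 7, 12, 18)) {
      ct <- coverage_at_size(f, t)
      if (t > 1 && ct > coverage_at_size(f, t - 1) + 1e-12) {
        st <- estimate_at_coverage(f, 0, ct)
        expect_equal(st$estimate, incidiv:::re_curve_at(f, 0, t),
                     tolerance = 1e-9)
      }
    }
    # rarefaction below the reference coverage lowers richness
    if (f$Q1 > 0) {
      lower <- estimate_at_coverage(f, 0, sample_coverage(f) * 0.97)
      expect_lte(lower$estimate, empirical_hill(f, 0) + 1e-9)
    }
  }
  f <- toy_freq()
  expect_error(estimate_at_coverage(f, 0, 0.9999), "refusing")
})

test_that("standardized comparisons are stable across sampling efforts", {
  # two habitats from one generating process but different T: standardized
  # Shannon estimates agree within the bootstrap interval width
  set.seed(91)
  p <- pmin(exp(rnorm(80, -2, 1)), 1)
  QA <- rbinom(80, 20, p); QB <- rbinom(80, 40, p)
  fA <- incfreq(QA[QA > 0], 20); fB <- incfreq(QB[QB > 0], 40)
  Cm <- cmax(list(fA, fB))
  dA <- estimate_at_coverage(fA, 1, Cm)$estimate
  dB <- estimate_at_coverage(fB, 1, Cm)$estimate
  bb <- incidence_bootstrap(fA, function(ff)
    estimate_at_coverage(ff, 1, min(Cm, coverage_at_size(ff, 2 * ff$T)))$estimate,
    B = 100, seed = 9)
  expect_lt(abs(dA - dB), bb$ci_high - bb$ci_low)
})

test_that("incidence bootstrap behaves like a bootstrap", {
  # degenerate assemblage: one phenotype in every unit -> zero-width interval
  f1 <- incfreq(5, 5)
  b1 <- incidence_bootstrap(f1, function(ff) empirical_hill(ff, 0),
                            B = 60, seed = 1)
  expect_equal(unname(b1$se), 0)

  # interval width shrinks with sampling effort
  set.seed(111)
  p <- pmin(exp(rnorm(60, -2, 1)), 1)
  widths <- vapply(c(8, 32, 128), function(T) {
    Q <- rbinom(60, T, p)
    f <- incfreq(Q[Q > 0], T)
    b <- incidence_bootstrap(f, function(ff) empirical_hill(ff, 1),
                             B = 150, seed = T)
    unname(b$ci_high - b$ci_low)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  # reproducible given seed
  f <- toy_freq()
  b2 <- incidence_bootstrap(f, function(ff) empirical_hill(ff, 1), B = 80, seed = 4)
  b3 <- incidence_bootstrap(f, function(ff) empirical_hill(ff, 1), B = 80, seed = 4)
  expect_identical(b2, b3)

  expect_error(incidence_bootstrap(f, identity, B = 10), "B must be >= 50")
})
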