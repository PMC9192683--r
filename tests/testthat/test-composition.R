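test_that("Bray-Curtis dissimilarities match hand arithmetic", {
  m <- cbind(s1 = c(1, 0), s2 = c(1, 0))
  expect_equal(as.numeric(bray_curtis(m, "none")), 0)          # identical
  m2 <- cbind(s1 = c(1, 0), s2 = c(0, 3))
  expect_equal(as.numeric(bray_curtis(m2, "sqrt")), 1)         # disjoint
  m3 <- cbind(s1 = c(4, 1), s2 = c(1, 1))
  expect_equal(as.numeric(bray_curtis(m3, "sqrt")), 0.2)       # (|2-1|)/(3+2)

  zz <- cbind(s1 = c(0, 0), s2 = c(0, 0), s3 = c(1, 2))
  expect_error(bray_curtis(zz, "none"), "all-zero")
})

test_that("presence transform equals set-based Sorensen dissimilarity", {
  set.seed(19)
  for (i in 1:15) {
    m <- matrix(rbinom(60, 1, 0.4), 12, 5)
    m[1, ] <- 1  # no all-zero samples
    d <- as.matrix(bray_curtis(m, "presence"))
    for (j in 1:4) for (k in (j + 1):5) {
      A <- which(m[, j] > 0); B <- which(m[, k] > 0)
      sorensen <- 2 * length(intersect(A, B)) / (length(A) + length(B))
      expect_equal(d[j, k], 1 - sorensen, tolerance = 1e-12)
    }
  }
})

test_that("one-way pseudo-F matches the textbook partition on a toy", {
  # 4 samples, 2 groups; partition computed by hand from the squared
  # dissimilarities: SS_T = sum d^2 / n, SS_W = per-group pair sums / n_g
  d <- stats::as.dist(matrix(c(0, .1, .8, .9,
                               .1, 0, .7, .85,
                               .8, .7, 0, .2,
                               .9, .85, .2, 0), 4, 4))
  g <- c("A", "A", "B", "B")
  ss_t <- (.1^2 + .8^2 + .9^2 + .7^2 + .85^2 + .2^2) / 4
  ss_w <- .1^2 / 2 + .2^2 / 2
  f_hand <- (ss_t - ss_w) / 1 / (ss_w / 2)
  r <- suppressWarnings(permanova(d, g, n_perm = 99, seed = 1))
  expect_equal(r$pseudo_F, f_hand, tolerance = 1e-12)
  expect_equal(r$df_between, 1)
  expect_equal(r$df_within, 2)
})

test_that("pseudo-F agrees with vegan::adonis2", {
  set.seed(23)
  m <- matrix(rpois(160, 4), 10, 16)
  d <- bray_curtis(m, "sqrt")
  g <- rep(c("A", "B"), each = 8)
  r <- permanova(d, g, n_perm = 199, seed = 2)
  a <- vegan::adonis2(d ~ g, permutations = 199)
  expect_equal(r$pseudo_F, a$F[1], tolerance = 1e-10)
})

test_that("fully separated clusters reach the minimal permutation p", {
  # between-group dissimilarity 1, within 0: no permutation beats observed F
  n <- 6
  dm <- matrix(1, 2 * n, 2 * n)
  dm[1:n, 1:n] <- 0; dm[(n + 1):(2 * n), (n + 1):(2 * n)] <- 0
  diag(dm) <- 0
  d <- stats::as.dist(dm)
  g <- rep(c("A", "B"), each = n)
  r <- permanova(d, g, n_perm = 99, seed = 3)
  expect_equal(r$p_perm, 1 / (99 + 1))
})

test_that("permanova p is invariant to relabeling and sample order", {
  set.seed(29)
  m <- matrix(rpois(140, 3), 10, 14)
  m[, 8:14] <- m[, 8:14] + rpois(70, 3)
  g <- rep(c("x", "y"), each = 7)
  d <- bray_curtis(m, "sqrt")
  r1 <- permanova(d, g, n_perm = 199, seed = 7)
  r2 <- permanova(d, ifelse(g == "x", "G1", "G2"), n_perm = 199, seed = 7)
  expect_equal(r1$p_perm, r2$p_perm)
  expect_equal(r1$pseudo_F, r2$pseudo_F)
})

test_that("tiny designs fall back to exact enumeration", {
  d <- stats::dist(matrix(rnorm(8), 4, 2))
  expect_warning(r <- permanova(d, c("A", "A", "B", "B"), n_perm = 999, seed = 1),
                 "exact enumeration")
  expect_true(r$exact)
  expect_equal(r$n_perm, 6)  # 4!/(2!2!) distinct arrangements
  expect_gte(r$p_perm, 1 / 6)
})

test_that("pairwise tests cover all group pairs", {
  set.seed(37)
  m <- matrix(rpois(120, 4), 10, 12)
  g <- rep(c("A", "B", "C"), each = 4)
  d <- bray_curtis(m, "sqrt")
  r <- suppressWarnings(permanova(d, g, n_perm = 99, seed = 5))
  expect_equal(nrow(r$pairwise), 3)
  expect_true(all(r$pairwise$p_perm >= 1 / 100))
})

test_that("dispersion check separates spread from location differences", {
  set.seed(43)
  # groups with identical dispersion but different centroids (one group's
  # mean profile is the other's reversed across exchangeable phenotypes):
  # the dispersion test should stay quiet
  g <- rep(c("A", "B"), each = 10)
  mu <- c(1, 2, 4, 8, 16, 32, 16, 8, 4, 2)
  ps <- replicate(10, {
    A <- matrix(rpois(100, rep(mu, 10)), 10, 10)
    B <- matrix(rpois(100, rep(rev(mu), 10)), 10, 10)
    d <- bray_curtis(cbind(A, B), "none", groups = g)
    suppressWarnings(
      dispersion_check(d, n_perm = 199, seed = sample.int(1e4, 1))$p_perm)
  })
  expect_gt(stats::median(ps), 0.3)

  # one group with much larger spread -> dispersion detected
  set.seed(47)
  hits <- replicate(20, {
    tight <- matrix(rpois(200, 20), 10, 20)
    loose <- matrix(rnbinom(200, mu = 20, size = 0.4), 10, 20)
    d <- bray_curtis(cbind(tight, loose), "none",
                     groups = rep(c("A", "B"), each = 20))
    dispersion_check(d, n_perm = 199, seed = sample.int(1e4, 1))$p_perm <= 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("nMDS recovers low-dimensional configurations", {
  set.seed(53)
  xy <- matrix(rnorm(24), 12, 2)
  d <- stats::dist(xy)
  fit <- nmds(d, dims = 2, restarts = 20, seed = 11)
  expect_lt(fit$stress, 0.05)

  # stress does not increase with an extra dimension
  set.seed(59)
  m <- matrix(rpois(96, 4), 8, 12)
  d2 <- bray_curtis(m, "sqrt")
  s2 <- nmds(d2, dims = 2, restarts = 20, seed = 13)$stress
  s3 <- nmds(d2, dims = 3, restarts = 20, seed = 13)$stress
  expect_lte(s3, s2 + 1e-6)

  # deterministic given seed
  f1 <- nmds(d2, dims = 2, restarts = 10, seed = 17)
  f2 <- nmds(d2, dims = 2, restarts = 10, seed = 17)
  expect_identical(f1, f2)

  expect_error(nmds(stats::dist(matrix(rnorm(6), 3, 2))), ">= 4 samples")
})

test_that("Venn partition performs exact set algebra", {
  v <- venn_partition(list(A = c("x", "y", "z"), B = c("u", "v", "w", "q")))
  expect_equal(v$shared_all, 0)
  expect_equal(unname(v$unique), c(3, 4))

  set.seed(61)
  for (i in 1:15) {
    pool <- paste0("p", 1:30)
    sets <- list(A = sample(pool, 12), B = sample(pool, 9), C = sample(pool, 15))
    v <- venn_partition(sets)
    # inclusion-exclusion identities
    expect_equal(v$union_total,
                 sum(v$totals) - sum(v$pairwise_shared) + v$shared_all)
    expect_equal(unname(v$pairwise_shared["A&B"]),
                 length(intersect(sets$A, sets$B)))
    expect_equal(unname(v$unique["A"]),
                 length(setdiff(sets$A, union(sets$B, sets$C))))
  }
})
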