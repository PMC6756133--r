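test_that("psychometric fits recover generating parameters", {
  x <- seq(-15, 0, by = 0.5)
  f <- fit_psychometric(x, psychometric_fun(x, -8, 1.5))
  expect_true(f$fit_ok)
  expect_equal(f$alpha, -8, tolerance = 1e-5)
  expect_equal(f$beta, 1.5, tolerance = 1e-5)
  expect_equal(psychometric_fun(f$alpha, f$alpha, f$beta), 0.5)
  expect_equal(f$slope_pct_per_db, 100 / (4 * 1.5), tolerance = 1e-4)
  # free guess/lapse mode recovers a floored and capped curve
  y <- psychometric_fun(x, -7, 1.2, guess = 0.05, lapse = 0.6)
  f4 <- fit_psychometric(x, y, fix_rates = FALSE)
  expect_equal(f4$alpha, -7, tolerance = 0.05)
  expect_equal(f4$lapse, 0.6, tolerance = 0.01)
  expect_error(fit_psychometric(c(-8, -6), c(0.4, 0.6), fix_rates = FALSE),
               "at least 4")
})

test_that("binomial psychometric fits are unbiased at the study scale", {
  fx <- read_behavioral_fixture()
  snrs <- -12:-3
  fits <- vapply(1:19, function(s) {
    sc <- gen_behavioral_scores(fx$alpha, fx$beta, snrs, n_words = 40,
                                seed = 1000 + s)
    f <- fit_psychometric(sc$snr, sc$proportion, n_trials = 40)
    c(f$alpha, f$slope_pct_per_db)
  }, numeric(2))
  expect_equal(mean(fits[1, ]), fx$alpha, tolerance = 0.3)
  expect_equal(mean(fits[2, ]), 100 / (4 * fx$beta), tolerance = 1)
})

test_that("1-D k-means binning is exact on small inputs", {
  grid <- c(-12.5, -10, -7.5, -5, -2.5, 0, 2.5)
  b <- bin_snrs(grid, 7)
  expect_equal(b$labels, 1:7)
  expect_equal(b$centers, grid)
  one <- bin_snrs(c(1, 3, 7, 9), 1)
  expect_equal(one$centers, 5)
  expect_error(bin_snrs(c(1, 1, 2), 3), "distinct")
  # objective matches the exact dynamic-programming optimum
  set.seed(21)
  for (i in 1:5) {
    x <- round(runif(15, -12, 3), 1)
    x <- unique(x)
    k <- 4
    b <- bin_snrs(x, k, seed = i)
    expect_equal(kmeans_objective(x, b$labels), oracle_kmeans_1d(x, k),
                 tolerance = 1e-9)
  }
  # deterministic under seed
  x <- rnorm(50)
  expect_identical(bin_snrs(x, 5, seed = 3), bin_snrs(x, 5, seed = 3))
})

test_that("dependent-correlation comparison is calibrated", {
  expect_equal(compare_dependent_correlations(0.4, 0.4, 0.3, 50)$p.value, 1)
  expect_error(compare_dependent_correlations(1, 0.4, 0.3, 50), "inside")
  expect_error(compare_dependent_correlations(0.5, 0.4, 0.3, 3), "at least 4")
  # p decreases monotonically as the correlations separate
  ps <- vapply(seq(0.35, 0.75, by = 0.1), function(rb)
    compare_dependent_correlations(0.3, rb, 0.2, 80)$p.value, 0)
  expect_true(all(diff(ps) < 0))
  # type-I error near nominal for overlapping correlations
  set.seed(7)
  rej <- mean(vapply(1:5000, function(i) {
    z <- matrix(rnorm(300), 100)
    y1 <- z[, 1] + z[, 2]
    y2 <- z[, 1] + z[, 3] # r(x, y1) == r(x, y2) under the null
    compare_dependent_correlations(cor(z[, 1], y1), cor(z[, 1], y2),
                                   cor(y1, y2), 100)$p.value < 0.05
  }, TRUE))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("paired sign-flip permutation tests with Holm adjustment", {
  set.seed(5)
  X <- matrix(rnorm(17 * 7), 17, 7)
  same <- paired_permutation_by_snr(X, X, n_perm = 1000, seed = 1)
  expect_true(all(same$p_adjusted == 1))
  # Holm adjustment properties: matches p.adjust, ordered, >= raw
  Y <- X + matrix(rnorm(17 * 7, mean = 0.4), 17, 7)
  pt <- paired_permutation_by_snr(X, Y, n_perm = 2000, seed = 2)
  expect_equal(pt$p_adjusted, p.adjust(pt$p_raw, method = "holm"))
  expect_true(all(pt$p_adjusted >= pt$p_raw))
  # invariant to subject ordering when exactly enumerated
  Xs <- matrix(rnorm(10 * 3), 10, 3)
  Ys <- Xs + matrix(rnorm(10 * 3, 0.5), 10, 3)
  p1 <- paired_permutation_by_snr(Xs, Ys, n_perm = 1024, seed = 3)
  ord <- sample(10)
  p2 <- paired_permutation_by_snr(Xs[ord, ], Ys[ord, ], n_perm = 1024,
                                  seed = 99)
  expect_true(p1$exact && p2$exact)
  expect_equal(p1$p_raw, p2$p_raw, tolerance = 1e-12)
  expect_error(paired_permutation_by_snr(X, X[, 1:3]), "paired")
  expect_error(paired_permutation_by_snr(X, X, n_perm = 10), "1000")
})

test_that("a one pooled-SD shift is detected reliably at n = 17", {
  set.seed(6)
  hits <- vapply(1:300, function(i) {
    x <- matrix(rnorm(17 * 3), 17, 3)
    y <- x
    y[, 2] <- y[, 2] + 1 # shift of one SD in a single bin
    pt <- paired_permutation_by_snr(x, y, n_perm = 1000, seed = i)
    pt$p_adjusted[2] < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.8)
})

test_that("Brown-Forsythe matches the direct formula and an external
           implementation", {
  g1 <- c(12.1, 14.3, 13.8, 15.2, 11.9)
  g2 <- c(22.5, 18.1, 25.4, 19.8, 30.2)
  bf <- brown_forsythe(list(g1, g2))
  # direct F on absolute deviations from medians
  z <- c(abs(g1 - median(g1)), abs(g2 - median(g2)))
  grp <- factor(rep(1:2, each = 5))
  a <- anova(lm(z ~ grp))
  expect_equal(bf$statistic, a$`F value`[1], tolerance = 1e-10)
  expect_equal(bf$p.value, a$`Pr(>F)`[1], tolerance = 1e-10)
  skip_if_not_installed("car")
  lv <- car::leveneTest(c(g1, g2), grp, center = median)
  expect_equal(bf$statistic, lv$`F value`[1], tolerance = 1e-10)
  # identical groups: zero statistic, p = 1
  same <- brown_forsythe(list(g1, g1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(brown_forsythe(list(g1)), "two groups")
})

test_that("Brown-Forsythe detects a 16-fold variance ratio", {
  set.seed(8)
  hits <- vapply(1:500, function(i)
    brown_forsythe(list(rnorm(20, sd = 1), rnorm(20, sd = 4)))$p.value <
      0.05, TRUE)
  expect_gt(mean(hits), 0.8)
})

test_that("cluster permutation finds no clusters in identical data and
           recovers injected differences", {
  set.seed(9)
  A <- array(rnorm(8 * 4 * 10), c(8, 4, 10))
  none <- cluster_permutation(A, A, n_perm = 1000, seed = 1)
  expect_equal(nrow(none$clusters), 0L)
  # injected right-frontal difference at 140-190 ms
  labs <- biosemi64_labels()
  adj <- channel_adjacency()
  lag_ms <- seq(0, 500, length.out = 65)
  target <- c("F2", "F4", "F6", "FC4", "FC2", "AF4")
  win <- lag_ms >= 140 & lag_ms <= 190
  ns <- 12
  A2 <- array(rnorm(ns * 64 * 65), c(ns, 64, 65))
  B2 <- array(rnorm(ns * 64 * 65), c(ns, 64, 65))
  A2[, labs %in% target, win] <- A2[, labs %in% target, win] + 1.5
  cr <- cluster_permutation(A2, B2, adjacency = adj, n_perm = 1000,
                            seed = 3, labels = labs, lag_ms = lag_ms)
  top <- cr$clusters[1, ]
  expect_lt(top$p, 0.05)
  expect_gt(length(intersect(top$channels[[1]], target)), 3)
  expect_lt(top$lag_low_ms, 190)
  expect_gt(top$lag_high_ms, 140)
  # determinism under seed and subject-order invariance (exact enumeration)
  cr2 <- cluster_permutation(A2, B2, adjacency = adj, n_perm = 1000,
                             seed = 3, labels = labs, lag_ms = lag_ms)
  expect_equal(cr$clusters$p, cr2$clusters$p)
  expect_error(cluster_permutation(A2[1:4, , ], B2[1:4, , ]), "5 subjects")
})

test_that("channel adjacency is symmetric and round-trips as an edge list", {
  adj <- channel_adjacency()
  expect_named(adj, biosemi64_labels())
  # symmetry: b in adj[a] <=> a in adj[b]
  for (a in names(adj)) for (b in adj[[a]])
    expect_true(a %in% adj[[b]])
  # immediate row neighbours are within 4 cm on the template
  expect_true("C1" %in% adj[["Cz"]])
  expect_true("FCz" %in% adj[["Cz"]])
  p <- tempfile(fileext = ".tsv")
  write_adjacency(adj, p)
  back <- read_adjacency(p)
  for (a in names(back))
    expect_setequal(back[[a]], adj[[a]])
})

test_that("an empty adjacency degenerates to per-channel lag clustering", {
  set.seed(10)
  ns <- 8
  A <- array(rnorm(ns * 3 * 20), c(ns, 3, 20))
  B <- A
  B[, 1, 5:9] <- B[, 1, 5:9] - 2
  B[, 3, 5:9] <- B[, 3, 5:9] - 2
  cr <- cluster_permutation(A, B, adjacency = NULL, n_perm = 500, seed = 2)
  sig <- cr$clusters[cr$clusters$p < 0.05, ]
  expect_gte(nrow(sig), 2L) # the two channels form separate clusters
  expect_true(all(vapply(sig$channels, length, 0L) == 1L))
})
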