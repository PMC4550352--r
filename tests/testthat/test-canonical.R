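test_that("Hellinger transformation yields unit-norm rows", {
  expect_equal(as.numeric(hellinger(rbind(c(1, 3)))), c(0.5, sqrt(0.75)))
  expect_equal(hellinger(rbind(c(1, 3)))[2], 0.86603, tolerance = 1e-5)
  # one-taxon community: all entries 1, and the transform is idempotent there
  one <- matrix(c(4, 9, 2), ncol = 1)
  expect_true(all(hellinger(one) == 1))
  expect_equal(hellinger(hellinger(one)), hellinger(one))
  # idempotence fails with >1 taxon
  y <- rbind(c(1, 3), c(2, 2))
  expect_false(isTRUE(all.equal(hellinger(hellinger(y)), hellinger(y))))

  set.seed(1)
  Y <- matrix(rpois(51 * 85, 3), 51, 85)
  H <- hellinger(Y)
  expect_equal(dim(H), c(51L, 85L))
  expect_lt(max(abs(rowSums(H^2) - 1)), 1e-12)

  bad <- rbind(c(1, 2), c(0, 0))
  rownames(bad) <- c("s1", "s2")
  expect_error(hellinger(bad), "'s2' has zero total abundance")
  expect_error(hellinger(rbind(c(-1, 2))), "negative")
})

test_that("rda_fit matches a least-squares oracle and the Ezekiel formula", {
  set.seed(10)
  n <- 20
  X <- matrix(rnorm(n * 3), n)
  # exact linear response
  Y <- X %*% matrix(rnorm(9), 3)
  expect_equal(rda_fit(Y, X)$r2, 1, tolerance = 1e-10)

  # predictors orthogonal to the centred response
  Yc <- scale(matrix(rnorm(n * 2), n), scale = FALSE)
  Xo <- qr.resid(qr(cbind(1, Yc)), matrix(rnorm(n * 2), n))
  f0 <- rda_fit(Yc, Xo)
  expect_equal(f0$r2, 0, tolerance = 1e-10)
  expect_lte(f0$adj_r2, 0)

  # normal-equations oracle on a random problem
  Y <- matrix(rnorm(n * 5), n)
  fit <- rda_fit(Y, X)
  Ycen <- scale(Y, scale = FALSE)
  Xs <- cbind(1, scale(X))
  B <- solve(crossprod(Xs), crossprod(Xs, Ycen))
  res <- Ycen - Xs %*% B
  r2_oracle <- 1 - sum(res^2) / sum(Ycen^2)
  expect_equal(fit$r2, r2_oracle, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1 - (1 - r2_oracle) * (n - 1) / (n - 3 - 1), tolerance = 1e-10)

  # printed-precision arithmetic: n = 51, m = 1, r2 = 0.5
  expect_equal(round(1 - (1 - 0.5) * 50 / 49, 5), 0.4898)
  expect_equal(dendropart:::adj_r2(0.5, 51, 1), 0.489796, tolerance = 1e-6)

  # vegan cross-check of R2 and adjusted R2
  vr <- vegan::RsquareAdj(vegan::rda(Ycen ~ ., data = as.data.frame(X)))
  expect_equal(fit$r2, vr$r.squared, tolerance = 1e-10)
  expect_equal(fit$adj_r2, vr$adj.r.squared, tolerance = 1e-10)
})

test_that("rda_fit prunes collinear predictors and rejects saturated models", {
  set.seed(2)
  n <- 15
  Y <- matrix(rnorm(n * 3), n)
  X <- matrix(rnorm(n * 2), n)
  Xdup <- cbind(X, X[, 1] * 2 - X[, 2])
  expect_warning(fit <- rda_fit(Y, Xdup), "collinear")
  expect_equal(fit$rank, 2L)
  expect_equal(fit$r2, suppressWarnings(rda_fit(Y, X)$r2), tolerance = 1e-12)
  expect_error(rda_fit(Y, matrix(rnorm(n * (n - 1)), n)), "saturated")
})

test_that("rda_fit R2 is invariant to invertible mixing of predictors", {
  set.seed(30)
  n <- 25
  Y <- matrix(rnorm(n * 4), n)
  X <- matrix(rnorm(n * 3), n)
  base <- rda_fit(Y, X)$r2
  for (rep in 1:10) {
    M <- matrix(rnorm(9), 3)
    while (abs(det(M)) < 1e-3) M <- matrix(rnorm(9), 3)
    expect_equal(rda_fit(Y, X %*% M)$r2, base, tolerance = 1e-8)
  }
})

test_that("permutation test is seeded, bounded below, and calibrated", {
  set.seed(4)
  n <- 30
  X <- matrix(rnorm(n * 2), n)
  Y <- X %*% matrix(rnorm(6), 2) + 0.01 * matrix(rnorm(n * 3), n)
  p1 <- permutation_test(Y, X, n_perm = 999, seed = 7)
  expect_equal(p1$p_value, 0.001)  # (1)/(1+999): minimum attainable
  p2 <- permutation_test(Y, X, n_perm = 999, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$statistic, p2$statistic)

  # pseudo-F definition check against the fit components
  fit <- p1$fit
  expect_equal(p1$statistic,
               (fit$ss_explained / fit$rank) /
                 ((sum(fit$Yw^2) - fit$ss_explained) / (n - fit$rank - 1)))
})

test_that("tiny samples switch to exact enumeration and are order-invariant", {
  set.seed(8)
  n <- 6
  Y <- matrix(rnorm(n * 2), n)
  X <- matrix(rnorm(n), n)
  expect_warning(p1 <- permutation_test(Y, X, n_perm = 999, seed = 1),
                 "enumerating exactly")
  expect_true(p1$exact)
  # joint row permutation of (Y, X) leaves the exact p unchanged
  ix <- sample(n)
  expect_warning(p2 <- permutation_test(Y[ix, ], X[ix, , drop = FALSE],
                                        n_perm = 999, seed = 99))
  expect_equal(p1$p_value, p2$p_value)
})

test_that("forward selection keeps true drivers and refuses duplicates", {
  set.seed(12)
  n <- 40
  cand <- qr.Q(qr(matrix(rnorm(n * 8), n)))
  colnames(cand) <- paste0("c", 1:8)
  Y <- cand[, 3] %*% t(rnorm(5)) + 0.1 * matrix(rnorm(n * 5), n)
  fs <- forward_select(Y, cand, n_perm = 199, seed = 3)
  expect_true("c3" %in% fs$selected)
  expect_equal(fs$selected[1], "c3")
  expect_lt(abs(fs$steps$cum_adj_r2[nrow(fs$steps)] - fs$global_adj_r2), 0.1)

  # a duplicated column of a selected candidate adds nothing and is never taken
  cand2 <- cbind(cand, c3dup = cand[, 3])
  fs2 <- suppressWarnings(forward_select(Y, cand2, n_perm = 199, seed = 3))
  expect_false("c3dup" %in% fs2$selected && "c3" %in% fs2$selected)
})

test_that("jackknife richness follows the first-order formula", {
  # every taxon in every sample: no singletons, estimate = observed
  allin <- matrix(1, 4, 7)
  expect_equal(jackknife1_richness(allin), 7)
  # S_obs = 10, f1 = 4, m = 5 -> 13.2
  inc <- matrix(0, 5, 10)
  inc[, 1:6] <- 1                       # 6 taxa everywhere
  for (k in 1:4) inc[k, 6 + k] <- 1     # 4 singletons
  expect_equal(jackknife1_richness(inc), 13.2)
  expect_equal(jackknife1_richness(inc),
               unname(vegan::specpool(inc)$jack1))
  expect_error(jackknife1_richness(matrix(1, 1, 3)), "at least 2 samples")
})

test_that("five replicate samples recover most of a site's richness", {
  # Surber-like subsampling of synthetic site abundance vectors: the
  # observed richness should reach at least ~60% of the jackknife estimate
  sim <- generate_dataset(simulation_scenario(), seed = 77)
  set.seed(77)
  ratios <- apply(sim$community, 1, function(ab) {
    draws <- t(rmultinom(5, size = max(20, round(sum(ab) / 5)), prob = ab + 1e-9))
    sum(colSums(draws > 0) > 0) / jackknife1_richness(draws)
  })
  expect_gte(mean(ratios), 0.6)
})
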