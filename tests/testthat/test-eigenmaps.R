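test_that("Moran's I distinguishes gradients from checkerboards", {
  n <- 10
  W <- matrix(0, n, n)
  for (i in 1:(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  expect_lt(morans_i(rep(c(-1, 1), 5), W), 0)
  expect_gt(morans_i(1:n, W), 0)
  expect_error(morans_i(rep(1, n), W), "constant")

  # naive double-sum oracle
  set.seed(3)
  for (rep in 1:20) {
    v <- rnorm(n); Wr <- matrix(runif(n * n), n); Wr <- Wr + t(Wr); diag(Wr) <- 0
    vc <- v - mean(v)
    num <- 0
    for (i in 1:n) for (j in 1:n) num <- num + Wr[i, j] * vc[i] * vc[j]
    oracle <- (n / sum(Wr)) * num / sum(vc^2)
    expect_equal(morans_i(v, Wr), oracle, tolerance = 1e-12)
  }
})

test_that("MEM of a transect is a sinusoid family", {
  x <- 0:9 * 100
  mem <- mem_eigenfunctions(as.matrix(dist(cbind(x, 0))))
  s <- x / max(x)
  cosim <- function(a, b) abs(sum(a * (b - mean(b)))) /
    sqrt(sum(a^2) * sum((b - mean(b))^2))
  for (k in seq_len(ncol(mem$basis))) {
    # axis k changes sign exactly k times and matches a sinusoid template
    expect_equal(sum(diff(sign(mem$basis[, k])) != 0), k)
    best <- 0
    for (f in seq(0.5, 6, by = 0.05)) for (ph in seq(0, pi, by = 0.15))
      best <- max(best, cosim(mem$basis[, k], cos(2 * pi * f * s + ph)))
    expect_gt(best, 0.95)
  }
})

test_that("MEM eigenvectors are orthonormal, centred, and oracle-consistent", {
  set.seed(21)
  xy <- matrix(runif(40) * 1000, 20, 2)
  D <- as.matrix(dist(xy))
  mem <- mem_eigenfunctions(D)
  B <- mem$basis
  expect_lt(max(abs(crossprod(B) - diag(ncol(B)))), 1e-8)
  expect_lt(max(abs(colSums(B))), 1e-8)
  expect_true(all(diff(mem$eigenvalues) <= 1e-9))

  # dense symmetric-eigendecomposition oracle: same positive count and pairs
  t <- mem$truncation
  Ds <- D; Ds[Ds > t] <- 4 * t
  A <- -0.5 * Ds^2
  H <- diag(20) - matrix(1 / 20, 20, 20)
  e <- eigen(H %*% A %*% H, symmetric = TRUE)
  pos <- e$values > 1e-10 * max(e$values)
  expect_equal(ncol(B), sum(pos))
  expect_equal(mem$eigenvalues, e$values[pos], tolerance = 1e-8)
  for (k in seq_len(ncol(B)))
    expect_equal(abs(sum(B[, k] * e$vectors[, k])), 1, tolerance = 1e-8)

  # vegan cross-check
  pc <- vegan::pcnm(dist(xy))
  expect_equal(ncol(B), ncol(pc$vectors))
  expect_equal(mem$eigenvalues, unname(pc$values[seq_len(ncol(B))]), tolerance = 1e-8)

  # too-small truncation disconnects the graph
  expect_error(mem_eigenfunctions(D, truncation = min(D[D > 0]) * 0.9),
               "disconnected")
})

test_that("MEM is invariant to site relabelling", {
  set.seed(5)
  xy <- matrix(runif(30) * 500, 15, 2)
  D <- as.matrix(dist(xy))
  dimnames(D) <- list(paste0("s", 1:15), paste0("s", 1:15))
  m1 <- mem_eigenfunctions(D)
  for (rep in 1:5) {
    p <- sample(15)
    m2 <- mem_eigenfunctions(D[p, p])
    expect_equal(m2$eigenvalues, m1$eigenvalues, tolerance = 1e-8)
    # compare spanned subspaces after aligning rows
    B1 <- m1$basis[rownames(m2$basis), ]
    proj <- B1 %*% solve(crossprod(B1), crossprod(B1, m2$basis))
    expect_lt(max(abs(proj - m2$basis)), 1e-8)
  }
})

test_that("MEM on overland and watercourse distances coincide on a straight chain", {
  net <- make_chain(8, seg_len = rep(120, 7))
  ov <- overland_distance_matrix(net)
  wc <- watercourse_distance_matrix(net)
  expect_equal(unclass(ov), unclass(wc), ignore_attr = TRUE, tolerance = 1e-12)
  m1 <- mem_eigenfunctions(ov); m2 <- mem_eigenfunctions(wc)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-10)
})

test_that("AEM edge weights follow 1 - (d/dmax)^alpha with an epsilon floor", {
  expect_equal(aem_edge_weights(c(25, 100), alpha = 1)[1], 0.75)
  expect_equal(aem_edge_weights(c(0, 10))[1], 1)
  expect_equal(aem_edge_weights(c(50, 100))[2], 1e-6)  # floor, not severed
  w <- aem_edge_weights(rep(7, 5))
  expect_true(all(w == w[1]))
  expect_error(aem_edge_weights(c(-1, 5)), "negative")
})

test_that("AEM of a chain has lower-triangular incidence and a monotone first axis", {
  net <- make_chain(4)
  E <- dendropart:::aem_incidence(net)
  expect_equal(dim(E), c(4L, 4L))  # 3 segments + 1 origin edge
  # reorder columns upstream-first: origin, e1, e2, e3
  Eo <- E[, c("origin_n1", "e1", "e2", "e3")]
  expect_equal(unname(Eo), lower.tri(diag(4), diag = TRUE) * 1)

  aem <- aem_eigenfunctions(net)
  b1 <- aem$basis[, 1]
  expect_true(all(diff(b1) > 0) || all(diff(b1) < 0))
  # explicit SVD of the printed incidence matrix
  s <- svd(scale(Eo, center = TRUE, scale = FALSE))
  expect_equal(abs(sum(aem$basis[, 1] * s$u[, 1])), 1, tolerance = 1e-10)

  # the monotone axis is positively autocorrelated and always retained
  f <- positive_eigenfunction_filter(aem)
  expect_gt(f$morans_i[1], 0)
  expect_gte(ncol(f$basis), 1)
})

test_that("AEM separates sibling branches and respects the rank bound", {
  y <- make_y()
  E <- dendropart:::aem_incidence(y)
  # sibling headwaters draw on disjoint edge sets (their own origin edges);
  # only the confluence site below collects both branches
  expect_equal(sum(E["A", ] * E["B", ]), 0)
  expect_true(all(E["C", c("sA", "sB", "sC")] == 1))

  for (seed in 1:10) {
    net <- random_tree_net(sample(5:20, 1), seed = 300 + seed)
    aem <- aem_eigenfunctions(net)
    n <- sum(net$nodes$is_site)
    expect_lte(ncol(aem$basis), min(n - 1, ncol(dendropart:::aem_incidence(net))))
  }
})

test_that("AEM spans the same subspace under edge reordering", {
  net <- random_tree_net(12, seed = 77)
  a1 <- aem_eigenfunctions(net)
  p <- sample(nrow(net$segments))
  net2 <- build_network(net$nodes[c("node_id", "x", "y", "elevation", "is_site")],
                        net$segments[p, ])
  a2 <- aem_eigenfunctions(net2)
  B1 <- a1$basis[rownames(a2$basis), ]
  proj <- B1 %*% solve(crossprod(B1), crossprod(B1, a2$basis))
  expect_lt(max(abs(proj - a2$basis)), 1e-8)
})

test_that("positive filter empties sets without spatial structure", {
  fake <- structure(list(basis = matrix(rnorm(20), 10, 2),
                         eigenvalues = c(-0.5, -1), morans_i = c(-0.5, -0.6),
                         construction = "MEM", dist_type = "overland_geo"),
                    class = "eigenfunctions")
  out <- positive_eigenfunction_filter(fake)
  expect_equal(ncol(out$basis), 0)
  expect_true(isTRUE(attr(out, "no_spatial_structure")))
})
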