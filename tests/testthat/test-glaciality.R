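test_that("min-max scaling maps columns onto [0, 1]", {
  expect_equal(as.numeric(minmax_scale(cbind(c(2, 4, 6)))), c(0, 0.5, 1))
  x <- cbind(a = c(0, 0.3, 1))
  expect_equal(minmax_scale(x), x)
  expect_error(minmax_scale(cbind(ok = 1:3, bad = c(2, 2, 2))), "constant column 'bad'")
})

test_that("non-centred PCA decomposes without centring", {
  # rank-1: axis-1 scores proportional to the single column
  x <- cbind(c(1, 4, 2, 7))
  fit <- noncentred_pca(x)
  expect_equal(abs(cor(fit$scores[, 1], x[, 1])), 1)

  # orthogonal equal-norm columns: equal eigenvalues
  x <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(diff(noncentred_pca(x)$eigenvalues), 0, tolerance = 1e-12)

  # reconstruction and axis-1 optimality (grid oracle in m = 2)
  set.seed(42)
  x <- matrix(runif(20), 10, 2)
  fit <- noncentred_pca(x)
  expect_lt(max(abs(x - fit$scores %*% t(fit$loadings))), 1e-10)
  ss <- function(v) sum((x %*% v)^2)
  thetas <- seq(0, pi, length.out = 20001)
  best <- thetas[which.max(vapply(thetas, function(t) ss(c(cos(t), sin(t))), 0))]
  expect_gt(abs(sum(fit$loadings[, 1] * c(cos(best), sin(best)))), 1 - 1e-5)
  expect_equal(fit$eigenvalues[1], ss(fit$loadings[, 1]) / nrow(x))

  expect_error(noncentred_pca(cbind(c(1, NA))), "non-finite")
})

test_that("glaciality index is highest at the harshest site and recovers a latent gradient", {
  # site 1 takes the columnwise minima of all four scaled variables
  env <- data.frame(temperature = c(1, 6, 9), conductivity = c(20, 90, 160),
                    turbidity = c(200, 40, 5), pfankuch = c(40, 25, 14))
  gi <- glaciality_index(env)
  expect_equal(which.max(gi), 1L)
  expect_equal(min(gi), 0)

  # identical sites: constant columns error
  env_const <- data.frame(temperature = c(5, 5), conductivity = c(50, 50),
                          turbidity = c(10, 10), pfankuch = c(20, 20))
  expect_error(glaciality_index(env_const), "constant column")

  # noiseless monotone latent gradient: perfect rank recovery
  g <- runif(30)
  gi <- glaciality_index(env_from_g(g, noise = 0))
  expect_equal(cor(as.numeric(gi), g, method = "spearman"), 1)
})

test_that("glaciality index is invariant to units of the raw variables", {
  set.seed(9)
  g <- runif(25)
  env <- env_from_g(g, noise = 0.1, seed = 2)
  base <- as.numeric(glaciality_index(env))
  for (rep in 1:10) {
    env2 <- env
    # temperature/conductivity: positive affine; turbidity/pfankuch enter as
    # reciprocals, so unit changes are multiplicative
    env2$temperature <- env$temperature * runif(1, 0.1, 10) + runif(1, -1, 5)
    env2$conductivity <- env$conductivity * runif(1, 0.1, 10)
    env2$turbidity <- env$turbidity * runif(1, 0.1, 10)
    env2$pfankuch <- env$pfankuch * runif(1, 0.1, 10)
    expect_equal(as.numeric(glaciality_index(env2)), base, tolerance = 1e-9)
  }
})

test_that("segment attribution follows the upstream-else-downstream rule", {
  # chain A (0.9) -> B (0.5): the segment carries the upstream value
  net <- make_chain(2)
  net <- assign_segment_glaciality(net, c(n1 = 0.9, n2 = 0.5))
  expect_equal(net$segments$glaciality, 0.9)

  # Y network: segments below the sites carry their site; the segment
  # below the (site-less) junction carries the downstream site's value
  y <- make_y()
  y <- assign_segment_glaciality(y, c(A = 0.8, B = 0.2, C = 0.4))
  g <- setNames(y$segments$glaciality, y$segments$segment_id)
  expect_equal(unname(g[c("sA", "sB", "sC")]), c(0.8, 0.2, 0.4))

  # idempotent, full coverage
  y2 <- assign_segment_glaciality(y, c(A = 0.8, B = 0.2, C = 0.4))
  expect_identical(y2$segments$glaciality, y$segments$glaciality)
  expect_false(anyNA(y$segments$glaciality))

  # a barren branch with no site upstream or downstream errors
  nodes <- data.frame(node_id = c("A", "s", "j", "o"),
                      x = c(-1, 1, 0, 0), y = c(2, 2, 1, 0),
                      elevation = c(4200, 4100, 4000, 3900),
                      is_site = c(TRUE, FALSE, FALSE, FALSE))
  segs <- data.frame(segment_id = c("eA", "eS", "eJ"),
                     up_node = c("A", "s", "j"), down_node = c("j", "j", "o"),
                     length = 100)
  bad <- build_network(nodes, segs)
  expect_error(assign_segment_glaciality(bad, c(A = 0.5)),
               "no site upstream on its branch nor downstream")
})

test_that("glaciality distances scan path segments plus endpoints", {
  net <- make_chain(4)
  idx <- c(n1 = 0.85, n2 = 0.5, n3 = 0.3, n4 = 0.2)
  net <- assign_segment_glaciality(net, idx)
  expect_equal(net$segments$glaciality, c(0.85, 0.5, 0.3))
  d <- glaciality_distance_matrix(net, idx)
  # endpoints 0.85 and 0.2; segments 0.85, 0.5, 0.3 -> 0.85 - 0.2
  expect_equal(d["n1", "n4"], 0.65)
  expect_true(all(d >= abs(outer(idx, idx, "-")) - 1e-12))

  # adjacent equal-glaciality sites: zero distance
  net2 <- make_chain(2)
  net2 <- assign_segment_glaciality(net2, c(n1 = 0.4, n2 = 0.4))
  expect_equal(glaciality_distance_matrix(net2, c(n1 = 0.4, n2 = 0.4))["n1", "n2"], 0)

  expect_error(glaciality_distance_matrix(make_chain(3), idx), "not fully attributed")

  # random attributed tree vs an igraph path-enumeration oracle
  skip_if_not_installed("igraph")
  for (seed in 1:20) {
    net <- random_tree_net(sample(6:20, 1), seed = 1200 + seed)
    set.seed(seed)
    idx <- setNames(runif(nrow(net$nodes)), net$nodes$node_id)
    net <- assign_segment_glaciality(net, idx)
    d <- glaciality_distance_matrix(net, idx)
    g <- as_igraph(net)
    ids <- rownames(d)
    segg <- setNames(net$segments$glaciality, net$segments$segment_id)
    igraph::E(g)$segment_id <- net$segments$segment_id
    for (rep in 1:5) {
      ij <- sample(ids, 2)
      ep <- igraph::shortest_paths(g, ij[1], ij[2], output = "epath")$epath[[1]]
      vals <- c(segg[igraph::E(g)$segment_id[as.integer(ep)]], idx[ij])
      expect_equal(d[ij[1], ij[2]], max(vals) - min(vals))
    }
  }
})
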