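# Small network builders used across tests. All coordinates are planar
# metres; elevations strictly decrease downstream unless stated.

# Linear chain: node 1 most upstream, node n the outlet.
make_chain <- function(n, seg_len = rep(100, n - 1), elevations = NULL,
                       sites = rep(TRUE, n)) {
  if (is.null(elevations)) elevations <- seq(4000 + 10 * (n - 1), 4000, by = -10)
  y <- rev(cumsum(c(0, seg_len)))
  nodes <- data.frame(node_id = paste0("n", seq_len(n)), x = 0, y = y,
                      elevation = elevations, is_site = sites)
  segs <- data.frame(segment_id = paste0("e", seq_len(n - 1)),
                     up_node = paste0("n", seq_len(n - 1)),
                     down_node = paste0("n", 2:n),
                     length = seg_len)
  build_network(nodes, segs)
}

# Y-shaped network: headwater sites A and B join at junction j (not a
# site), then one segment down to outlet site C.
make_y <- function(len_a = 200, len_b = 300, len_c = 150,
                   elev = c(A = 4200, B = 4200, j = 4000, C = 3900),
                   junction_site = FALSE) {
  nodes <- data.frame(node_id = c("A", "B", "j", "C"),
                      x = c(-100, 100, 0, 0), y = c(200, 200, 0, -150),
                      elevation = unname(elev),
                      is_site = c(TRUE, TRUE, junction_site, TRUE))
  segs <- data.frame(segment_id = c("sA", "sB", "sC"),
                     up_node = c("A", "B", "j"), down_node = c("j", "j", "C"),
                     length = c(len_a, len_b, len_c))
  build_network(nodes, segs)
}

# Random rooted tree on n nodes (node 1 = outlet), every node a site.
# Segment lengths exceed the straight-line separation of their endpoints,
# as in any planar channel.
random_tree_net <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
  elev <- numeric(n); elev[1] <- 3900
  for (i in 2:n) elev[i] <- elev[parent[i]] + runif(1, 1, 50)
  euclid <- sqrt((x[-1] - x[parent[-1]])^2 + (y[-1] - y[parent[-1]])^2)
  nodes <- data.frame(node_id = paste0("n", 1:n), x = x, y = y,
                      elevation = elev, is_site = TRUE)
  segs <- data.frame(segment_id = paste0("e", 2:n),
                     up_node = paste0("n", 2:n),
                     down_node = paste0("n", parent[-1]),
                     length = euclid * runif(n - 1, 1.01, 1.4))
  build_network(nodes, segs)
}

# igraph twin of a stream_network, undirected with length weights.
as_igraph <- function(net, directed = FALSE) {
  igraph::graph_from_data_frame(
    data.frame(from = net$segments$up_node, to = net$segments$down_node,
               weight = net$segments$length),
    directed = directed,
    vertices = data.frame(name = net$nodes$node_id))
}

# Quick environment table with a clean monotone glaciality signal.
env_from_g <- function(g, noise = 0, seed = 1) {
  set.seed(seed)
  ln <- function() exp(rnorm(length(g), 0, noise))
  data.frame(site_id = names(g) %||% paste0("s", seq_along(g)),
             temperature = (1.5 + 8.5 * (1 - g)) * ln(),
             conductivity = (15 + 165 * (1 - g)) * ln(),
             turbidity = (2 + 198 * g) * ln(),
             pfankuch = (12 + 28 * g) * ln(),
             width = runif(length(g), 1, 5), depth = runif(length(g), .1, .5),
             slope = runif(length(g), .01, .2), ph = rnorm(length(g), 7.8, .2),
             epilithic_algae = runif(length(g), 1, 10),
             benthic_om = runif(length(g), .5, 5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small scenario for fast pipeline tests.
small_scenario <- function(...) {
  simulation_scenario(n_sites = 30, n_taxa = 40, n_flying = 30,
                      n_first_order = 14, n_headwaters = 5,
                      n_glacial_sources = 2, ...)
}
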