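#' Build a dendritic stream network
#'
#' Validates node and segment tables and assembles them into a rooted
#' `stream_network`: a tree (or forest) whose segments point downstream.
#' Flow direction is encoded by the segment table (`up_node` -> `down_node`);
#' each node may have at most one downstream segment.
#'
#' @param nodes data frame with columns `node_id`, `x`, `y` (planar projected
#'   metres), `elevation` (m), `is_site` (logical/0-1) and optionally
#'   `site_class` (`"first_order"`, `"mainstem"` or `NA` to auto-assign).
#' @param segments data frame with columns `segment_id`, `up_node`,
#'   `down_node`, `length` (m, > 0) and optionally `glaciality`.
#' @param elevation_check what to do when a segment runs uphill
#'   (upstream node lower than its downstream node): `"warn"` (default) or
#'   `"error"`.
#'
#' @details Site classes are auto-assigned from Strahler order computed on the
#'   segment tree: sites on order-1 (headwater) channels are `first_order`,
#'   all others `mainstem`. A non-`NA` `site_class` in the input table
#'   overrides the computed class for that site.
#'
#' @return An object of class `stream_network`: list with elements `nodes`,
#'   `segments`, `outlets` (root node of each connected component), and
#'   index vectors used internally for path queries.
#' @export
build_network <- function(nodes, segments, elevation_check = c("warn", "error")) {
  elevation_check <- match.arg(elevation_check)
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  need_n <- c("node_id", "x", "y", "elevation", "is_site")
  if (!all(need_n %in% names(nodes)))
    stopf("nodes table must have columns: %s", paste(need_n, collapse = ", "))
  need_s <- c("segment_id", "up_node", "down_node", "length")
  if (!all(need_s %in% names(segments)))
    stopf("segments table must have columns: %s", paste(need_s, collapse = ", "))
  nodes$node_id <- as.character(nodes$node_id)
  segments$segment_id <- as.character(segments$segment_id)
  segments$up_node <- as.character(segments$up_node)
  segments$down_node <- as.character(segments$down_node)
  if (anyDuplicated(nodes$node_id))
    stopf("duplicated node_id: %s", nodes$node_id[duplicated(nodes$node_id)][1])
  if (anyDuplicated(segments$segment_id))
    stopf("duplicated segment_id: %s", segments$segment_id[duplicated(segments$segment_id)][1])
  bad <- setdiff(c(segments$up_node, segments$down_node), nodes$node_id)
  if (length(bad))
    stopf("orphan segment: node '%s' not in node table", bad[1])
  if (any(segments$length <= 0))
    stopf("segment '%s' has non-positive length",
          segments$segment_id[segments$length <= 0][1])
  nodes$is_site <- as.logical(nodes$is_site)

  n <- nrow(nodes)
  idx <- seq_len(n)
  names(idx) <- nodes$node_id
  up <- idx[segments$up_node]
  down <- idx[segments$down_node]

  # each node has <= 1 downstream segment
  if (anyDuplicated(up)) {
    dup <- nodes$node_id[up[duplicated(up)][1]]
    stopf("multiple downstream segments from node '%s'", dup)
  }
  parent <- rep(NA_integer_, n)      # downstream neighbour
  parent_seg <- rep(NA_integer_, n)  # segment to downstream neighbour
  parent[up] <- down
  parent_seg[up] <- seq_len(nrow(segments))

  # cycle / forest check: follow parents; depth must terminate
  depth <- rep(NA_integer_, n)
  root <- rep(NA_integer_, n)
  for (i in idx) {
    chain <- i
    j <- i
    while (!is.na(parent[j]) && is.na(depth[j])) {
      j <- parent[j]
      if (j %in% chain) stopf("cycle detected involving node '%s'", nodes$node_id[j])
      chain <- c(chain, j)
    }
    base_d <- if (is.na(depth[j])) 0L else depth[j]
    base_r <- if (is.na(root[j])) j else root[j]
    k <- length(chain)
    depth[chain] <- base_d + rev(seq_len(k)) - 1L
    root[chain] <- base_r
  }
  n_comp <- length(unique(root))
  if (nrow(segments) != n - n_comp)
    stopf("segment count (%d) != node count - components (%d)", nrow(segments), n - n_comp)

  uphill <- nodes$elevation[up] < nodes$elevation[down]
  if (any(uphill)) {
    msg <- sprintf("segment '%s' runs uphill (upstream node lower than downstream)",
                   segments$segment_id[uphill][1])
    if (elevation_check == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  net <- structure(list(
    nodes = nodes, segments = segments,
    idx = idx, parent = parent, parent_seg = parent_seg,
    depth = depth, root = root,
    outlets = nodes$node_id[unique(root)]
  ), class = "stream_network")
  net$nodes$strahler <- strahler_order(net)
  net <- assign_site_classes(net)
  net
}

# Strahler order of each node: sources are 1; at a confluence the order is
# the max of tributary orders, +1 when the max is attained more than once.
strahler_order <- function(net) {
  n <- nrow(net$nodes)
  children <- split(seq_len(n)[!is.na(net$parent)], net$parent[!is.na(net$parent)])
  ord <- rep(NA_integer_, n)
  o <- order(net$depth, decreasing = TRUE)  # deepest (most upstream) first
  for (i in o) {
    kids <- children[[as.character(i)]]
    if (is.null(kids) || !length(kids)) ord[i] <- 1L
    else {
      ko <- ord[kids]
      m <- max(ko)
      ord[i] <- if (sum(ko == m) > 1L) m + 1L else m
    }
  }
  ord
}

assign_site_classes <- function(net) {
  cls <- if ("site_class" %in% names(net$nodes)) as.character(net$nodes$site_class)
         else rep(NA_character_, nrow(net$nodes))
  auto <- ifelse(net$nodes$strahler == 1L, "first_order", "mainstem")
  cls[is.na(cls) | cls == "" | cls == "none"] <- auto[is.na(cls) | cls == "" | cls == "none"]
  cls[!net$nodes$is_site] <- "none"
  bad <- !cls %in% c("first_order", "mainstem", "none")
  if (any(bad)) stopf("unknown site_class '%s'", cls[bad][1])
  net$nodes$site_class <- cls
  net
}

site_ids <- function(net) net$nodes$node_id[net$nodes$is_site]
site_index <- function(net) net$idx[site_ids(net)]

#' @export
print.stream_network <- function(x, ...) {
  cat(sprintf("Stream network: %d nodes (%d sites), %d segments, %d component(s)\n",
              nrow(x$nodes), sum(x$nodes$is_site), nrow(x$segments),
              length(x$outlets)))
  cat(sprintf("  site classes: %d first-order, %d mainstem\n",
              sum(x$nodes$site_class == "first_order"),
              sum(x$nodes$site_class == "mainstem")))
  cat(sprintf("  elevation range: %.0f - %.0f m\n",
              min(x$nodes$elevation), max(x$nodes$elevation)))
  invisible(x)
}

# Chain of node indices from `i` down to its root (inclusive).
down_chain <- function(net, i) {
  out <- integer(net$depth[i] + 1L)
  k <- 1L
  while (!is.na(i)) { out[k] <- i; k <- k + 1L; i <- net$parent[i] }
  out[seq_len(k - 1L)]
}

# Unique tree path between node indices i and j via their lowest common
# ancestor (rooting: parent = downstream). Returns node and segment indices,
# or NULL when i and j are in different components.
tree_path <- function(net, i, j) {
  if (net$root[i] != net$root[j]) return(NULL)
  a <- i; b <- j
  seg_a <- integer(0); seg_b <- integer(0)
  nodes_a <- a; nodes_b <- b
  while (net$depth[a] > net$depth[b]) { seg_a <- c(seg_a, net$parent_seg[a]); a <- net$parent[a]; nodes_a <- c(nodes_a, a) }
  while (net$depth[b] > net$depth[a]) { seg_b <- c(seg_b, net$parent_seg[b]); b <- net$parent[b]; nodes_b <- c(nodes_b, b) }
  while (a != b) {
    seg_a <- c(seg_a, net$parent_seg[a]); a <- net$parent[a]; nodes_a <- c(nodes_a, a)
    seg_b <- c(seg_b, net$parent_seg[b]); b <- net$parent[b]; nodes_b <- c(nodes_b, b)
  }
  list(nodes = c(nodes_a, rev(nodes_b[nodes_b != a])),
       segments = c(seg_a, rev(seg_b)))
}

# Apply f(path) over all site pairs; fills a symmetric matrix. f returns a
# scalar; disconnected pairs give NA (or error when allow_na = FALSE).
pairwise_path_apply <- function(net, f, dist_type, allow_na = TRUE) {
  si <- site_index(net)
  ids <- site_ids(net)
  n <- length(si)
  m <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    p <- tree_path(net, si[a], si[b])
    if (is.null(p)) {
      if (!allow_na) stopf("sites '%s' and '%s' are in disconnected components", ids[a], ids[b])
      m[a, b] <- m[b, a] <- NA_real_
    } else m[a, b] <- m[b, a] <- f(p)
  }
  new_dist_matrix(m, ids, dist_type)
}

#' Straight-line (overland) geographical distances between sites
#'
#' Euclidean distance in the planar x/y coordinate plane for every pair of
#' sites.
#'
#' @param network a `stream_network`.
#' @return a symmetric `dendro_dist` matrix, `dist_type = "overland_geo"`.
#' @export
overland_distance_matrix <- function(network) {
  si <- site_index(network)
  xy <- as.matrix(network$nodes[si, c("x", "y")])
  if (any(!is.finite(xy))) stopf("missing site coordinates")
  m <- as.matrix(stats::dist(xy))
  new_dist_matrix(unname(m), site_ids(network), "overland_geo")
}

#' Watercourse (along-channel) geographical distances between sites
#'
#' Sum of segment lengths on the unique tree path between each pair of
#' sites, ignoring flow direction. Pairs in disconnected components are `NA`
#' unless `allow_disconnected = FALSE`, in which case they raise an error.
#'
#' @param network a `stream_network`.
#' @param allow_disconnected return `NA` for cross-component pairs?
#' @return a symmetric `dendro_dist` matrix, `dist_type = "watercourse_geo"`.
#' @export
watercourse_distance_matrix <- function(network, allow_disconnected = TRUE) {
  len <- network$segments$length
  pairwise_path_apply(network, function(p) sum(len[p$segments]),
                      "watercourse_geo", allow_disconnected)
}

#' Watercourse altitudinal distances between sites
#'
#' Relief along the channel: max minus min of node elevations over the
#' unique tree path between each pair of sites (endpoints included). A path
#' that dips through a confluence below both endpoints picks up the dip.
#'
#' @inheritParams watercourse_distance_matrix
#' @return a symmetric `dendro_dist` matrix, `dist_type = "watercourse_alt"`.
#' @export
watercourse_altitudinal_matrix <- function(network, allow_disconnected = TRUE) {
  elev <- network$nodes$elevation
  if (any(!is.finite(elev))) stopf("missing node elevations")
  pairwise_path_apply(network, function(p) {
    e <- elev[p$nodes]; max(e) - min(e)
  }, "watercourse_alt", allow_disconnected)
}

#' Downstream connectivity relation between sites
#'
#' Boolean site-by-site matrix `R` with `R[i, j]` true when site `i` lies on
#' the downstream flow path from site `j` (water flows from `j` to `i`).
#' The relation is transitive and irreflexive.
#'
#' @param network a `stream_network`.
#' @return logical matrix with site ids as dimnames.
#' @export
downstream_connectivity <- function(network) {
  si <- site_index(network)
  ids <- site_ids(network)
  n <- length(si)
  R <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  pos <- match(seq_len(nrow(network$nodes)), si)  # node idx -> site row
  for (j in seq_len(n)) {
    ch <- down_chain(network, si[j])
    below <- pos[ch[-1L]]
    R[below[!is.na(below)], j] <- TRUE
  }
  R
}
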