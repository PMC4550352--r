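#' Moran's I spatial autocorrelation
#'
#' `I = (n / sum(W)) * (v_c' W v_c) / (v_c' v_c)` with `v_c` the centred
#' variable. Positive for smooth gradients over the weights, negative for
#' checkerboard patterns; the null expectation is `-1/(n-1)`.
#'
#' @param v numeric vector with nonzero variance.
#' @param W nonnegative weight matrix, zero diagonal, nonzero sum.
#' @return scalar Moran's I.
#' @export
morans_i <- function(v, W) {
  n <- length(v)
  if (stats::var(v) == 0) stopf("Moran's I undefined for a constant variable")
  if (any(diag(W) != 0)) stopf("weight matrix must have a zero diagonal")
  sw <- sum(W)
  if (sw <= 0) stopf("weight matrix has zero total weight")
  vc <- v - mean(v)
  (n / sw) * as.numeric(vc %*% W %*% vc) / sum(vc^2)
}

new_eigenfunctions <- function(basis, eigenvalues, morans, construction, dist_type,
                               extra = list()) {
  colnames(basis) <- paste0(construction, seq_len(ncol(basis)))
  structure(c(list(basis = basis, eigenvalues = eigenvalues, morans_i = morans,
                   construction = construction, dist_type = dist_type), extra),
            class = "eigenfunctions")
}

#' @export
print.eigenfunctions <- function(x, ...) {
  cat(sprintf("%s eigenfunctions (%s): %d sites x %d axes\n", x$construction,
              x$dist_type, nrow(x$basis), ncol(x$basis)))
  if (ncol(x$basis))
    cat("  eigenvalues:", paste(signif(utils::head(x$eigenvalues, 6), 3), collapse = ", "),
        if (length(x$eigenvalues) > 6) "..." else "", "\n")
  invisible(x)
}

#' Moran's eigenvector maps from a distance matrix
#'
#' Distance-based MEM (the PCNM construction): distances above the
#' truncation threshold `t` are replaced by `4t`, the truncated matrix is
#' double-centred (Gower) as `-d^2/2`, and the principal coordinates
#' (eigenvectors of the centred matrix) form the spatial basis. The default
#' threshold, the longest edge of the minimum spanning tree of the distance
#' matrix, is the smallest value keeping all sites connected.
#'
#' Only eigenvectors whose eigenvalue exceeds `1e-10` times the leading
#' eigenvalue -- the positive, spatially structured set -- are retained;
#' negative-eigenvalue axes are dropped. Moran's I of each axis against the
#' binary within-threshold neighbour graph is attached for reference.
#'
#' @param D symmetric distance matrix (matrix or [dist]) with zero diagonal.
#' @param truncation threshold `t`; `NULL` (default) uses the largest
#'   minimum-spanning-tree edge.
#' @return an `eigenfunctions` object (`construction = "MEM"`), extra fields
#'   `truncation` and `n_positive`.
#' @export
mem_eigenfunctions <- function(D, truncation = NULL) {
  dt <- if (inherits(D, "dendro_dist")) attr(D, "dist_type") else "unknown"
  D <- as.matrix(D)
  if (any(is.na(D))) stopf("distance matrix has missing values (disconnected sites?)")
  check_distance_matrix(D, "MEM input")
  n <- nrow(D)
  if (is.null(truncation)) {
    sp <- vegan::spantree(stats::as.dist(D))
    truncation <- max(sp$dist)
  }
  # connectivity at the threshold (BFS over the d <= t graph)
  adj <- D <= truncation & upper.tri(D) | D <= truncation & lower.tri(D)
  diag(adj) <- FALSE
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE; frontier <- nxt
  }
  if (!all(seen))
    stopf("graph disconnected at truncation %.6g; increase the truncation threshold", truncation)
  Dstar <- D
  Dstar[Dstar > truncation] <- 4 * truncation
  A <- -0.5 * Dstar^2
  G <- t(t(A - rowMeans(A)) - colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  basis <- e$vectors[, keep, drop = FALSE]
  rownames(basis) <- rownames(D)
  W <- (D <= truncation) * 1; diag(W) <- 0
  mi <- apply(basis, 2, morans_i, W = W)
  new_eigenfunctions(basis, e$values[keep], mi, "MEM", dt,
                     extra = list(truncation = truncation,
                                  n_positive = sum(keep),
                                  all_eigenvalues = e$values))
}

#' Edge weights for asymmetric eigenvector maps
#'
#' Down-weights connections by the per-edge distance value:
#' `w = 1 - (d / d_max)^alpha`. A harsh or long edge acts as a partial
#' barrier; the edge at `d_max` receives a small floor (1e-6) instead of 0
#' so no connection is fully severed.
#'
#' @param d nonnegative per-edge distance values (max > 0).
#' @param scheme weighting scheme; only `"linear"` family (power `alpha`).
#' @param alpha exponent (>= 0); 1 = linear decay.
#' @return numeric weights in (0, 1].
#' @export
aem_edge_weights <- function(d, scheme = "linear", alpha = 1) {
  if (any(d < 0)) stopf("negative distance value in edge weights")
  if (max(d) <= 0) stopf("all edge distance values are zero")
  w <- 1 - (d / max(d))^alpha
  pmax(w, 1e-6)
}

# Reduce a transitive downstream-reachability relation to immediate
# neighbour pairs: i is j's nearest downstream site when no third site sits
# between them on the flow path. Returned symmetric binary weights.
immediate_neighbours <- function(R) {
  n <- nrow(R)
  W <- matrix(0, n, n, dimnames = dimnames(R))
  for (j in seq_len(n)) {
    below <- which(R[, j])
    for (i in below)
      if (!any(R[i, below])) { W[i, j] <- W[j, i] <- 1 }
  }
  W
}

# Site x edge incidence for the directed network: E[i, k] = 1 when edge k is
# upstream of site i (water through k reaches i). Edges are the network
# segments plus one virtual-origin edge per source node.
aem_incidence <- function(network) {
  ids <- site_ids(network)
  si <- site_index(network)
  nnode <- nrow(network$nodes)
  nseg <- nrow(network$segments)
  dnn <- network$idx[network$segments$down_node]
  sources <- setdiff(seq_len(nnode), dnn)  # nodes with no upstream segment
  # reach[i, v] = TRUE when node v is on the downstream chain of site i, incl i
  n <- length(si)
  E <- matrix(0, n, nseg + length(sources),
              dimnames = list(ids, c(network$segments$segment_id,
                                     paste0("origin_", network$nodes$node_id[sources]))))
  # below[v, i]: site i lies on the downstream chain of node v (v included),
  # i.e. water passing v reaches site i
  pos <- match(seq_len(nnode), si)
  below <- matrix(FALSE, nnode, n)
  for (v in seq_len(nnode)) {
    s_on <- pos[down_chain(network, v)]
    below[v, s_on[!is.na(s_on)]] <- TRUE
  }
  for (k in seq_len(nseg)) E[, k] <- below[dnn[k], ]
  for (s in seq_along(sources)) E[, nseg + s] <- below[sources[s], ]
  E
}

#' Asymmetric eigenvector maps from a directed stream network
#'
#' AEM models directional (downstream) processes. A virtual origin is placed
#' upstream of every source node; the site-by-edge incidence matrix `E`
#' (`E[i,k] = 1` when edge `k` lies on the flow path from the origin to site
#' `i`) is column-weighted, column-centred and decomposed by SVD. The left
#' singular vectors are the directional eigenfunctions; Moran's I against
#' the symmetrized downstream-connectivity graph classifies each axis as
#' positively or negatively autocorrelated.
#'
#' @param network a `stream_network` (a tree with downstream direction).
#' @param edge_values optional per-segment distance values used to weight
#'   edges via [aem_edge_weights()] (virtual-origin edges get weight 1);
#'   `NULL` uses unit weights.
#' @param alpha weighting exponent, see [aem_edge_weights()].
#' @param sites optional character vector restricting the rows (site ids) of
#'   the incidence matrix, e.g. for a first-order subset; edges carrying no
#'   retained site are silently dropped in that case.
#' @return an `eigenfunctions` object (`construction = "AEM"`), eigenvalues
#'   are squared singular values; extra field `weights`.
#' @export
aem_eigenfunctions <- function(network, edge_values = NULL, alpha = 1, sites = NULL) {
  E <- aem_incidence(network)
  nseg <- nrow(network$segments)
  w <- rep(1, ncol(E))
  dist_type <- "downstream_geo"
  if (!is.null(edge_values)) {
    if (length(edge_values) != nseg) stopf("edge_values must have one value per segment")
    w[seq_len(nseg)] <- aem_edge_weights(edge_values, alpha = alpha)
  }
  subset_mode <- !is.null(sites)
  if (subset_mode) {
    missing <- setdiff(sites, rownames(E))
    if (length(missing)) stopf("unknown site '%s' in subset", missing[1])
    E <- E[sites, , drop = FALSE]
    nonzero <- colSums(E) > 0
    E <- E[, nonzero, drop = FALSE]; w <- w[nonzero]
  } else if (any(colSums(E) == 0)) {
    stopf("all-zero incidence column for edge '%s' (no site downstream)",
          colnames(E)[colSums(E) == 0][1])
  }
  Ew <- sweep(E, 2, w, "*")
  Ec <- scale(Ew, center = TRUE, scale = FALSE)
  s <- svd(Ec)
  keep <- s$d > 1e-10 * max(s$d)
  basis <- s$u[, keep, drop = FALSE]
  rownames(basis) <- rownames(E)
  # Moran's I against the symmetrized *immediate* downstream-neighbour
  # relation (nearest site pairs along the channel); the transitive closure
  # would be a complete graph on a chain and carry no autocorrelation signal
  R <- downstream_connectivity(network)[rownames(E), rownames(E)]
  W <- immediate_neighbours(R)
  mi <- apply(basis, 2, function(v) if (stats::var(v) == 0) NA_real_ else morans_i(v, W))
  new_eigenfunctions(basis, s$d[keep]^2, mi, "AEM", dist_type,
                     extra = list(weights = w))
}

#' Keep the positively autocorrelated eigenfunctions
#'
#' MEM sets keep the positive-eigenvalue axes (already the retained set from
#' [mem_eigenfunctions()]); AEM singular values are always nonnegative, so
#' AEM sets are filtered on Moran's I above its null expectation
#' `-1/(n-1)`. An empty result is returned with attribute
#' `no_spatial_structure = TRUE` so pipelines can report it.
#'
#' @param set an `eigenfunctions` object.
#' @return the filtered `eigenfunctions` object.
#' @export
positive_eigenfunction_filter <- function(set) {
  n <- nrow(set$basis)
  keep <- if (set$construction == "MEM") set$eigenvalues > 0
          else set$morans_i > -1 / (n - 1)
  keep[is.na(keep)] <- FALSE
  out <- set
  out$basis <- set$basis[, keep, drop = FALSE]
  out$eigenvalues <- set$eigenvalues[keep]
  out$morans_i <- set$morans_i[keep]
  if (!ncol(out$basis)) attr(out, "no_spatial_structure") <- TRUE
  out
}

#' Write an eigenfunction set to CSV plus JSON metadata
#'
#' The basis goes to `<path>.csv` (site_id column + one column per axis);
#' eigenvalues, Moran's I, construction, distance type and settings go to
#' `<path>.json`.
#'
#' @param set an `eigenfunctions` object.
#' @param path output path without extension.
#' @export
write_eigenfunctions <- function(set, path) {
  df <- data.frame(site_id = rownames(set$basis), set$basis, check.names = FALSE)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(construction = set$construction, dist_type = set$dist_type,
               eigenvalues = set$eigenvalues, morans_i = set$morans_i,
               truncation = set$truncation, weights = set$weights)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
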