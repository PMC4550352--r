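#' Column-wise min-max scaling to [0, 1]
#'
#' `(x - min) / (max - min)` per column. Constant columns are an error: a
#' variable with no range carries no gradient information and would divide
#' by zero.
#'
#' @param x numeric matrix or data frame.
#' @return matrix of the same shape with every column in \[0, 1\].
#' @export
minmax_scale <- function(x) {
  x <- as.matrix(x)
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    nm <- colnames(x)[span == 0][1]
    stopf("constant column%s cannot be min-max scaled",
          if (is.null(nm) || is.na(nm)) "" else paste0(" '", nm, "'"))
  }
  sweep(sweep(x, 2, rng[1, ]), 2, span, "/")
}

#' Non-centred principal component analysis
#'
#' Singular value decomposition of the data matrix *without* column
#' centring, so the first axis tracks the overall (shared) magnitude of the
#' variables rather than their covariance about the mean. Used to ordinate
#' sites along a shared harshness gradient.
#'
#' @param x numeric n x m matrix, finite.
#' @return list of class `npca` with `scores` (U S, n x m), `loadings`
#'   (V), and `eigenvalues` (squared singular values / n), axes ordered by
#'   decreasing eigenvalue. Axis signs are fixed so each loading column has
#'   a nonnegative sum.
#' @export
noncentred_pca <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stopf("non-finite entries in input matrix")
  s <- svd(x)
  flip <- ifelse(colSums(s$v) < 0, -1, 1)
  structure(list(scores = sweep(s$u %*% diag(s$d, length(s$d)), 2, flip, "*"),
                 loadings = sweep(s$v, 2, flip, "*"),
                 eigenvalues = s$d^2 / nrow(x)),
            class = "npca")
}

#' @export
print.npca <- function(x, ...) {
  cat("Non-centred PCA:", nrow(x$scores), "rows,", length(x$eigenvalues), "axes\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Glaciality index of stream sites
#'
#' Composite index of glacial influence. The four harshness variables --
#' water temperature, conductivity, 1/turbidity and 1/Pfankuch (bottom
#' score) -- are scaled to \[0, 1\] and ordinated by non-centred PCA; the
#' first-axis site scores, oriented so that the *highest* values mark the
#' most glacially influenced sites (uniformly low temperature, conductivity,
#' clarity and stability) and shifted to a zero minimum, form the index.
#'
#' @param env data frame with per-site columns `temperature` (deg C),
#'   `conductivity` (uS/cm), `turbidity` (NTU, > 0) and `pfankuch`
#'   (bottom-component score, > 0); a `site_id` column, if present, labels
#'   the result.
#' @return numeric vector of class `glaciality_index` (one nonnegative score
#'   per site, minimum 0), with the NPCA fit attached as attribute `npca`.
#' @export
glaciality_index <- function(env) {
  need <- c("temperature", "conductivity", "turbidity", "pfankuch")
  if (!all(need %in% names(env)))
    stopf("environment table must have columns: %s", paste(need, collapse = ", "))
  if (any(env$turbidity <= 0)) stopf("turbidity must be > 0 (reciprocal is taken)")
  if (any(env$pfankuch <= 0)) stopf("pfankuch must be > 0 (reciprocal is taken)")
  raw <- cbind(temperature = env$temperature, conductivity = env$conductivity,
               inv_turbidity = 1 / env$turbidity, inv_pfankuch = 1 / env$pfankuch)
  if (any(!is.finite(raw))) stopf("non-finite values among the four glacier variables")
  sc <- minmax_scale(raw)
  fit <- noncentred_pca(sc)
  ax1 <- fit$scores[, 1]
  if (max(ax1) - min(ax1) < 1e-12) stopf("first-axis scores are constant; orientation undefined")
  # glacial sites have uniformly *low* scaled harshness variables, so the
  # index must anti-correlate with the row means of the scaled matrix
  if (stats::cor(ax1, rowMeans(sc)) > 0) ax1 <- -ax1
  ax1 <- ax1 - min(ax1)
  if (!is.null(env$site_id)) names(ax1) <- as.character(env$site_id)
  structure(ax1, npca = fit, class = "glaciality_index")
}

#' @export
print.glaciality_index <- function(x, ...) {
  cat(sprintf("Glaciality index for %d sites (0 = least, %.3f = most glacial)\n",
              length(x), max(x)))
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Attribute the glaciality index to stream segments
#'
#' Each segment carries the index of the nearest site upstream along its own
#' branch: walking upstream from the segment's upper node, the first site
#' found supplies the value. Segments with no single upstream site on their
#' branch -- the first segments downstream of a tributary junction, or below
#' a site-less source -- instead carry the nearest *downstream* site's
#' value. Idempotent: re-running overwrites with the same values.
#'
#' @param network a `stream_network` whose sites all appear in `index`.
#' @param index a [glaciality_index] named by site id (or a named numeric
#'   vector covering every site).
#' @return the network with a `glaciality` column filled in on `$segments`.
#' @export
assign_segment_glaciality <- function(network, index) {
  ids <- site_ids(network)
  if (is.null(names(index))) {
    if (length(index) != length(ids)) stopf("unnamed index must have one value per site")
    names(index) <- ids
  }
  if (!all(ids %in% names(index))) stopf("index missing site '%s'", setdiff(ids, names(index))[1])
  node_val <- rep(NA_real_, nrow(network$nodes))
  node_val[network$idx[ids]] <- as.numeric(index[ids])
  nseg <- nrow(network$segments)
  upn <- network$idx[network$segments$up_node]
  dnn <- network$idx[network$segments$down_node]
  n_up_segs <- tabulate(dnn[!is.na(dnn)], nbins = nrow(network$nodes))

  g <- rep(NA_real_, nseg)
  for (s in seq_len(nseg)) {
    # upstream scan along this segment's own branch
    u <- upn[s]
    repeat {
      if (!is.na(node_val[u])) { g[s] <- node_val[u]; break }
      ups <- which(dnn == u)
      if (length(ups) != 1L) break  # confluence or barren source: no single branch
      u <- upn[ups]
    }
    if (is.na(g[s])) {
      # fall back to the nearest downstream site
      d <- dnn[s]
      while (!is.na(d)) {
        if (!is.na(node_val[d])) { g[s] <- node_val[d]; break }
        d <- network$parent[d]
      }
    }
    if (is.na(g[s]))
      stopf("segment '%s' has no site upstream on its branch nor downstream",
            network$segments$segment_id[s])
  }
  network$segments$glaciality <- g
  network
}

#' Glaciality distances between sites along the channel
#'
#' For each pair of sites, the difference between the highest and lowest
#' glaciality encountered following the stream channel: the segment
#' glaciality values on the unique tree path between the sites, together
#' with the two sites' own index values.
#'
#' @param network a `stream_network` with segment glaciality attributed
#'   (see [assign_segment_glaciality()]).
#' @param index the [glaciality_index] used in the attribution.
#' @param allow_disconnected return `NA` for cross-component pairs?
#' @return a symmetric `dendro_dist` matrix, `dist_type = "watercourse_gla"`.
#' @export
glaciality_distance_matrix <- function(network, index, allow_disconnected = TRUE) {
  if (!"glaciality" %in% names(network$segments) ||
      any(is.na(network$segments$glaciality)))
    stopf("segments are not fully attributed; run assign_segment_glaciality() first")
  ids <- site_ids(network)
  if (is.null(names(index))) names(index) <- ids
  segg <- network$segments$glaciality
  sv <- as.numeric(index[ids])
  si <- site_index(network)
  pos <- match(seq_len(nrow(network$nodes)), si)
  pairwise_path_apply(network, function(p) {
    ends <- pos[c(p$nodes[1], p$nodes[length(p$nodes)])]
    vals <- c(segg[p$segments], sv[ends])
    max(vals) - min(vals)
  }, "watercourse_gla", allow_disconnected)
}
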