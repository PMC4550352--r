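#' Simulation scenario for a glacierized catchment
#'
#' Bundle of generator settings. Defaults emulate the kind of system the
#' package targets: a ~51-site dendritic network between roughly 3886 and
#' 4835 m a.s.l. with a handful of glacial headwater sources, an 85-taxon
#' macroinvertebrate community of which 70 taxa fly as adults, a glaciality
#' gradient decaying downstream, and communities shaped jointly by
#' species sorting along that gradient, spatially autocorrelated (dispersal)
#' structure, and a glaciality barrier penalizing non-flying taxa.
#'
#' @param n_sites number of site nodes (>= 3).
#' @param n_taxa,n_flying taxon counts (flying <= total).
#' @param n_first_order number of sites on first-order (Strahler order 1)
#'   channels; the remainder sit on the mainstem. Must be at least
#'   `n_headwaters` (every headwater tip is a site).
#' @param n_headwaters number of headwater sources in the network skeleton.
#' @param n_glacial_sources how many (highest) headwaters are glacial.
#' @param elevation_range catchment elevation span, metres a.s.l.
#' @param decay_per_km downstream decay rate of the latent glaciality
#'   signal (per km of channel).
#' @param niche_breadth Gaussian niche breadth on the latent glaciality
#'   scale (0-1).
#' @param env_effect species-sorting effect size (log-abundance units).
#' @param spatial_effect dispersal/spatial-structure effect size
#'   (log-abundance units, applied to the driving eigenfunctions).
#' @param barrier_strength log-abundance penalty for non-flying taxa whose
#'   colonization path crosses a high-glaciality segment.
#' @param barrier_threshold latent glaciality above which a segment acts as
#'   a barrier.
#' @param observation count model: `"poisson"` or `"negbin"`.
#' @param nb_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @return list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_sites = 51, n_taxa = 85, n_flying = 70,
                                n_first_order = 25,
                                n_headwaters = 8, n_glacial_sources = 4,
                                elevation_range = c(3886, 4835),
                                decay_per_km = 0.15, niche_breadth = 0.3,
                                env_effect = 1.5, spatial_effect = 0.6,
                                barrier_strength = 1.2, barrier_threshold = 0.5,
                                observation = c("poisson", "negbin"),
                                nb_dispersion = 5) {
  observation <- match.arg(observation)
  if (n_sites < 3) stopf("need at least 3 sites")
  if (n_flying > n_taxa) stopf("n_flying must be <= n_taxa")
  if (env_effect < 0 || spatial_effect < 0 || barrier_strength < 0)
    stopf("effect sizes must be >= 0")
  if (n_glacial_sources > n_headwaters) stopf("more glacial sources than headwaters")
  if (n_first_order < n_headwaters || n_first_order > n_sites - 1)
    stopf("n_first_order must be between n_headwaters and n_sites - 1")
  structure(as.list(environment()), class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %d sites, %d taxa (%d flying), %d headwaters (%d glacial)\n",
              x$n_sites, x$n_taxa, x$n_flying, x$n_headwaters, x$n_glacial_sources))
  cat(sprintf("  effects: env %.2f, spatial %.2f, barrier %.2f (threshold %.2f); %s counts\n",
              x$env_effect, x$spatial_effect, x$barrier_strength,
              x$barrier_threshold, x$observation))
  invisible(x)
}

#' Generate a dendritic stream network and matching DEM
#'
#' Grows a random recursive bifurcating skeleton (outlet, junctions,
#' headwater tips), distributes site nodes along its reaches, embeds it in
#' the plane with channel sinuosity >= 1 (so along-channel lengths always
#' dominate straight-line separations), and assigns elevations that strictly
#' decrease downstream within the scenario's elevation range. The highest
#' `n_glacial_sources` headwaters are flagged glacial. A smooth cone-like
#' DEM consistent with the node elevations (inverse-distance interpolation)
#' is returned alongside.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed.
#' @return list with `network` (a `stream_network`, with logical node column
#'   `is_glacial_source`) and `raster` (an `elevation_raster`).
#' @export
generate_network <- function(scenario = simulation_scenario(), seed = NULL) {
  with_seed(seed, {
    H <- scenario$n_headwaters
    # skeleton: reaches between outlet/junction/tip "anchor" nodes
    # anchors: 1 = outlet; grow tips by splitting
    anchor_parent <- c(NA_integer_, 1L)  # anchor 2 hangs below? no: 2 is first tip above outlet
    tips <- 2L
    while (length(tips) < H) {
      t0 <- tips[sample.int(length(tips), 1L)]
      new <- length(anchor_parent) + 1:2
      anchor_parent <- c(anchor_parent, t0, t0)
      tips <- c(setdiff(tips, t0), new)
    }
    n_anchor <- length(anchor_parent)
    is_tip <- !(seq_len(n_anchor) %in% anchor_parent)
    # geometry: place anchors recursively going upstream
    ax <- ay <- numeric(n_anchor)
    aang <- numeric(n_anchor)
    aang[1] <- pi / 2
    kids <- split(which(!is.na(anchor_parent)), anchor_parent[!is.na(anchor_parent)])
    ordv <- order(anchor_depth <- {
      d <- integer(n_anchor)
      for (i in seq_len(n_anchor)) { j <- i; while (!is.na(anchor_parent[j])) { d[i] <- d[i] + 1L; j <- anchor_parent[j] } }
      d
    })
    for (i in ordv) {
      if (is.na(anchor_parent[i])) next
      p <- anchor_parent[i]
      sibs <- kids[[as.character(p)]]
      off <- if (length(sibs) == 1) stats::runif(1, -0.3, 0.3)
             else (match(i, sibs) - 1.5) * stats::runif(1, 0.5, 0.9)
      aang[i] <- aang[p] + off
      reach_len <- stats::runif(1, 900, 2200)
      ax[i] <- ax[p] + reach_len * cos(aang[i])
      ay[i] <- ay[p] + reach_len * sin(aang[i])
    }
    # distribute intermediate sites across reaches (reach i = anchor i -> parent).
    # Sites on tip reaches are first-order (Strahler order 1); placing exactly
    # n_first_order - H intermediates there fixes the first-order site count.
    reaches <- which(!is.na(anchor_parent))
    tip_reach <- is_tip[reaches]
    n_inter <- scenario$n_sites - sum(is_tip) - 1L
    if (n_inter < 0) stopf("n_sites too small for %d headwaters", H)
    n_fo_inter <- min(scenario$n_first_order - H, n_inter)
    n_ms_inter <- n_inter - n_fo_inter
    if (!any(!tip_reach) && n_ms_inter > 0)
      stopf("no mainstem reach to host %d sites", n_ms_inter)
    alloc <- integer(length(reaches))
    if (n_fo_inter > 0)
      alloc <- alloc + tabulate(sample(which(tip_reach), n_fo_inter, replace = TRUE),
                                nbins = length(reaches))
    if (n_ms_inter > 0)
      alloc <- alloc + tabulate(sample(which(!tip_reach), n_ms_inter, replace = TRUE),
                                nbins = length(reaches))
    # build node & segment tables; anchors become nodes (tips+outlet are sites,
    # junctions are not); intermediates are sites
    node_id <- x <- y <- character(0)
    nodes <- data.frame(node_id = character(0), x = numeric(0), y = numeric(0),
                        elevation = numeric(0), is_site = logical(0))
    segs <- data.frame(segment_id = character(0), up_node = character(0),
                       down_node = character(0), length = numeric(0))
    aid <- sprintf("a%02d", seq_len(n_anchor))
    for (i in seq_len(n_anchor))
      nodes <- rbind(nodes, data.frame(node_id = aid[i], x = ax[i], y = ay[i],
                                       elevation = NA_real_,
                                       is_site = is_tip[i] || i == 1L))
    sct <- 0L; gct <- 0L
    for (ri in seq_along(reaches)) {
      i <- reaches[ri]; p <- anchor_parent[i]
      k <- alloc[ri]
      ts <- sort(stats::runif(k, 0.15, 0.85))
      chain <- aid[p]
      pts <- cbind(ax[p] + (ax[i] - ax[p]) * c(ts, 1), ay[p] + (ay[i] - ay[p]) * c(ts, 1))
      prev_xy <- c(ax[p], ay[p])
      for (j in seq_len(k + 1L)) {
        if (j <= k) { sct <- sct + 1L; nid <- sprintf("s%02d", sct) } else nid <- aid[i]
        if (j <= k)
          nodes <- rbind(nodes, data.frame(node_id = nid, x = pts[j, 1], y = pts[j, 2],
                                           elevation = NA_real_, is_site = TRUE))
        gct <- gct + 1L
        euclid <- sqrt(sum((pts[j, ] - prev_xy)^2))
        segs <- rbind(segs, data.frame(segment_id = sprintf("e%03d", gct),
                                       up_node = nid, down_node = chain,
                                       length = euclid * stats::runif(1, 1.05, 1.3)))
        chain <- nid; prev_xy <- pts[j, ]
      }
    }
    # elevations: climb upstream proportionally to segment length, then
    # rescale the whole relief into the scenario range
    idx <- seq_len(nrow(nodes)); names(idx) <- nodes$node_id
    elev <- rep(NA_real_, nrow(nodes)); elev[idx["a01"]] <- 0
    remaining <- segs
    while (nrow(remaining)) {
      ready <- !is.na(elev[idx[remaining$down_node]])
      for (r in which(ready))
        elev[idx[remaining$up_node[r]]] <- elev[idx[remaining$down_node[r]]] +
          remaining$length[r] * stats::runif(1, 0.05, 0.12)
      remaining <- remaining[!ready, , drop = FALSE]
    }
    er <- scenario$elevation_range
    elev <- er[1] + (elev - min(elev)) * diff(er) / (max(elev) - min(elev))
    nodes$elevation <- elev
    net <- build_network(nodes, segs)
    # glacial sources: the highest headwater tips
    tip_ids <- aid[is_tip]
    gl <- tip_ids[order(-nodes$elevation[idx[tip_ids]])][seq_len(scenario$n_glacial_sources)]
    net$nodes$is_glacial_source <- net$nodes$node_id %in% gl
    raster <- idw_raster(net, n_cells = 60)
    list(network = net, raster = raster)
  })
}

# Smooth DEM by inverse-distance-squared interpolation of node elevations.
idw_raster <- function(net, n_cells = 60, margin = 0.08) {
  xs <- net$nodes$x; ys <- net$nodes$y; zs <- net$nodes$elevation
  mx <- diff(range(xs)) * margin + 1; my <- diff(range(ys)) * margin + 1
  x0 <- min(xs) - mx; x1 <- max(xs) + mx
  y0 <- min(ys) - my; y1 <- max(ys) + my
  cs <- max(x1 - x0, y1 - y0) / n_cells
  gx <- seq(x0, x1, by = cs); gy <- seq(y0, y1, by = cs)
  v <- matrix(0, length(gy), length(gx))
  for (r in seq_along(gy)) {
    d2 <- outer(rep(gy[r], length(gx)), ys, function(a, b) (a - b)^2) +
          outer(gx, xs, function(a, b) (a - b)^2)
    w <- 1 / (d2 + 25)
    v[r, ] <- (w %*% zs) / rowSums(w)
  }
  elevation_raster(v, xll = x0, yll = y0, cellsize = cs)
}

# Latent glaciality per node: sources carry 1 (glacial) or 0, the signal
# decays exponentially along the channel and is diluted at confluences by
# flow-weighted averaging (flow ~ upstream headwater count).
latent_glaciality <- function(net, decay_per_km) {
  n <- nrow(net$nodes)
  dnn <- net$idx[net$segments$down_node]
  upn <- net$idx[net$segments$up_node]
  sources <- setdiff(seq_len(n), dnn)
  g <- rep(NA_real_, n); flow <- rep(NA_real_, n)
  g[sources] <- ifelse(net$nodes$is_glacial_source[sources], 1, 0)
  flow[sources] <- 1
  o <- order(net$depth, decreasing = TRUE)
  for (i in o) {
    if (i %in% sources) next
    segs_in <- which(dnn == i)
    gi <- g[upn[segs_in]] * exp(-decay_per_km * net$segments$length[segs_in] / 1000)
    fi <- flow[upn[segs_in]]
    g[i] <- sum(gi * fi) / sum(fi)
    flow[i] <- sum(fi)
  }
  g
}

#' Generate site environmental measurements from the network
#'
#' Computes the latent glaciality `g` of every site (exponential downstream
#' decay from glacial sources, flow-weighted dilution at confluences), then
#' draws the four harshness variables -- temperature, conductivity,
#' turbidity (inverted: rises with `g`), Pfankuch bottom score (rises with
#' `g`) -- as monotone functions of `g` with multiplicative lognormal noise,
#' and the Instream (width, depth, slope, pH) and Resources (epilithic
#' algae, benthic organic matter) variables independently of `g`.
#'
#' @param network a generated `stream_network` with `is_glacial_source`.
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed.
#' @return data frame (one row per site) with attribute `latent_g` (named
#'   latent glaciality of the sites).
#' @export
generate_environment <- function(network, scenario = simulation_scenario(), seed = NULL) {
  if (is.null(network$nodes$is_glacial_source)) stopf("network has no glacial sources marked")
  if (scenario$n_glacial_sources > 0 && !any(network$nodes$is_glacial_source))
    stopf("scenario requires glacial sources but none are marked")
  g_node <- latent_glaciality(network, scenario$decay_per_km)
  si <- site_index(network)
  g <- g_node[si]; names(g) <- site_ids(network)
  n <- length(g)
  with_seed(seed, {
    ln <- function(s) exp(stats::rnorm(n, 0, s))
    env <- data.frame(
      site_id = site_ids(network),
      temperature = (1.5 + 8.5 * (1 - g)) * ln(0.12),
      conductivity = (15 + 165 * (1 - g)) * ln(0.12),
      turbidity = (2 + 198 * g) * ln(0.12),
      pfankuch = (12 + 28 * g) * ln(0.08),
      width = exp(stats::rnorm(n, log(3), 0.4)),
      depth = exp(stats::rnorm(n, log(0.25), 0.4)),
      slope = exp(stats::rnorm(n, log(0.08), 0.5)),
      ph = stats::rnorm(n, 7.8, 0.3),
      epilithic_algae = exp(stats::rnorm(n, log(5), 0.5)),
      benthic_om = exp(stats::rnorm(n, log(2), 0.5)))
    attr(env, "latent_g") <- g
    env
  })
}

#' Generate a structured community matrix
#'
#' Log mean abundance of taxon `t` at site `i` combines (a) a Gaussian
#' species-sorting response to the latent glaciality gradient (taxon optima
#' uniform on \[0, 1\], so the pool spans glacial specialists through
#' groundwater specialists), (b) a taxon-specific linear combination of the
#' supplied spatial eigenfunctions, and (c) for non-flying taxa, a barrier
#' penalty whenever the channel path from the taxon's source site (its best
#' site) crosses a segment whose latent glaciality exceeds the scenario
#' threshold. Counts are Poisson (default) or negative-binomial. Taxa that
#' come up all-zero are redrawn up to 10 times then dropped; all-zero site
#' rows are resampled so every site stays analyzable.
#'
#' @param network the `stream_network` the environment was generated on.
#' @param environment output of [generate_environment()] (carries
#'   `latent_g`).
#' @param eigenfunctions optional site x axis matrix driving the spatial
#'   component (rows in site order); `NULL` disables it even if
#'   `spatial_effect > 0`.
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed.
#' @return sites x taxa count matrix with attributes `traits` (data frame
#'   `taxon_id`, `flying`) and `truth` (latent drivers and effect sizes).
#' @export
generate_community <- function(network, environment, eigenfunctions = NULL,
                               scenario = simulation_scenario(), seed = NULL) {
  g <- attr(environment, "latent_g")
  ids <- site_ids(network)
  n <- length(ids)
  p <- scenario$n_taxa
  with_seed(seed, {
    flying <- c(rep(TRUE, scenario$n_flying), rep(FALSE, p - scenario$n_flying))
    opt <- stats::runif(p)
    intercept <- stats::rnorm(p, log(8), 0.8)
    niche <- exp(-outer(g, opt, "-")^2 / (2 * scenario$niche_breadth^2))  # n x p
    eta <- matrix(intercept, n, p, byrow = TRUE) +
      scenario$env_effect * (niche - 0.5)
    S <- NULL
    if (!is.null(eigenfunctions) && scenario$spatial_effect > 0) {
      B <- as.matrix(eigenfunctions) * sqrt(n)  # unit-norm columns -> O(1) values
      coefs <- matrix(stats::rnorm(ncol(B) * p, 0, 1), ncol(B), p)
      S <- B %*% coefs
      eta <- eta + scenario$spatial_effect * S / max(1, sqrt(ncol(B)))
    }
    barrier_mat <- NULL
    if (scenario$barrier_strength > 0) {
      seg_g <- latent_glaciality(network, scenario$decay_per_km)[network$idx[network$segments$up_node]]
      si <- site_index(network)
      blocked <- matrix(FALSE, n, n)  # [i, s]: path s -> i crosses a barrier
      for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
        pth <- tree_path(network, si[a], si[b])
        hit <- !is.null(pth) && any(seg_g[pth$segments] > scenario$barrier_threshold)
        blocked[a, b] <- blocked[b, a] <- hit
      }
      src <- apply(niche, 2, which.max)
      barrier_mat <- vapply(seq_len(p), function(t) {
        if (flying[t]) rep(0, n)
        else scenario$barrier_strength * as.numeric(blocked[, src[t]])
      }, numeric(n))
      eta <- eta - barrier_mat
    }
    draw <- function(lambda) {
      if (scenario$observation == "poisson") stats::rpois(length(lambda), lambda)
      else stats::rnbinom(length(lambda), mu = lambda, size = scenario$nb_dispersion)
    }
    lam <- exp(eta)
    Y <- matrix(draw(lam), n, p)
    # redraw all-zero taxa, then drop persistent zeros
    for (t in which(colSums(Y) == 0)) {
      for (r in 1:10) { Y[, t] <- draw(lam[, t]); if (sum(Y[, t]) > 0) break }
    }
    dropped <- which(colSums(Y) == 0)
    if (length(dropped)) {
      message(sprintf("dropping %d taxa with zero total after 10 redraws", length(dropped)))
      Y <- Y[, -dropped, drop = FALSE]; flying <- flying[-dropped]
      opt <- opt[-dropped]; lam <- lam[, -dropped, drop = FALSE]
    }
    # resample all-zero site rows
    for (i in which(rowSums(Y) == 0)) {
      for (r in 1:50) { Y[i, ] <- draw(lam[i, ]); if (sum(Y[i, ]) > 0) break }
      if (sum(Y[i, ]) == 0) Y[i, which.max(lam[i, ])] <- 1L
    }
    dimnames(Y) <- list(ids, sprintf("taxon%02d", seq_len(ncol(Y))))
    attr(Y, "traits") <- data.frame(taxon_id = colnames(Y), flying = as.integer(flying))
    attr(Y, "truth") <- list(latent_g = g, niche_optima = opt,
                             env_effect = scenario$env_effect,
                             spatial_effect = scenario$spatial_effect,
                             barrier_strength = scenario$barrier_strength,
                             spatial_component = S)
    Y
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_network()], [generate_environment()] and
#' [generate_community()] with sub-seeds derived from one master seed. When
#' `scenario$spatial_effect > 0` the community's spatial component is driven
#' by the first `n_driver_axes` directional (AEM, downstream-geographic)
#' eigenfunctions of the generated network.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed master integer seed; the same seed reproduces the dataset
#'   byte-for-byte.
#' @param n_driver_axes number of AEM axes driving the spatial component.
#' @return list of class `dendro_sim`: `network`, `raster`, `env`,
#'   `community`, `traits`, `truth`, `scenario`.
#' @export
generate_dataset <- function(scenario = simulation_scenario(), seed = NULL,
                             n_driver_axes = 3) {
  gn <- generate_network(scenario, seed = derive_seed(seed, 1L))
  env <- generate_environment(gn$network, scenario, seed = derive_seed(seed, 2L))
  drivers <- NULL
  if (scenario$spatial_effect > 0) {
    aem <- aem_eigenfunctions(gn$network, edge_values = gn$network$segments$length)
    drivers <- aem$basis[, seq_len(min(n_driver_axes, ncol(aem$basis))), drop = FALSE]
  }
  Y <- generate_community(gn$network, env, eigenfunctions = drivers,
                          scenario = scenario, seed = derive_seed(seed, 3L))
  structure(list(network = gn$network, raster = gn$raster, env = env,
                 community = Y, traits = attr(Y, "traits"),
                 truth = attr(Y, "truth"), scenario = scenario),
            class = "dendro_sim")
}

#' @export
print.dendro_sim <- function(x, ...) {
  cat("Synthetic glacial-catchment dataset\n")
  print(x$network)
  cat(sprintf("  community: %d sites x %d taxa (%d flying), %s counts\n",
              nrow(x$community), ncol(x$community), sum(x$traits$flying),
              x$scenario$observation))
  invisible(x)
}
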