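#' Split a community matrix into the four taxon matrices
#'
#' `all` = the full matrix; `flying` / `nonflying` = column subsets by the
#' winged-adult trait flag; `first_order` = rows restricted to first-order
#' (headwater) sites with columns restricted to taxa that occur there.
#'
#' @param community sites x taxa abundance matrix (site ids as rownames).
#' @param traits data frame `taxon_id`, `flying` (0/1) covering every taxon.
#' @param site_classes named character vector (`"first_order"` /
#'   `"mainstem"`) per site; taken from a `stream_network` via
#'   [site_classes()] if a network is supplied.
#' @return named list of four matrices.
#' @export
split_taxa <- function(community, traits, site_classes) {
  community <- as.matrix(community)
  if (inherits(site_classes, "stream_network")) site_classes <- site_classes(site_classes)
  missing <- setdiff(colnames(community), traits$taxon_id)
  if (length(missing)) stopf("taxon '%s' has no trait value", missing[1])
  fl <- as.logical(traits$flying[match(colnames(community), traits$taxon_id)])
  if (anyNA(fl)) stopf("taxon '%s' has no trait value", colnames(community)[is.na(fl)][1])
  splits <- list(all = community)
  for (nm in c("flying", "nonflying")) {
    keep <- if (nm == "flying") fl else !fl
    if (!any(keep)) stopf("empty matrix: no %s taxa", nm)
    splits[[nm]] <- community[, keep, drop = FALSE]
  }
  fo <- names(site_classes)[site_classes == "first_order"]
  fo <- intersect(rownames(community), fo)
  if (!length(fo)) stopf("empty matrix: no first-order sites")
  m <- community[fo, , drop = FALSE]
  splits$first_order <- m[, colSums(m) > 0, drop = FALSE]
  splits
}

#' Site classes of a stream network
#'
#' @param network a `stream_network`.
#' @return named character vector over sites.
#' @export
site_classes <- function(network) {
  cl <- network$nodes$site_class[network$nodes$is_site]
  names(cl) <- site_ids(network)
  cl
}

#' Environmental predictor blocks
#'
#' Builds the three environmental component matrices from a site
#' environment table, each min-max scaled to \[0, 1\]: `Glacier`
#' (temperature, conductivity, 1/turbidity, 1/Pfankuch), `Instream` (width,
#' depth, slope, pH) and `Resources` (epilithic algae, benthic organic
#' matter).
#'
#' @param env environment table as from [generate_environment()].
#' @return named list of three scaled matrices (site ids as rownames).
#' @export
environment_blocks <- function(env) {
  rn <- if (!is.null(env$site_id)) as.character(env$site_id) else rownames(env)
  mk <- function(m) { rownames(m) <- rn; minmax_scale(m) }
  list(
    Glacier = mk(cbind(temperature = env$temperature, conductivity = env$conductivity,
                       inv_turbidity = 1 / env$turbidity, inv_pfankuch = 1 / env$pfankuch)),
    Instream = mk(cbind(width = env$width, depth = env$depth,
                        slope = env$slope, ph = env$ph)),
    Resources = mk(cbind(epilithic_algae = env$epilithic_algae,
                         benthic_om = env$benthic_om)))
}

# Gatekeeping for one spatial variable: positive-eigenfunction filter,
# global test, forward selection. Returns the selected basis (or NULL with
# a reason) plus bookkeeping.
select_spatial_block <- function(Y, set, alpha, n_perm, seed) {
  set <- positive_eigenfunction_filter(set)
  if (isTRUE(attr(set, "no_spatial_structure")))
    return(list(basis = NULL, reason = "no spatial structure", selection = NULL,
                global_p = NA_real_))
  fs <- forward_select(Y, set$basis, alpha = alpha, n_perm = n_perm, seed = seed)
  if (!length(fs$selected))
    return(list(basis = NULL,
                reason = if (fs$global$p_value > alpha) "global test not significant"
                         else "no eigenfunction selected",
                selection = fs, global_p = fs$global$p_value))
  list(basis = set$basis[, fs$selected, drop = FALSE], reason = NULL,
       selection = fs, global_p = fs$global$p_value)
}

new_model_report <- function(model, splits, extra = list()) {
  structure(c(list(model = model, splits = splits), extra), class = "model_report")
}

split_names <- c("all", "flying", "nonflying", "first_order")

#' Model 1: Glacier vs. other environmental components
#'
#' Three-block variation partitioning of each Hellinger-transformed taxon
#' matrix on the `Glacier`, `Instream` and `Resources` environmental
#' components.
#'
#' @param data a `dendro_sim` (or compatible list with `network`, `env`,
#'   `community`, `traits`).
#' @param alpha significance level for the reported stars.
#' @param n_perm permutations for the unique-fraction tests.
#' @param seed master seed.
#' @return a `model_report` with one `varpart_result` per taxon matrix.
#' @export
run_model1 <- function(data, alpha = 0.05, n_perm = 999, seed = NULL) {
  blocks <- environment_blocks(data$env)
  taxa <- split_taxa(data$community, data$traits, data$network)
  out <- list()
  for (si in seq_along(split_names)) {
    nm <- split_names[si]
    Y <- hellinger(taxa[[nm]])
    bl <- lapply(blocks, function(b) b[rownames(Y), , drop = FALSE])
    out[[nm]] <- list(varpart = variation_partition(Y, bl, n_perm = n_perm,
                                                    seed = derive_seed(seed, 10L + si)),
                      spatial = list())
  }
  new_model_report("model1", out, list(alpha = alpha))
}

# Distance machinery shared by models 2 and 3: returns the three (or two)
# eigenfunction sets for one distance family, restricted to `sites`.
spatial_sets <- function(data, family, sites) {
  net <- data$network
  all_sites <- site_ids(net)
  sub <- !identical(sites, all_sites)
  sets <- list()
  if (family == "geographic") {
    ov <- overland_distance_matrix(net)
    wc <- watercourse_distance_matrix(net)
    edge_vals <- net$segments$length
  } else if (family == "altitudinal") {
    ov <- overland_altitudinal_matrix(net, data$raster)
    wc <- watercourse_altitudinal_matrix(net)
    up <- net$idx[net$segments$up_node]; dn <- net$idx[net$segments$down_node]
    edge_vals <- net$nodes$elevation[up] - net$nodes$elevation[dn]
  } else if (family == "glaciality") {
    idx <- glaciality_index(data$env)
    netg <- assign_segment_glaciality(net, idx)
    wc <- glaciality_distance_matrix(netg, idx)
    if (max(wc) <= 0) stopf("degenerate distance matrix: glaciality is constant across the network")
    ov <- NULL  # never constructed: no glaciality difference through the air
    edge_vals <- netg$segments$glaciality
    if (max(edge_vals) - min(edge_vals) <= 0)
      stopf("degenerate distance matrix: constant segment glaciality")
    edge_vals <- edge_vals - min(edge_vals)
  } else stopf("unknown distance family '%s'", family)
  if (!is.null(ov)) {
    m <- unclass(ov)[sites, sites]
    sets$overland <- mem_eigenfunctions(structure(m, dist_type = attr(ov, "dist_type"),
                                                  class = class(ov)))
  }
  m <- unclass(wc)[sites, sites]
  sets$watercourse <- mem_eigenfunctions(structure(m, dist_type = attr(wc, "dist_type"),
                                                   class = class(wc)))
  sets$downstream <- aem_eigenfunctions(net, edge_values = edge_vals,
                                        sites = if (sub) sites else NULL)
  if (!sub) sets$downstream$basis <- sets$downstream$basis[sites, , drop = FALSE]
  sets$downstream$dist_type <- paste0("downstream_", substr(family, 1, 3))
  sets
}

run_spatial_model <- function(data, family, spatial_names, with_glacier,
                              alpha, n_perm, seed, model_label) {
  taxa <- split_taxa(data$community, data$traits, data$network)
  env_bl <- environment_blocks(data$env)
  out <- list()
  for (si in seq_along(split_names)) {
    nm <- split_names[si]
    Y <- hellinger(taxa[[nm]])
    sites <- rownames(Y)
    sets <- spatial_sets(data, family, sites)
    spatial <- list()
    blocks <- list()
    for (vi in seq_along(spatial_names)) {
      v <- spatial_names[vi]
      sel <- select_spatial_block(Y, sets[[v]], alpha, n_perm,
                                  derive_seed(seed, 100L * si + vi))
      spatial[[v]] <- sel
      if (!is.null(sel$basis)) blocks[[v]] <- sel$basis
      else message(sprintf("[%s/%s] %s block dropped: %s", model_label, nm, v, sel$reason))
    }
    if (with_glacier) blocks$Glacier <- env_bl$Glacier[sites, , drop = FALSE]
    vp <- if (length(blocks) >= 2)
      variation_partition(Y, blocks, n_perm = n_perm, seed = derive_seed(seed, 500L + si))
    else NULL
    out[[nm]] <- list(varpart = vp, spatial = spatial)
  }
  new_model_report(model_label, out, list(alpha = alpha, family = family))
}

#' Model 2: Glacier vs. spatial variables
#'
#' Builds the three eigenfunction-based spatial variables -- overland (MEM),
#' watercourse (MEM) and directional downstream (AEM) -- from geographic or
#' altitudinal distances, gatekeeps each through a global test and forward
#' selection, and partitions each Hellinger-transformed taxon matrix over
#' the surviving spatial blocks plus the `Glacier` component (up to four
#' blocks). A spatial variable whose global test fails enters as absent and
#' the partition degrades gracefully.
#'
#' @inheritParams run_model1
#' @param family `"geographic"` or `"altitudinal"`.
#' @return a `model_report`; each split records its `varpart_result` and the
#'   per-variable selection bookkeeping.
#' @export
run_model2 <- function(data, family = c("geographic", "altitudinal"),
                       alpha = 0.05, n_perm = 999, seed = NULL) {
  family <- match.arg(family)
  run_spatial_model(data, family, c("overland", "watercourse", "downstream"),
                    with_glacier = TRUE, alpha, n_perm, seed,
                    paste0("model2_", substr(family, 1, 3)))
}

#' Model 3: glaciality distances as dispersal barriers
#'
#' Watercourse (MEM) and directional downstream (AEM) spatial variables
#' computed from glaciality distances -- the difference in glacial
#' influence along the channel -- then a two-block variation partitioning
#' per taxon matrix. Overland glaciality variables are never constructed:
#' there is no glaciality difference through the air.
#'
#' @inheritParams run_model1
#' @return a `model_report`.
#' @export
run_model3 <- function(data, alpha = 0.05, n_perm = 999, seed = NULL) {
  run_spatial_model(data, "glaciality", c("watercourse", "downstream"),
                    with_glacier = FALSE, alpha, n_perm, seed, "model3")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("== %s%s ==\n", x$model,
              if (!is.null(x$family)) paste0(" (", x$family, " distances)") else ""))
  for (nm in names(x$splits)) {
    sp <- x$splits[[nm]]
    cat(sprintf("-- %s --\n", nm))
    if (is.null(sp$varpart)) { cat("  (fewer than 2 blocks survived; no partition)\n"); next }
    print(sp$varpart)
    for (v in names(sp$spatial)) {
      s <- sp$spatial[[v]]
      if (is.null(s$basis)) cat(sprintf("  %s: %s\n", v, s$reason))
      else cat(sprintf("  %s: %d eigenfunction(s) selected (global p = %.3g)\n",
                       v, ncol(s$basis), s$global_p))
    }
  }
  invisible(x)
}

#' Fraction table of a model report
#'
#' One row per (taxon matrix, fraction): unique fractions with stars,
#' pooled shared variance and residual, as percentages.
#'
#' @param report a `model_report`.
#' @return data frame.
#' @export
fraction_table <- function(report) {
  rows <- list()
  for (nm in names(report$splits)) {
    vp <- report$splits[[nm]]$varpart
    if (is.null(vp)) next
    st <- if (!is.null(vp$tests)) vp$tests$stars[match(names(vp$uniques), vp$tests$block)] else ""
    pv <- if (!is.null(vp$tests)) vp$tests$p_value[match(names(vp$uniques), vp$tests$block)] else NA
    rows[[nm]] <- data.frame(
      taxa = nm,
      fraction = c(paste0("unique_", names(vp$uniques)), "shared_total", "residual"),
      percent = 100 * c(unname(vp$uniques), vp$shared_total, vp$residual),
      p_value = c(pv, NA, NA), stars = c(st, "", ""))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Confounding of distance types within each spatial variable
#'
#' For each spatial variable (overland, watercourse, downstream), partitions
#' community variation across the eigenfunctions *selected* for that
#' variable under the different distance types (geographic, altitudinal,
#' and -- except overland -- glaciality), per taxon matrix. Each distance
#' type is then classified: `unique_significant` (its unique fraction
#' passes the permutation test), `confounded_significant` (its own global
#' test passed but its unique fraction does not), or `not_significant`.
#'
#' @param data the dataset the model reports were computed from.
#' @param m2_geo,m2_alt model-2 reports for the two distance families.
#' @param m3 model-3 report.
#' @param alpha significance level.
#' @param n_perm permutations.
#' @param seed master seed.
#' @return object of class `confounding_report`: data frame `table` plus the
#'   underlying `varpart_result`s.
#' @export
confounding_report <- function(data, m2_geo, m2_alt, m3, alpha = 0.05,
                               n_perm = 999, seed = NULL) {
  reports <- list(geographic = m2_geo, altitudinal = m2_alt, glaciality = m3)
  if (any(vapply(reports, is.null, TRUE))) stopf("missing upstream model report")
  taxa <- split_taxa(data$community, data$traits, data$network)
  rows <- list(); parts <- list()
  vars <- list(overland = c("geographic", "altitudinal"),
               watercourse = c("geographic", "altitudinal", "glaciality"),
               downstream = c("geographic", "altitudinal", "glaciality"))
  cnt <- 0L
  for (nm in split_names) {
    Y <- hellinger(taxa[[nm]])
    for (v in names(vars)) {
      blocks <- list(); glob <- c()
      for (fam in vars[[v]]) {
        s <- reports[[fam]]$splits[[nm]]$spatial[[v]]
        glob[fam] <- if (!is.null(s$global_p)) s$global_p else NA_real_
        if (!is.null(s$basis)) blocks[[fam]] <- s$basis
      }
      cnt <- cnt + 1L
      vp <- if (length(blocks) >= 2)
        variation_partition(Y, blocks, n_perm = n_perm, seed = derive_seed(seed, 700L + cnt))
      else NULL
      parts[[paste(nm, v, sep = ".")]] <- vp
      for (fam in vars[[v]]) {
        status <- if (!fam %in% names(blocks)) {
          if (!is.na(glob[fam]) && glob[fam] <= alpha) "confounded_significant" else "not_significant"
        } else if (is.null(vp)) {
          "unique_significant"  # only surviving family: its global test passed
        } else {
          p <- vp$tests$p_value[vp$tests$block == fam]
          if (length(p) && !is.na(p) && p <= alpha) "unique_significant"
          else if (!is.na(glob[fam]) && glob[fam] <= alpha) "confounded_significant"
          else "not_significant"
        }
        rows[[length(rows) + 1L]] <- data.frame(taxa = nm, spatial_variable = v,
                                                distance = fam, status = status)
      }
    }
  }
  structure(list(table = do.call(rbind, rows), partitions = parts, alpha = alpha),
            class = "confounding_report")
}

#' @export
print.confounding_report <- function(x, ...) {
  cat("== Confounding of distance types ==\n")
  w <- stats::reshape(x$table, idvar = c("taxa", "spatial_variable"),
                      timevar = "distance", direction = "wide")
  names(w) <- sub("^status\\.", "", names(w))
  print(w, row.names = FALSE)
  invisible(x)
}

#' Run the full analysis
#'
#' Models 1-3 (model 2 for both geographic and altitudinal distances) on
#' the four taxon matrices, followed by the distance-type confounding
#' report. Every random step is seeded from the master seed, so the same
#' `data` + `seed` reproduce every fraction and p-value exactly.
#'
#' @param data a `dendro_sim` or equivalently structured dataset.
#' @param alpha significance level.
#' @param n_perm permutations per test (default 999).
#' @param seed master seed.
#' @return object of class `dendropart_analysis` with elements `model1`,
#'   `model2_geo`, `model2_alt`, `model3`, `confounding`.
#' @export
run_full_analysis <- function(data, alpha = 0.05, n_perm = 999, seed = NULL) {
  m1 <- run_model1(data, alpha, n_perm, derive_seed(seed, 1L))
  m2g <- run_model2(data, "geographic", alpha, n_perm, derive_seed(seed, 2L))
  m2a <- run_model2(data, "altitudinal", alpha, n_perm, derive_seed(seed, 3L))
  m3 <- run_model3(data, alpha, n_perm, derive_seed(seed, 4L))
  cf <- confounding_report(data, m2g, m2a, m3, alpha, n_perm, derive_seed(seed, 5L))
  structure(list(model1 = m1, model2_geo = m2g, model2_alt = m2a,
                 model3 = m3, confounding = cf,
                 alpha = alpha, n_perm = n_perm),
            class = "dendropart_analysis")
}

#' @export
print.dendropart_analysis <- function(x, ...) {
  for (m in c("model1", "model2_geo", "model2_alt", "model3")) { print(x[[m]]); cat("\n") }
  print(x$confounding)
  invisible(x)
}
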