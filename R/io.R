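#' Write a synthetic dataset to plain-text files
#'
#' Emits `nodes.csv`, `segments.csv`, `dem.asc` (ESRI ASCII grid),
#' `environment.csv`, `community.csv`, `traits.csv` and `truth.json`
#' (latent glaciality and generating effect sizes) into a directory.
#'
#' @param sim a `dendro_sim` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  nodes <- sim$network$nodes[c("node_id", "x", "y", "elevation", "is_site", "site_class")]
  utils::write.csv(nodes, p("nodes.csv"), row.names = FALSE)
  utils::write.csv(sim$network$segments, p("segments.csv"), row.names = FALSE)
  write_ascii_grid(sim$raster, p("dem.asc"))
  utils::write.csv(sim$env, p("environment.csv"), row.names = FALSE)
  comm <- data.frame(site_id = rownames(sim$community), sim$community, check.names = FALSE)
  utils::write.csv(comm, p("community.csv"), row.names = FALSE)
  utils::write.csv(sim$traits, p("traits.csv"), row.names = FALSE)
  truth <- sim$truth[c("latent_g", "niche_optima", "env_effect", "spatial_effect",
                       "barrier_strength")]
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory back into analysis form
#'
#' Counterpart of [write_dataset()]; also accepts hand-built directories
#' with the same file layout. `dem.asc` and `truth.json` are optional.
#'
#' @param dir directory containing the CSV files.
#' @return a `dendro_sim`-compatible list (`network`, `raster`, `env`,
#'   `community`, `traits`, `truth`).
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  nodes <- utils::read.csv(p("nodes.csv"))
  segments <- utils::read.csv(p("segments.csv"))
  net <- build_network(nodes, segments)
  raster <- if (file.exists(p("dem.asc"))) read_ascii_grid(p("dem.asc")) else NULL
  env <- utils::read.csv(p("environment.csv"))
  comm <- utils::read.csv(p("community.csv"), check.names = FALSE)
  Y <- as.matrix(comm[, -1, drop = FALSE])
  rownames(Y) <- as.character(comm[[1]])
  traits <- utils::read.csv(p("traits.csv"))
  truth <- if (file.exists(p("truth.json"))) jsonlite::read_json(p("truth.json"), simplifyVector = TRUE) else NULL
  structure(list(network = net, raster = raster, env = env, community = Y,
                 traits = traits, truth = truth),
            class = "dendro_sim")
}

#' Write a distance matrix as labelled CSV
#'
#' Row and column headers are the site ids.
#'
#' @param d a `dendro_dist` (or plain matrix with dimnames).
#' @param path output file.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.csv(as.data.frame(unclass(d)), path, row.names = TRUE)
  invisible(path)
}
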