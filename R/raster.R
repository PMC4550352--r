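#' Elevation raster
#'
#' A rectangular digital elevation model on a regular grid. `values` is a
#' matrix with rows running south -> north (row 1 = southernmost), columns
#' west -> east; `xll`/`yll` are the coordinates of the lower-left cell
#' *centre* and `cellsize` the grid spacing in metres.
#'
#' @param values numeric matrix of elevations (m).
#' @param xll,yll coordinates (m) of the lower-left cell centre.
#' @param cellsize grid spacing (m), > 0.
#' @return object of class `elevation_raster`.
#' @export
elevation_raster <- function(values, xll = 0, yll = 0, cellsize = 1) {
  values <- as.matrix(values)
  if (cellsize <= 0) stopf("cellsize must be > 0")
  if (any(!is.finite(values))) stopf("raster contains non-finite elevations")
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "elevation_raster")
}

#' @export
print.elevation_raster <- function(x, ...) {
  cat(sprintf("Elevation raster: %d x %d cells, %.4g m resolution\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("  elevation %.1f - %.1f m\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Read / write ESRI ASCII grids
#'
#' Minimal reader and writer for the plain-text `.asc` exchange format
#' (header keys ncols, nrows, xllcorner/xllcenter, cellsize, nodata_value;
#' rows listed north to south). NODATA cells are rejected: elevation lines
#' are sampled by interpolation and must be defined everywhere.
#'
#' @param path file path.
#' @return `read_ascii_grid` returns an `elevation_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); i <- i + 1L
    } else break
  }
  nc <- hdr$ncols; nr <- hdr$nrows; cs <- hdr$cellsize
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nc * nr) stopf("grid body has %d values, expected %d", length(vals), nc * nr)
  if (!is.null(hdr$nodata_value) && any(vals == hdr$nodata_value))
    stopf("grid contains NODATA cells")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]  # stored north->south; flip to south->north
  xll <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else hdr$xllcorner + cs / 2
  yll <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else hdr$yllcorner + cs / 2
  elevation_raster(m, xll = xll, yll = yll, cellsize = cs)
}

#' @rdname read_ascii_grid
#' @param raster an `elevation_raster`.
#' @export
write_ascii_grid <- function(raster, path) {
  v <- raster$values
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcenter %.10g", raster$xll), sprintf("yllcenter %.10g", raster$yll),
           sprintf("cellsize %.10g", raster$cellsize), "nodata_value -9999")
  body <- apply(v[nrow(v):1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Bilinear interpolation of raster elevations at arbitrary points.
# Points must lie within the hull of cell centres.
raster_interpolate <- function(raster, x, y) {
  v <- raster$values; cs <- raster$cellsize
  gx <- (x - raster$xll) / cs + 1  # fractional column
  gy <- (y - raster$yll) / cs + 1  # fractional row
  if (any(gx < 1 - 1e-9 | gx > ncol(v) + 1e-9 | gy < 1 - 1e-9 | gy > nrow(v) + 1e-9))
    stopf("point outside raster extent")
  gx <- pmin(pmax(gx, 1), ncol(v)); gy <- pmin(pmax(gy, 1), nrow(v))
  c0 <- pmin(floor(gx), ncol(v) - 1L); c0[ncol(v) == 1L] <- 1L
  r0 <- pmin(floor(gy), nrow(v) - 1L); r0[nrow(v) == 1L] <- 1L
  c1 <- pmin(c0 + 1L, ncol(v)); r1 <- pmin(r0 + 1L, nrow(v))
  tx <- gx - c0; ty <- gy - r0
  v[cbind(r0, c0)] * (1 - tx) * (1 - ty) + v[cbind(r0, c1)] * tx * (1 - ty) +
    v[cbind(r1, c0)] * (1 - tx) * ty + v[cbind(r1, c1)] * tx * ty
}

#' Relief along a straight line over a DEM
#'
#' Samples elevations by bilinear interpolation at points spaced at most
#' `step` apart along the straight line between two points (endpoints
#' included) and returns the elevational difference between the highest and
#' lowest sampled point.
#'
#' @param raster an `elevation_raster`.
#' @param p_start,p_end numeric length-2 vectors `c(x, y)` in metres.
#' @param step sampling interval (m); defaults to the raster cell size.
#' @return relief in metres (max - min along the profile).
#' @export
line_relief <- function(raster, p_start, p_end, step = raster$cellsize) {
  if (step <= 0) stopf("step must be > 0")
  L <- sqrt(sum((p_end - p_start)^2))
  k <- max(1L, ceiling(L / step))
  t <- seq(0, 1, length.out = k + 1L)
  z <- raster_interpolate(raster, p_start[1] + t * (p_end[1] - p_start[1]),
                          p_start[2] + t * (p_end[2] - p_start[2]))
  max(z) - min(z)
}

#' Overland altitudinal distances between sites
#'
#' For every site pair, the relief (highest minus lowest elevation) along
#' the straight line between the sites, sampled from the DEM with
#' [line_relief()]. Always at least `|elevation_i - elevation_j|`.
#'
#' @param network a `stream_network`.
#' @param raster an `elevation_raster` covering all sites.
#' @param step profile sampling interval (m); default raster cell size.
#' @return a symmetric `dendro_dist` matrix, `dist_type = "overland_alt"`.
#' @export
overland_altitudinal_matrix <- function(network, raster, step = raster$cellsize) {
  si <- site_index(network)
  ids <- site_ids(network)
  xy <- as.matrix(network$nodes[si, c("x", "y")])
  n <- length(si)
  m <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    m[a, b] <- m[b, a] <- line_relief(raster, xy[a, ], xy[b, ], step)
  new_dist_matrix(m, ids, "overland_alt")
}
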