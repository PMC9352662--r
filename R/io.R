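# Plain-text spatial I/O: ESRI ASCII grids for rasters, GeoJSON for range
# polygons, CSV for tables, JSON manifests.

#' Write a cell-value vector as an ESRI ASCII grid
#'
#' North-up, row-major from the north-west corner, matching the grid
#' convention used throughout. Missing values are written as the nodata
#' sentinel, never zero.
#'
#' @param values Numeric vector of length `grid$n_cells` (or a `pe_layer`).
#' @param grid A [grid_spec()].
#' @param path Output path (`.asc`).
#' @param nodata Nodata sentinel value.
#' @export
write_asc <- function(values, grid, path, nodata = -9999) {
  if (inherits(values, "pe_layer")) values <- values$values
  assert_grid(grid)
  stopifnot(length(values) == grid$n_cells)
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           "xllcorner -180", "yllcorner -90",
           sprintf("cellsize %.10g", grid$resolution),
           sprintf("NODATA_value %g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  writeLines(hdr, path)
  m <- matrix(v, nrow = grid$n_rows, byrow = TRUE)
  data.table::fwrite(as.data.frame(m), path, append = TRUE, sep = " ",
                     col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_asc()]
#'
#' @param path Input path.
#' @return List with `values` (NA where nodata) and `grid`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("raster file not found: %s", path), call. = FALSE)
  }
  hdr <- strsplit(readLines(path, n = 6L), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, "", 2), vapply(hdr, `[`, "", 1))
  grid <- grid_spec(as.numeric(kv[["cellsize"]]))
  nodata <- as.numeric(kv[["NODATA_value"]])
  m <- data.table::fread(path, skip = 6L, sep = " ", header = FALSE)
  vals <- as.vector(t(as.matrix(m)))
  stopifnot(length(vals) == grid$n_cells)
  vals[vals == nodata] <- NA
  list(values = vals, grid = grid)
}

#' Write range polygons as a GeoJSON FeatureCollection
#'
#' One feature per seasonal polygon with properties `species_id`,
#' `seasonal`, `presence`, `origin`.
#'
#' @param ranges Named list (species_id) of polygon lists.
#' @param path Output path (`.geojson`).
#' @return Invisibly, the number of features written.
#' @export
write_ranges_geojson <- function(ranges, path) {
  feats <- list()
  for (sid in names(ranges)) {
    for (p in ranges[[sid]]) {
      ring <- rbind(p$coords, p$coords[1, , drop = FALSE])
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(species_id = sid, seasonal = p$seasonal,
                          presence = p$presence, origin = p$origin),
        geometry = list(type = "Polygon",
                        coordinates = list(unname(
                          lapply(seq_len(nrow(ring)), function(i)
                            as.numeric(ring[i, ]))))))
    }
  }
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 10), path)
  invisible(length(feats))
}

#' Read a GeoJSON FeatureCollection written by [write_ranges_geojson()]
#' @param path Input path.
#' @return Named list (species_id) of polygon lists.
#' @export
read_ranges_geojson <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("GeoJSON file not found: %s", path), call. = FALSE)
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (f in gj$features) {
    sid <- f$properties$species_id
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring <- ring[-nrow(ring), , drop = FALSE]   # drop closing vertex
    colnames(ring) <- c("lon", "lat")
    poly <- list(coords = ring, seasonal = f$properties$seasonal,
                 presence = f$properties$presence,
                 origin = f$properties$origin)
    out[[sid]] <- c(out[[sid]], list(poly))
  }
  out
}

#' Write a synthetic world to disk
#'
#' Layers as ESRI ASCII grids under `layers/`, ranges as GeoJSON, species
#' and occurrences as CSV, plus a JSON manifest recording the seed and
#' generation parameters.
#'
#' @param world A [generate_world()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_world <- function(world, outdir) {
  stopifnot(inherits(world, "pe_world"))
  dir.create(file.path(outdir, "layers"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    stop(sprintf("cannot create output directory: %s", outdir),
         call. = FALSE)
  }
  layer_files <- character(0)
  for (l in world$layers) {
    f <- file.path(outdir, "layers", paste0(l$name, ".asc"))
    write_asc(l, world$grid, f)
    layer_files[l$name] <- f
  }
  n_feat <- write_ranges_geojson(world$ranges,
                                 file.path(outdir, "ranges.geojson"))
  data.table::fwrite(world$species, file.path(outdir, "species.csv"))
  data.table::fwrite(world$occurrences,
                     file.path(outdir, "occurrences.csv"))
  rc <- data.table::data.table(
    species_id = rep(names(world$range_cells),
                     lengths(world$range_cells)),
    cell = unlist(world$range_cells, use.names = FALSE))
  data.table::fwrite(rc, file.path(outdir, "range_cells.csv"))
  manifest <- list(
    seed = world$seed,
    params = world$params,
    layer_kinds = as.list(vapply(world$layers, `[[`, "", "kind")),
    n_species = nrow(world$species),
    n_geojson_features = n_feat,
    files = c(layers = unname(layer_files),
              file.path(outdir, c("ranges.geojson", "species.csv",
                                  "occurrences.csv", "range_cells.csv"))))
  mp <- file.path(outdir, "world_manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE), mp)
  invisible(mp)
}

#' Read a world written by [write_world()]
#' @param outdir Directory passed to [write_world()].
#' @return A `pe_world`-like list (float32-precision-equivalent values).
#' @export
read_world <- function(outdir) {
  mp <- file.path(outdir, "world_manifest.json")
  if (!file.exists(mp)) {
    stop(sprintf("world manifest not found in %s", outdir), call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(mp)
  first <- read_asc(list.files(file.path(outdir, "layers"),
                               full.names = TRUE, pattern = "\\.asc$")[1])
  grid <- first$grid
  kinds <- manifest$layer_kinds
  layers <- lapply(names(kinds), function(nm) {
    v <- read_asc(file.path(outdir, "layers", paste0(nm, ".asc")))$values
    stressor_layer(nm, v, kinds[[nm]], grid)
  })
  names(layers) <- names(kinds)
  species <- as.data.frame(data.table::fread(
    file.path(outdir, "species.csv")))
  occurrences <- as.data.frame(data.table::fread(
    file.path(outdir, "occurrences.csv")))
  rc <- data.table::fread(file.path(outdir, "range_cells.csv"))
  range_cells <- split(rc$cell, rc$species_id)
  ranges <- read_ranges_geojson(file.path(outdir, "ranges.geojson"))
  structure(list(grid = grid, layers = layers, species = species,
                 ranges = ranges,
                 range_cells = range_cells[species$species_id],
                 occurrences = occurrences,
                 params = manifest$params, seed = manifest$seed),
            class = "pe_world")
}
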