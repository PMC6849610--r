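## Equal-area grid geometry: Behrmann projection, cell indexing, and the
## distance-to-range-edge metric D0 / D'.

# row/col <-> cell_id encoding; ranges are generous for any earth model
.ROW_OFF <- 512L
.COL_OFF <- 2048L
.ROW_MULT <- 4096L

# geodesic distances use a sphere with the IUGG mean earth radius
.GC_RADIUS_KM <- 6371.0088

#' Behrmann equal-area grid specification
#'
#' Defines the cylindrical equal-area (Behrmann, standard parallel 30
#' degrees) grid used to aggregate point records.  All cells are squares of
#' `cell_edge_km` on the projected plane, so all have identical area; cell
#' bounding boxes are half-open (`[x0, x0 + edge)`), which makes the cells a
#' partition of the plane and sends points on a shared edge to the
#' higher-index cell.
#'
#' @param cell_edge_km cell edge length in km.  The default 48.24 km
#'   corresponds to a 30-arc-minute resolution at the standard parallel.
#' @param radius_km radius of the spherical earth model used by the
#'   projection, in km.
#' @param origin projected (x, y) coordinate, in km, of the corner shared by
#'   cells (0, 0) and (-1, -1).  Cell boundaries fall at
#'   `origin + k * cell_edge_km`.
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec()
#' project_point(0, 0, g)
#' @export
grid_spec <- function(cell_edge_km = 48.24, radius_km = 6378.137,
                      origin = c(0, 0)) {
  stopifnot(is.numeric(cell_edge_km), length(cell_edge_km) == 1L,
            cell_edge_km > 0, is.numeric(radius_km), radius_km > 0,
            is.numeric(origin), length(origin) == 2L)
  structure(list(cell_edge_km = cell_edge_km, radius_km = radius_km,
                 origin = as.numeric(origin),
                 cos_sp = cos(pi / 6)),   # cos(30 deg)
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Behrmann equal-area grid: %.2f km cells, earth radius %.3f km\n",
              x$cell_edge_km, x$radius_km))
  invisible(x)
}

.check_lonlat <- function(lon, lat) {
  bad <- !is.finite(lon) | !is.finite(lat) | lat < -90 | lat > 90 |
    lon < -180 | lon > 180
  if (any(bad))
    stop("invalid coordinates at record(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "),
         if (sum(bad) > 5L) " ..." else "",
         " (need lat in [-90, 90], lon in [-180, 180])")
  invisible(TRUE)
}

#' Project lon/lat to Behrmann x/y (km)
#'
#' Closed-form cylindrical equal-area projection with standard parallel 30
#' degrees: `x = R * lambda * cos(30)`, `y = R * sin(phi) / cos(30)`.
#'
#' @param lon,lat coordinates in decimal degrees (vectors allowed).
#' @param grid a [grid_spec()].
#' @return a two-column matrix of projected coordinates in km.
#' @export
project_point <- function(lon, lat, grid = grid_spec()) {
  .check_lonlat(lon, lat)
  R <- grid$radius_km
  cbind(x = R * (lon * pi / 180) * grid$cos_sp,
        y = R * sin(lat * pi / 180) / grid$cos_sp)
}

#' Inverse Behrmann projection
#'
#' @param x,y projected coordinates in km.
#' @inheritParams project_point
#' @return a two-column matrix of lon/lat in degrees.
#' @export
unproject_point <- function(x, y, grid = grid_spec()) {
  R <- grid$radius_km
  s <- y * grid$cos_sp / R
  if (any(abs(s) > 1 + 1e-12)) stop("y outside projection extent")
  s <- pmin(1, pmax(-1, s))
  cbind(lon = (x / (R * grid$cos_sp)) * 180 / pi,
        lat = asin(s) * 180 / pi)
}

#' Encode grid (row, col) as a cell id
#'
#' The encoding is a bijection between (row, col) pairs and positive
#' integers for all rows/cols reachable on Earth at the default resolution.
#'
#' @param row,col integer cell indices (row = floor(y / edge), col =
#'   floor(x / edge), relative to the grid origin).
#' @return integer cell ids.
#' @export
cell_id_from_rowcol <- function(row, col) {
  row <- as.integer(row); col <- as.integer(col)
  stopifnot(all(row > -.ROW_OFF & row < .ROW_OFF),
            all(col >= -.COL_OFF & col < .COL_OFF))
  (row + .ROW_OFF) * .ROW_MULT + (col + .COL_OFF)
}

#' Decode a cell id back to (row, col)
#'
#' @param cell_id integer cell ids from [cell_id_from_rowcol()].
#' @return a two-column integer matrix with columns `row`, `col`.
#' @export
cell_rowcol <- function(cell_id) {
  cell_id <- as.integer(cell_id)
  row <- cell_id %/% .ROW_MULT - .ROW_OFF
  col <- cell_id %% .ROW_MULT - .COL_OFF
  cbind(row = row, col = col)
}

#' Assign projected points / records to grid cells
#'
#' Each point falls in exactly one half-open cell bounding box
#' `[x0, x0 + edge) x [y0, y0 + edge)`; points on shared edges therefore go
#' to the higher-index cell.
#'
#' @inheritParams project_point
#' @return integer vector of cell ids.
#' @export
point_to_cell <- function(lon, lat, grid = grid_spec()) {
  xy <- project_point(lon, lat, grid)
  col <- floor((xy[, 1] - grid$origin[1]) / grid$cell_edge_km)
  row <- floor((xy[, 2] - grid$origin[2]) / grid$cell_edge_km)
  cell_id_from_rowcol(row, col)
}

#' Projected bounding box of cells
#'
#' @param cell_id integer cell ids.
#' @inheritParams project_point
#' @return matrix with columns `x0, y0, x1, y1` (km); boxes are half-open.
#' @export
cell_bbox <- function(cell_id, grid = grid_spec()) {
  rc <- cell_rowcol(cell_id)
  e <- grid$cell_edge_km
  x0 <- grid$origin[1] + rc[, "col"] * e
  y0 <- grid$origin[2] + rc[, "row"] * e
  cbind(x0 = x0, y0 = y0, x1 = x0 + e, y1 = y0 + e)
}

#' Cell centroids in lon/lat
#'
#' Centroid of the projected bounding box, inverse-projected to degrees.
#'
#' @inheritParams cell_bbox
#' @return two-column matrix of lon/lat in degrees.
#' @export
cell_centroid <- function(cell_id, grid = grid_spec()) {
  bb <- cell_bbox(cell_id, grid)
  unproject_point((bb[, "x0"] + bb[, "x1"]) / 2,
                  (bb[, "y0"] + bb[, "y1"]) / 2, grid)
}

#' Great-circle distance between points (km)
#'
#' Haversine formula on a sphere of radius 6371.0088 km.  Used for the
#' inter-centroid distances underlying D0: geodesic distances are
#' independent of the map projection.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorized).
#' @return distances in km.
#' @export
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * .GC_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

## ---- species range cell sets and D0 / D' ---------------------------------

#' Build a species' occupied-range cell set
#'
#' The range is the union of cells holding at least one native record and
#' cells supplied from a range polygon (pre-intersected with the grid).
#' Non-native records contribute no range cells.
#'
#' @param records data frame with at least `cell_id` and `native` (logical)
#'   for one species; may be empty.
#' @param polygon_cells integer vector of cell ids from the species' range
#'   polygon (may be empty).
#' @param species_id species identifier.
#' @return integer vector of cell ids (sorted, unique).
#' @export
build_range_cells <- function(records, polygon_cells = integer(0),
                              species_id = NULL) {
  rec_cells <- integer(0)
  if (!is.null(records) && nrow(records) > 0) {
    native <- if ("native" %in% names(records)) records$native else TRUE
    rec_cells <- records$cell_id[as.logical(native)]
  }
  cells <- sort(unique(as.integer(c(rec_cells, polygon_cells))))
  if (length(cells) == 0L)
    stop("species ", species_id,
         ": no native record cells and no polygon cells; range is empty")
  cells
}

#' Geometric-mean distance to the rest of the range (D0)
#'
#' For each cell of a species' range, D0 is the geometric mean of the
#' great-circle distances from that cell's centroid to the centroids of all
#' *other* cells of the range.  A cell's own (zero) distance is excluded --
#' including it would annihilate the geometric mean.  For a single-cell
#' range D0 is undefined (`NA`); [standardize_Dprime()] assigns such ranges
#' D' = 1 directly, treating tiny ranges as all edge.
#'
#' @param cells integer vector of range cell ids.
#' @inheritParams project_point
#' @return named numeric vector of D0 in km (NA for a single-cell range).
#' @export
compute_D0 <- function(cells, grid = grid_spec()) {
  cells <- as.integer(cells)
  n <- length(cells)
  if (n == 0L) stop("empty range")
  if (n == 1L) return(stats::setNames(NA_real_, cells))
  cc <- cell_centroid(cells, grid)
  lon <- cc[, "lon"] * pi / 180
  lat <- cc[, "lat"] * pi / 180
  # pairwise haversine on the unit sphere, vectorized via outer products
  sl <- sin(lat); cl <- cos(lat)
  # central angle: cos(theta) = sin a sin b + cos a cos b cos(dlon)
  cosang <- tcrossprod(sl) + tcrossprod(cl) * cos(outer(lon, lon, "-"))
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  d <- .GC_RADIUS_KM * acos(cosang)
  diag(d) <- 0        # guard against acos(1 - eps) on the diagonal
  off <- d[row(d) != col(d)]
  if (any(off <= 0))
    stop("duplicate cell centroids in range (zero inter-cell distance); ",
         "grid malformed or repeated cell ids")
  logd <- log(d + diag(1, n))        # diag placeholder, excluded below
  D0 <- exp((rowSums(logd)) / (n - 1))   # log(1) = 0 on the diagonal
  stats::setNames(D0, cells)
}

#' Standardize D0 to the edge score D'
#'
#' D' = D0 / max(D0) within a species, so the farthest-out cell(s) score
#' exactly 1 and all cells score in (0, 1].  Values near 1 mark cells near
#' the range edge.  Single-cell ranges (D0 undefined) get D' = 1.
#'
#' @param D0 named numeric vector from [compute_D0()].
#' @return named numeric vector of D' in (0, 1].
#' @export
standardize_Dprime <- function(D0) {
  if (length(D0) == 1L && is.na(D0[1L]))
    return(stats::setNames(1, names(D0)))
  if (any(!is.finite(D0) | D0 <= 0)) stop("D0 must be positive and finite")
  D0 / max(D0)
}

#' Per-species range table with D0, D' and cell covariates
#'
#' Convenience wrapper producing the standard long-format table
#' (species_id, cell_id, D0_km, Dprime, R, C) for a set of species ranges.
#'
#' @param ranges named list of integer cell-id vectors, one per species.
#' @param cell_attr data frame with columns `cell_id`, `realm` (0/1) and
#'   either `C` or `converted_fraction`.
#' @inheritParams project_point
#' @return data frame with one row per species:cell pair.
#' @export
range_covariates <- function(ranges, cell_attr, grid = grid_spec()) {
  stopifnot(is.list(ranges), !is.null(names(ranges)))
  if (!"C" %in% names(cell_attr))
    cell_attr$C <- classify_conversion(cell_attr$converted_fraction)
  out <- lapply(names(ranges), function(sid) {
    cells <- ranges[[sid]]
    D0 <- compute_D0(cells, grid)
    Dp <- standardize_Dprime(D0)
    m <- match(cells, cell_attr$cell_id)
    data.frame(species_id = sid, cell_id = cells,
               D0_km = as.numeric(D0), Dprime = as.numeric(Dp),
               R = cell_attr$realm[m], C = cell_attr$C[m],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify land-conversion status of a cell
#'
#' A cell is human-dominated (C = 1) when strictly more than one-third of
#' its land was converted for human use; exactly one-third classifies as
#' unconverted (the underlying fragmentation literature phrases the
#' threshold as exceedance of ~30%).
#'
#' @param converted_fraction proportion(s) in \[0, 1\].
#' @return integer vector of 0 (unconverted) / 1 (human-dominated).
#' @export
classify_conversion <- function(converted_fraction) {
  if (any(!is.finite(converted_fraction) | converted_fraction < 0 |
          converted_fraction > 1))
    stop("converted_fraction must lie in [0, 1]")
  as.integer(converted_fraction > 1 / 3)
}

#' Assign cells to a biogeographic realm code
#'
#' Maps realm labels to the model's indicator coding: 0 for the Palearctic,
#' 1 for Indo-Malaya.  Cells with an unrecognized or missing label get `NA`
#' with a warning; callers should exclude them.
#'
#' @param labels character (or 0/1 numeric) realm labels per cell.
#' @return integer vector of realm codes (0, 1 or NA).
#' @export
assign_realm <- function(labels) {
  if (is.numeric(labels)) {
    out <- as.integer(labels)
    out[!out %in% c(0L, 1L)] <- NA_integer_
  } else {
    key <- gsub("[^a-z]", "", tolower(as.character(labels)))
    out <- rep(NA_integer_, length(labels))
    out[key %in% c("palearctic", "palaearctic", "pa")] <- 0L
    out[key %in% c("indomalaya", "indomalay", "indomalayan", "im")] <- 1L
  }
  if (anyNA(out))
    warning(sum(is.na(out)), " cell(s) in neither realm; exclude them")
  out
}
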