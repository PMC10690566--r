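#' Construct a labeled region
#'
#' Regions segment the field of view: closed polygons for `cell`, `speck`,
#' `roi` and `background` labels, and open polylines for `filament_backbone`.
#' Vertices are in nm, image convention (y downward).
#'
#' @param label One of `"cell"`, `"speck"`, `"roi"`, `"background"`,
#'   `"filament_backbone"`.
#' @param vertices Two-column matrix (x, y) of vertices in nm. Closed
#'   polygons must not repeat the first vertex.
#' @param cell_id,day_id Optional identifiers attached to the region.
#'
#' @return A list of class `region`.
#' @export
region <- function(label, vertices, cell_id = NA, day_id = NA) {
  label <- match.arg(label,
                     c("cell", "speck", "roi", "background", "filament_backbone"))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must be a two-column (x, y) matrix")
  storage.mode(vertices) <- "double"
  if (any(!is.finite(vertices))) stop("region vertices must be finite")
  closed <- label != "filament_backbone"
  if (closed && nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  if (!closed && nrow(vertices) < 2L) stop("a polyline needs at least 2 vertices")
  structure(list(label = label, vertices = vertices, closed = closed,
                 cell_id = cell_id, day_id = day_id),
            class = "region")
}

#' Bundle regions into a region set
#'
#' @param ... `region` objects, or a single list of them.
#' @return A list of class `region_set`.
#' @export
region_set <- function(...) {
  regs <- list(...)
  if (length(regs) == 1L && !inherits(regs[[1L]], "region")) regs <- regs[[1L]]
  stopifnot(all(vapply(regs, inherits, logical(1), "region")))
  structure(regs, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  lab <- vapply(x, `[[`, character(1), "label")
  cat(sprintf("<region_set> %d regions (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(lab)), table(lab)),
                    collapse = ", ")))
  invisible(x)
}

regions_with_label <- function(rs, label, cell_id = NULL) {
  keep <- vapply(rs, function(r) {
    r$label == label && (is.null(cell_id) || identical(r$cell_id, cell_id) ||
                           (is.numeric(r$cell_id) && is.numeric(cell_id) &&
                              r$cell_id == cell_id))
  }, logical(1))
  region_set(unclass(rs)[keep])
}

#' Signed polygon area (shoelace)
#'
#' @param vertices Two-column vertex matrix in nm.
#' @return Absolute enclosed area in square micrometres.
#' @export
polygon_area_um2 <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])) / 2 / 1e6
}

#' Area of a region in square micrometres
#' @param reg A closed `region`.
#' @export
region_area_um2 <- function(reg) {
  if (!reg$closed) stop("a polyline has no area")
  polygon_area_um2(reg$vertices)
}

# Vectorized even-odd ray casting with boundary points counted inside.
# Points within `tol` of an edge are inside by convention.
point_in_polygon <- function(px, py, vertices, tol = 1e-9) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  inside <- logical(length(px))
  boundary <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]; xj <- v[j, 1L]; yj <- v[j, 2L]
    # boundary test: distance from point to segment
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2)) else 0
    ddx <- px - (xi + t * dx); ddy <- py - (yi + t * dy)
    boundary <- boundary | (ddx * ddx + ddy * ddy <= tol * tol)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | boundary
}

#' Select localizations inside a closed region
#'
#' Point-in-polygon membership by even-odd ray casting. Points on the polygon
#' boundary count as inside (deterministic tie-break; documented convention).
#'
#' @param table A [loc_table].
#' @param reg A closed `region` (polygons only; backbones have no interior).
#' @return The subset of `table` strictly inside (or on) the polygon.
#' @export
select_in_region <- function(table, reg) {
  if (inherits(reg, "region_set")) {
    if (length(reg) != 1L) stop("pass a single region")
    reg <- reg[[1L]]
  }
  if (!reg$closed) stop("region is a polyline, not an area")
  if (!nrow(table)) return(table)
  # bounding-box prefilter, then exact polygon test on the candidates
  xr <- range(reg$vertices[, 1L]); yr <- range(reg$vertices[, 2L])
  cand <- which(table$x >= xr[1L] & table$x <= xr[2L] &
                  table$y >= yr[1L] & table$y <= yr[2L])
  if (!length(cand)) return(table[0L, , drop = FALSE])
  keep <- cand[point_in_polygon(table$x[cand], table$y[cand], reg$vertices)]
  table[keep, , drop = FALSE]
}

#' Select cytoplasmic localizations (cell minus speck)
#'
#' The cytoplasm is defined as the set difference of the cell polygon and the
#' speck polygon(s) belonging to it.
#'
#' @param table A [loc_table].
#' @param cell_region Closed cell `region`.
#' @param speck_regions Optional `region_set` (or single region) of specks to
#'   exclude; `NULL` for unstimulated cells.
#' @return List with `table` (cytoplasmic localizations) and `area_um2`
#'   (cell area minus speck areas).
#' @export
select_cytoplasm <- function(table, cell_region, speck_regions = NULL) {
  inside <- select_in_region(table, cell_region)
  area <- region_area_um2(cell_region)
  if (!is.null(speck_regions)) {
    if (inherits(speck_regions, "region")) speck_regions <- region_set(list(speck_regions))
    for (sp in speck_regions) {
      if (nrow(inside)) {
        drop <- point_in_polygon(inside$x, inside$y, sp$vertices)
        inside <- inside[!drop, , drop = FALSE]
      }
      area <- area - region_area_um2(sp)
    }
  }
  list(table = inside, area_um2 = max(area, 0))
}

#' Read a region set from a JSON document
#'
#' Schema: a top-level object with a `regions` array; each entry has
#' `label`, `vertices` (array of `[x, y]` nm pairs) and optional `cell_id`,
#' `day_id`.
#'
#' @param path JSON file path.
#' @return A [region_set].
#' @export
read_regions <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$regions)) stop("ROI document has no 'regions' entry")
  regs <- doc$regions
  if (is.data.frame(regs)) regs <- split(regs, seq_len(nrow(regs)))
  region_set(lapply(regs, function(r) {
    v <- r$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    if (is.data.frame(v)) v <- as.matrix(v)
    if (is.list(r$vertices) && length(r$vertices) == 1L) v <- r$vertices[[1L]]
    region(r$label[[1L]], matrix(as.numeric(v), ncol = 2L),
           cell_id = if (!is.null(r$cell_id)) r$cell_id[[1L]] else NA,
           day_id = if (!is.null(r$day_id)) r$day_id[[1L]] else NA)
  }))
}

#' Write a region set to a JSON document
#' @param rs A [region_set].
#' @param path Output path.
#' @export
write_regions <- function(rs, path) {
  doc <- list(regions = lapply(rs, function(r) {
    list(label = r$label, cell_id = r$cell_id, day_id = r$day_id,
         vertices = unname(apply(r$vertices, 1L, as.list, simplify = FALSE)))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Regular polygon approximating a circle; used by the generator and tests.
circle_region <- function(label, cx, cy, radius, n = 64L, cell_id = NA,
                          day_id = NA) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  region(label, cbind(cx + radius * cos(th), cy + radius * sin(th)),
         cell_id = cell_id, day_id = day_id)
}
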