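#' Spatial units
#'
#' A spatial unit is an identified polygon (or multipolygon) in a planar
#' coordinate system. Geometry is stored as a list of rings, each ring a
#' two-column coordinate matrix; multipolygon parts are additional rings.
#' Geometry may be omitted when the contiguity structure is supplied as an
#' edge list instead.
#'
#' @param unit_id Character scalar, unique within a dataset.
#' @param geometry A two-column numeric matrix (one ring) or a list of such
#'   matrices (multiple rings / multipolygon parts), or `NULL`.
#' @return An object of class `spatial_unit`.
#' @export
spatial_unit <- function(unit_id, geometry = NULL) {
  stopifnot(is.character(unit_id), length(unit_id) == 1L, nzchar(unit_id))
  if (!is.null(geometry)) {
    if (is.matrix(geometry)) geometry <- list(geometry)
    geometry <- lapply(geometry, repair_ring, unit_id = unit_id)
  }
  structure(list(unit_id = unit_id, geometry = geometry),
            class = "spatial_unit")
}

# Drop consecutive duplicate vertices and an explicit closing vertex; the
# ring is treated as implicitly closed. Rejects rings that are degenerate
# after this repair.
repair_ring <- function(ring, unit_id) {
  if (!is.matrix(ring) || ncol(ring) != 2L || !is.numeric(ring))
    stop("unit '", unit_id, "': ring must be a two-column numeric matrix")
  if (anyNA(ring) || any(!is.finite(ring)))
    stop("invalid geometry for unit '", unit_id, "': non-finite coordinates")
  n <- nrow(ring)
  if (n > 1L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) < 3L)
    stop("invalid geometry for unit '", unit_id,
         "': fewer than 3 distinct vertices after repair")
  ring
}

#' @export
print.spatial_unit <- function(x, ...) {
  nv <- if (is.null(x$geometry)) 0L else sum(vapply(x$geometry, nrow, 0L))
  cat("<spatial_unit ", x$unit_id, ": ",
      if (is.null(x$geometry)) "no geometry" else
        paste0(length(x$geometry), " ring(s), ", nv, " vertices"),
      ">\n", sep = "")
  invisible(x)
}

new_contiguity_graph <- function(vertices, edge_idx) {
  n <- length(vertices)
  adj <- rep(list(integer(0)), n)
  m <- 0L
  if (NROW(edge_idx) > 0L) {
    a <- pmin(edge_idx[, 1L], edge_idx[, 2L])
    b <- pmax(edge_idx[, 1L], edge_idx[, 2L])
    keep <- !duplicated(a * (n + 1) + b)
    a <- a[keep]; b <- b[keep]
    o <- order(a, b)
    a <- a[o]; b <- b[o]
    m <- length(a)
    adj <- unname(split(c(b, a), factor(c(a, b), levels = seq_len(n))))
    adj <- lapply(adj, function(v) sort(unique(v)))
    edge_idx <- cbind(a, b)
  } else {
    edge_idx <- matrix(integer(0), 0L, 2L)
  }
  structure(list(vertices = vertices,
                 edge_idx = edge_idx,
                 adj = adj,
                 degree = lengths(adj)),
            class = "contiguity_graph")
}

#' @export
print.contiguity_graph <- function(x, ...) {
  cat("<contiguity_graph: ", length(x$vertices), " vertices, ",
      nrow(x$edge_idx), " edges>\n", sep = "")
  invisible(x)
}

#' Edges of a contiguity graph
#'
#' @param g A `contiguity_graph`.
#' @return A two-column character matrix of unit-id pairs (each row sorted
#'   by vertex position, one row per undirected edge).
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "contiguity_graph"))
  cbind(src = g$vertices[g$edge_idx[, 1L]],
        dst = g$vertices[g$edge_idx[, 2L]])
}

#' Neighbor map of a contiguity graph
#'
#' @param g A `contiguity_graph`.
#' @return Named list mapping each unit id to the character vector of its
#'   neighbors' ids.
#' @export
neighbor_map <- function(g) {
  stopifnot(inherits(g, "contiguity_graph"))
  stats::setNames(lapply(g$adj, function(i) g$vertices[i]), g$vertices)
}

# Snap coordinates to a tolerance grid and key them as strings so that
# vertices shared between polygons compare exactly.
vertex_keys <- function(ring, snap_tolerance) {
  if (snap_tolerance > 0) ring <- round(ring / snap_tolerance) * snap_tolerance
  sprintf("%.12g|%.12g", ring[, 1L], ring[, 2L])
}

segment_keys <- function(vkeys) {
  nxt <- c(vkeys[-1L], vkeys[1L])
  paste(pmin(vkeys, nxt), pmax(vkeys, nxt), sep = "~")
}

#' Build a contiguity graph from polygon geometries
#'
#' Detects neighbors by the classical chess metaphors: rook contiguity links
#' units whose boundaries share a positive-length stretch (a common segment),
#' bishop contiguity links units that touch only at isolated points (common
#' vertices but no common segment), and queen contiguity is their union.
#' Detection operates on the polygons' vertex and segment sets after snapping
#' coordinates to `snap_tolerance`, so shared boundaries must be topologically
#' noded (they share vertices, as census geometries and the synthetic grid
#' do). Multipolygon units are neighbors if any of their parts touch.
#' Units with no neighbors are retained as isolates.
#'
#' @param units List of [spatial_unit()] objects, all with geometries.
#' @param rule One of `"queen"`, `"rook"`, `"bishop"`.
#' @param snap_tolerance Coordinates are snapped to this grid before
#'   comparison; `0` (default) compares exactly.
#' @return A `contiguity_graph` with vertices in input order.
#' @export
build_contiguity_graph <- function(units, rule = c("queen", "rook", "bishop"),
                                   snap_tolerance = 0) {
  rule <- match.arg(rule)
  stopifnot(length(units) >= 2L, snap_tolerance >= 0)
  ids <- vapply(units, function(u) u$unit_id, "")
  if (anyDuplicated(ids))
    stop("duplicate unit_id: ", ids[duplicated(ids)][1L])
  no_geom <- vapply(units, function(u) is.null(u$geometry), TRUE)
  if (any(no_geom))
    stop("unit '", ids[no_geom][1L],
         "' has no geometry; edge list required")
  n <- length(units)
  vk <- lapply(units, function(u)
    unique(unlist(lapply(u$geometry, vertex_keys, snap_tolerance))))
  sk <- lapply(units, function(u)
    unique(unlist(lapply(u$geometry, function(r)
      segment_keys(vertex_keys(r, snap_tolerance))))))

  # candidate pairs: units sharing at least one snapped vertex
  owner <- data.frame(key = unlist(vk),
                      unit = rep.int(seq_len(n), lengths(vk)))
  grp <- split(owner$unit, owner$key)
  grp <- grp[lengths(grp) > 1L]
  pairs <- unique(do.call(rbind, lapply(grp, function(u) {
    u <- sort(unique(u))
    if (length(u) < 2L) return(NULL)
    t(utils::combn(u, 2L))
  })))
  edge_idx <- matrix(integer(0), 0L, 2L)
  if (NROW(pairs) > 0L) {
    shares_segment <- vapply(seq_len(nrow(pairs)), function(r)
      any(sk[[pairs[r, 1L]]] %in% sk[[pairs[r, 2L]]]), TRUE)
    keep <- switch(rule,
                   queen  = rep(TRUE, nrow(pairs)),
                   rook   = shares_segment,
                   bishop = !shares_segment)
    edge_idx <- pairs[keep, , drop = FALSE]
  }
  new_contiguity_graph(ids, edge_idx)
}

#' Build a contiguity graph from an explicit edge list
#'
#' Duplicate and reversed pairs are collapsed to a single undirected edge.
#'
#' @param edges Two-column character matrix or data frame of unit-id pairs.
#' @param vertices Optional character vector fixing vertex order (and
#'   including isolates); defaults to the ids in order of first appearance.
#' @return A `contiguity_graph`.
#' @export
graph_from_edgelist <- function(edges, vertices = NULL) {
  edges <- as.matrix(edges)
  if (NROW(edges) > 0L) storage.mode(edges) <- "character"
  stopifnot(ncol(edges) == 2L || NROW(edges) == 0L)
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loop edge: ", edges[edges[, 1L] == edges[, 2L], 1L][1L])
  if (is.null(vertices))
    vertices <- unique(as.vector(t(edges)))
  else if (!all(edges %in% vertices))
    stop("edge references unknown unit_id")
  idx <- matrix(match(edges, vertices), ncol = 2L)
  new_contiguity_graph(vertices, idx)
}

#' Summary statistics of a contiguity graph
#'
#' Average node degree `k = 2m/n` and undirected density `d = 2m/(n(n-1))`,
#' reported at full precision together with display-rounded versions
#' (3 decimals for `k`, 3 significant digits for `d`).
#'
#' @param g A `contiguity_graph` with at least 2 vertices.
#' @return A list of class `graph_stats` with fields `n`, `m`, `avg_degree`,
#'   `density`, `avg_degree_display`, `density_display`.
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "contiguity_graph"))
  n <- length(g$vertices)
  if (n < 2L) stop("density undefined for n < 2")
  m <- nrow(g$edge_idx)
  k <- 2 * m / n
  d <- 2 * m / (n * (n - 1))
  structure(list(n = n, m = m, avg_degree = k, density = d,
                 avg_degree_display = round(k, 3),
                 density_display = signif(d, 3)),
            class = "graph_stats")
}

#' @export
print.graph_stats <- function(x, ...) {
  cat("n = ", x$n, ", m = ", x$m,
      ", k = ", x$avg_degree_display,
      ", d = ", x$density_display, "\n", sep = "")
  invisible(x)
}

#' Read spatial units from a GeoJSON file
#'
#' Accepts Polygon and MultiPolygon features in a planar coordinate system.
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @param id_property Name of the feature property holding the unit id.
#' @return List of [spatial_unit()] objects in feature order.
#' @export
read_units_geojson <- function(path, id_property = "unit_id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats)) stop("not a GeoJSON FeatureCollection: ", path)
  lapply(feats, function(f) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature lacks property '", id_property, "'")
    geom <- f$geometry
    ring_mat <- function(ring)
      matrix(unlist(ring), ncol = 2L, byrow = TRUE)
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates, function(part)
        lapply(part, ring_mat)), recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    spatial_unit(as.character(id), rings)
  })
}

#' Read an edge list from CSV
#'
#' @param path CSV with character columns `src,dst`.
#' @return A `contiguity_graph`.
#' @export
read_edgelist_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("src", "dst") %in% names(df)))
  graph_from_edgelist(df[, c("src", "dst")])
}

#' Write a graph's edge list to CSV
#'
#' @param g A `contiguity_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist_csv <- function(g, path) {
  e <- graph_edges(g)
  utils::write.csv(data.frame(src = e[, 1L], dst = e[, 2L]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write graph summary statistics to JSON
#'
#' @param stats A `graph_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_stats_json <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
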