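test_that("queen/rook/bishop degrees on a 3x3 unit-square grid", {
  units <- generate_units(synthetic_scenario(rows = 3, cols = 3))
  # row-major ids: u0005 is the center, u0001 a corner, u0002 an edge cell
  queen <- build_contiguity_graph(units, "queen")
  rook <- build_contiguity_graph(units, "rook")
  bishop <- build_contiguity_graph(units, "bishop")
  nm <- neighbor_map(queen)
  expect_length(nm[["u0005"]], 8L)
  expect_length(nm[["u0001"]], 3L)
  expect_length(nm[["u0002"]], 5L)
  expect_length(neighbor_map(rook)[["u0005"]], 4L)
  expect_length(neighbor_map(bishop)[["u0005"]], 4L)
  expect_equal(nrow(bishop$edge_idx),
               nrow(queen$edge_idx) - nrow(rook$edge_idx))
  expect_equal(nrow(queen$edge_idx), 20L)
})

test_that("queen edges equal the union of rook and bishop edges", {
  for (layout in c("grid", "perturbed-grid")) {
    units <- generate_units(synthetic_scenario(rows = 4, cols = 5,
                                               layout = layout, seed = 3L))
    key <- function(g) apply(graph_edges(g), 1L, paste, collapse = "~")
    q <- key(build_contiguity_graph(units, "queen"))
    r <- key(build_contiguity_graph(units, "rook"))
    b <- key(build_contiguity_graph(units, "bishop"))
    expect_setequal(q, union(r, b))
    expect_length(intersect(r, b), 0L)
  }
})

test_that("handshake identity and order invariance of construction", {
  units <- generate_units(synthetic_scenario(rows = 4, cols = 4,
                                             layout = "perturbed-grid",
                                             seed = 9L))
  g <- build_contiguity_graph(units, "queen")
  expect_equal(sum(g$degree), 2L * nrow(g$edge_idx))
  set.seed(5)
  perm <- sample(length(units))
  g2 <- build_contiguity_graph(units[perm], "queen")
  key <- function(g) sort(apply(graph_edges(g), 1L, function(e)
    paste(sort(e), collapse = "~")))
  expect_identical(key(g), key(g2))
  expect_identical(g2$vertices, vapply(units[perm], `[[`, "", "unit_id"))
})

test_that("multipolygon units are neighbors when any part touches", {
  a <- spatial_unit("a", list(
    rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    rbind(c(2, 0), c(3, 0), c(3, 1), c(2, 1))))
  b <- spatial_unit("b", list(
    rbind(c(5, 5), c(6, 5), c(6, 6), c(5, 6)),
    rbind(c(3, 0), c(4, 0), c(4, 1), c(3, 1))))
  g <- build_contiguity_graph(list(a, b), "rook")
  expect_equal(nrow(g$edge_idx), 1L)
})

test_that("snap tolerance merges nearly identical shared vertices", {
  eps <- 1e-9
  a <- spatial_unit("a", rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  b <- spatial_unit("b", rbind(c(1 + eps, 0), c(2, 0), c(2, 1), c(1 + eps, 1)))
  exact <- build_contiguity_graph(list(a, b), "queen", snap_tolerance = 0)
  snapped <- build_contiguity_graph(list(a, b), "queen", snap_tolerance = 1e-6)
  expect_equal(nrow(exact$edge_idx), 0L)
  expect_equal(nrow(snapped$edge_idx), 1L)
  expect_equal(nrow(build_contiguity_graph(list(a, b), "rook",
                                           snap_tolerance = 1e-6)$edge_idx),
               1L)
})

test_that("invalid inputs are rejected with informative errors", {
  a <- spatial_unit("a", rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_error(build_contiguity_graph(list(a, spatial_unit("b")), "queen"),
               "edge list required")
  expect_error(spatial_unit("bad", rbind(c(0, 0), c(0, 0), c(0, 0))),
               "bad")
  expect_error(spatial_unit("nan", rbind(c(0, 0), c(NA, 1), c(1, 1))),
               "nan")
  expect_error(build_contiguity_graph(list(a, a), "queen"), "duplicate")
})

test_that("edge lists collapse duplicates and reject self-loops", {
  g <- graph_from_edgelist(rbind(c("a", "b"), c("b", "a")))
  expect_equal(nrow(g$edge_idx), 1L)
  expect_error(graph_from_edgelist(rbind(c("a", "a"))), "self-loop")
  g2 <- graph_from_edgelist(rbind(c("a", "b"), c("b", "c")))
  expect_setequal(neighbor_map(g2)[["b"]], c("a", "c"))
})

test_that("graph statistics match hand-checked and printed values", {
  g <- study_size_graph()
  st <- graph_stats(g)
  expect_equal(st$n, 2010L)
  expect_equal(st$m, 6079L)
  expect_equal(st$avg_degree_display, 6.049)
  expect_equal(st$density_display, 0.00301)

  tiny <- graph_from_edgelist(rbind(c("a", "b")))
  expect_equal(graph_stats(tiny)$avg_degree, 1)
  expect_equal(graph_stats(tiny)$density, 1)

  nine <- build_contiguity_graph(
    generate_units(synthetic_scenario(rows = 3, cols = 3)), "queen")
  st9 <- graph_stats(nine)
  expect_equal(st9$avg_degree_display, 4.444)
  expect_equal(st9$density_display, 0.556)

  iso <- graph_from_edgelist(matrix(character(0), 0, 2), vertices = "a")
  expect_error(graph_stats(iso), "n < 2")
})

test_that("GeoJSON and edge-list CSV readers round-trip a small lattice", {
  units <- generate_units(synthetic_scenario(rows = 2, cols = 2))
  feat <- function(u) list(
    type = "Feature",
    properties = list(unit_id = u$unit_id),
    geometry = list(type = "Polygon",
                    coordinates = list(lapply(seq_len(nrow(u$geometry[[1L]])),
                      function(i) as.list(u$geometry[[1L]][i, ])))))
  gj <- list(type = "FeatureCollection", features = lapply(units, feat))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  read <- read_units_geojson(path)
  g <- build_contiguity_graph(read, "queen")
  expect_equal(nrow(g$edge_idx), 6L)  # complete graph on the 2x2 block

  csv <- withr::local_tempfile(fileext = ".csv")
  write_edgelist_csv(g, csv)
  g2 <- read_edgelist_csv(csv)
  expect_equal(nrow(g2$edge_idx), 6L)
})
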