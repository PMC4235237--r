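test_that("box generator produces the expected combinatorics", {
  b1 <- generate_box(1, 1, 1)
  expect_equal(nrow(b1$tets), 6L)
  expect_equal(sum(element_geometry(b1)$volume), 1, tolerance = 1e-12)

  b2 <- generate_box(2, 2, 2)
  expect_equal(nrow(b2$tets), 48L)

  b3 <- generate_box(2, 3, 4)
  expect_equal(nrow(b3$face_sets$x0), 2L * 3L * 4L)
  expect_equal(nrow(b3$face_sets$y1), 2L * 2L * 4L)
  expect_equal(nrow(b3$face_sets$z0), 2L * 2L * 3L)
})

test_that("proxy carries all regions, sets, and implant dimensions", {
  pm <- coarse_proxy()
  tags <- region_tags()
  for (r in c("cortical", "cancellous", "implant", "virtual"))
    expect_gt(sum(pm$region == tags[[r]]), 0L)
  for (s in c("end_cap_A", "end_cap_B", "outer_surface", "inner_interface",
              "implant_surface", "crest_ring"))
    expect_gt(length(pm$node_sets[[s]]), 0L)
  expect_true(validate_mesh(pm)$ok)

  # implant bounding extent along its (vertical) axis = length +- edge
  gp <- attr(pm, "proxy_params")
  imp_nodes <- unique(as.vector(pm$tets[pm$region == tags[["implant"]], ]))
  extent <- diff(range(pm$nodes[imp_nodes, 3]))
  expect_lt(abs(extent - gp$implant_length), gp$edge_length)
})

test_that("proxy generation is deterministic for a fixed seed", {
  p <- proxy_params(edge_length = 3, seed = 42L)
  m1 <- generate_proxy(p)
  m2 <- generate_proxy(p)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$region, m2$region)
  m3 <- generate_proxy(proxy_params(edge_length = 3, seed = 43L))
  expect_false(identical(m1$nodes, m3$nodes))
})

test_that("bone plus virtual fill forms a watertight unnotched tube", {
  pm <- coarse_proxy()
  tags <- region_tags()
  el <- which(pm$region %in% c(tags[["cortical"]], tags[["cancellous"]],
                               tags[["virtual"]], tags[["implant"]]))
  bf <- orthobone:::boundary_faces(pm, el)
  # watertight: every edge of the boundary surface bounds exactly 2 faces
  edges <- rbind(bf[, c(1, 2)], bf[, c(2, 3)], bf[, c(1, 3)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2L))
})

test_that("removing virtual elements leaves a conforming connected mesh", {
  pm <- coarse_proxy()
  tags <- region_tags()
  bone <- c(tags[["cortical"]], tags[["cancellous"]], tags[["implant"]])
  sub <- region_submesh(pm, bone)
  expect_true(all(!is.na(sub$local_index[as.vector(pm$tets[sub$elem_ids, ])])))
  comp <- orthobone:::element_components(pm, sub$elem_ids)
  expect_equal(max(comp), 1L)
})

test_that("implant is bonded to bone everywhere except its crest platform", {
  pm <- coarse_proxy()
  gp <- attr(pm, "proxy_params")
  tags <- region_tags()
  imp <- which(pm$region == tags[["implant"]])
  bf <- orthobone:::boundary_faces(pm, imp)
  all_bf <- orthobone:::boundary_faces(pm)
  fkey <- function(f) paste(f[, 1], f[, 2], f[, 3])
  canon <- function(f) t(apply(f, 1, sort))
  exposed <- intersect(fkey(canon(bf)), fkey(canon(all_bf)))
  # faces exposed at the mesh surface may only be the occlusal platform
  # where the crown would attach; everything below is bone-bonded
  if (length(exposed)) {
    idx <- match(exposed, fkey(canon(bf)))
    fcen_z <- (pm$nodes[bf[idx, 1], 3] + pm$nodes[bf[idx, 2], 3] +
               pm$nodes[bf[idx, 3], 3]) / 3
    expect_true(all(fcen_z > gp$outer_radius - gp$cortical_thickness))
  }
  # lateral/apical bonding: every implant node below the crest band is
  # shared with a bone element
  imp_nodes <- unique(as.vector(pm$tets[imp, ]))
  bone_nodes <- unique(as.vector(pm$tets[pm$region %in% c(1L, 2L), ]))
  below <- imp_nodes[pm$nodes[imp_nodes, 3] <
                       gp$outer_radius - gp$cortical_thickness]
  interior_imp <- setdiff(imp_nodes, unique(as.vector(bf)))
  expect_true(all(setdiff(below, interior_imp) %in% bone_nodes))
})

test_that("centerline tangents follow circle geometry", {
  p <- proxy_params()
  # mid-arc point: tangent is unit and orthogonal to the radial direction
  mid <- c(p$arc_radius, 0, 0)
  t0 <- centerline_tangent(p, mid)
  expect_equal(sqrt(sum(t0^2)), 1, tolerance = 1e-12)
  expect_equal(abs(sum(t0 * c(1, 0, 0))), 0, tolerance = 1e-12)

  # two arc points separated by delta: tangents rotate by exactly delta
  th <- p$arc_angle * pi / 180
  a1 <- -th / 4; a2 <- th / 4
  pts <- rbind(p$arc_radius * c(cos(a1), sin(a1), 0),
               p$arc_radius * c(cos(a2), sin(a2), 0))
  tt <- centerline_tangent(p, pts)
  ang <- acos(sum(tt[1, ] * tt[2, ]))
  expect_equal(ang, a2 - a1, tolerance = 1e-10)

  set.seed(5)
  rnd <- matrix(rnorm(30, sd = 10), ncol = 3)
  expect_equal(rowSums(centerline_tangent(p, rnd)^2), rep(1, 10),
               tolerance = 1e-12)
})

test_that("invalid proxy parameter combinations are rejected", {
  expect_error(proxy_params(cortical_thickness = 8, outer_radius = 7),
               "cortical")
  expect_error(proxy_params(implant_diameter = 11), "implant")
  expect_error(proxy_params(notch_depth = 10), "notch")
  expect_error(proxy_params(edge_length = 0), "edge")
})
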