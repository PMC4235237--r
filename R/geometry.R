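# Deterministic synthetic geometry: a curved-tube mandible proxy and
# simple box / single-tet fixtures.
#
# The proxy is an idealised circular-arc tube with a cortical shell and a
# cancellous core, an alveolar-ridge notch cut into its crest, "virtual"
# elements that fill the notch flush with the unnotched outer surface, and
# a cylindrical implant embedded vertically at a molar-like arc position.
# It is not an anatomic mandible; it reproduces the geometric features the
# material-assignment method reacts to (a curved long axis and a ridge
# interruption) on a mesh small enough for routine testing.

#' Parameters of the mandible-proxy generator
#'
#' @param arc_radius centerline arc radius (mm).
#' @param arc_angle arc angle (degrees).
#' @param outer_radius outer tube (cross-section) radius (mm).
#' @param cortical_thickness cortical shell thickness (mm).
#' @param notch_depth alveolar notch depth from the crest (mm); 0 disables
#'   the notch.
#' @param notch_center arc-length fraction (0..1) of the notch centre.
#' @param notch_extent angular extent of the notch along the arc (degrees).
#' @param implant_length,implant_diameter implant dimensions (mm); defaults
#'   are a wide-neck molar fixture, 10.0 mm long and 4.8 mm in diameter.
#' @param implant_pos arc-length fraction of the implant axis.
#' @param edge_length target element edge length (mm).
#' @param jitter interior-node perturbation as a fraction of
#'   `edge_length` (capped at 0.1); 0 gives the unperturbed template mesh.
#' @param seed integer seed for the (deterministic) interior jitter.
#' @return List of class `proxy_params`.
#' @export
proxy_params <- function(arc_radius = 25, arc_angle = 120,
                         outer_radius = 7, cortical_thickness = 2,
                         notch_depth = 3, notch_center = 0.35,
                         notch_extent = 30,
                         implant_length = 10, implant_diameter = 4.8,
                         implant_pos = 0.65,
                         edge_length = 1.75, jitter = 0.05, seed = 1L) {
  p <- list(arc_radius = arc_radius, arc_angle = arc_angle,
            outer_radius = outer_radius,
            cortical_thickness = cortical_thickness,
            notch_depth = notch_depth, notch_center = notch_center,
            notch_extent = notch_extent,
            implant_length = implant_length,
            implant_diameter = implant_diameter,
            implant_pos = implant_pos,
            edge_length = edge_length, jitter = min(jitter, 0.1),
            seed = as.integer(seed))
  if (p$cortical_thickness >= p$outer_radius)
    stop("cortical thickness must be smaller than the outer radius")
  if (p$implant_diameter >= 2 * (p$outer_radius - p$cortical_thickness))
    stop("implant diameter must fit inside the cancellous core")
  if (p$notch_depth > p$outer_radius)
    stop("notch depth cannot exceed the outer radius")
  if (p$edge_length <= 0) stop("edge length must be positive")
  if (p$implant_length >= 2 * p$outer_radius)
    stop("implant is longer than the tube cross-section")
  class(p) <- "proxy_params"
  p
}

# Square [-1,1]^2 -> unit disc, elliptical mapping (no degenerate cells).
square_to_disc <- function(u, v) {
  cbind(u * sqrt(pmax(0, 1 - v^2 / 2)), v * sqrt(pmax(0, 1 - u^2 / 2)))
}

#' Generate the curved-tube mandible proxy
#'
#' Builds a structured tetrahedral mesh of a circular-arc tube with region
#' tags cortical (1), cancellous (2), implant (3) and virtual (9), and the
#' named node sets `end_cap_A`, `end_cap_B`, `outer_surface`,
#' `inner_interface`, `implant_surface`, `implant_top` and `crest_ring`.
#' Virtual elements occupy exactly the notch volume, flush with the
#' unnotched outer surface, so removing them restores the notched bone and
#' keeping them restores the full tube.  The mesh is deterministic for a
#' fixed parameter set and seed.
#'
#' @param params a [proxy_params()] object.
#' @return A [tet_mesh()].
#' @export
generate_proxy <- function(params = proxy_params()) {
  stopifnot(inherits(params, "proxy_params"))
  p <- params
  theta <- p$arc_angle * pi / 180
  arc_len <- p$arc_radius * theta
  ns <- max(6L, ceiling(arc_len / p$edge_length))
  ncs <- max(6L, ceiling(2 * p$outer_radius / p$edge_length))
  hu <- 2 / ncs                       # parametric cross-section step

  # parametric grids
  sg <- seq(0, 1, length.out = ns + 1L)
  ug <- seq(-1, 1, length.out = ncs + 1L)
  alpha <- (sg - 0.5) * theta

  # cross-section template (shared by all stations)
  uv <- as.matrix(expand.grid(u = ug, v = ug))
  disc <- square_to_disc(uv[, 1], uv[, 2]) * p$outer_radius
  npc <- nrow(uv)                     # nodes per cross-section

  nid <- function(iu, iv, k) iu + (ncs + 1L) * (iv - 1L) +
    npc * (k - 1L)                    # iu,iv in 1..ncs+1, k in 1..ns+1

  nodes <- matrix(0, npc * (ns + 1L), 3L)
  for (k in seq_len(ns + 1L)) {
    er <- c(cos(alpha[k]), sin(alpha[k]), 0)
    ctr <- p$arc_radius * er
    idx <- npc * (k - 1L) + seq_len(npc)
    nodes[idx, 1] <- ctr[1] + disc[, 1] * er[1]
    nodes[idx, 2] <- ctr[2] + disc[, 1] * er[2]
    nodes[idx, 3] <- disc[, 2]
  }

  # Kuhn subdivision of each (iu, iv, k) hex cell into 6 tets sharing the
  # main diagonal; conforming across cells.
  kuhn <- rbind(c(1L, 2L, 4L, 8L), c(1L, 4L, 3L, 8L), c(1L, 3L, 7L, 8L),
                c(1L, 7L, 5L, 8L), c(1L, 5L, 6L, 8L), c(1L, 6L, 2L, 8L))
  cells <- as.matrix(expand.grid(iu = seq_len(ncs), iv = seq_len(ncs),
                                 k = seq_len(ns)))
  corner <- function(du, dv, dk)
    nid(cells[, 1] + du, cells[, 2] + dv, cells[, 3] + dk)
  crn <- cbind(corner(0L, 0L, 0L), corner(1L, 0L, 0L),
               corner(0L, 1L, 0L), corner(1L, 1L, 0L),
               corner(0L, 0L, 1L), corner(1L, 0L, 1L),
               corner(0L, 1L, 1L), corner(1L, 1L, 1L))
  ncell <- nrow(cells)
  tets <- matrix(0L, 6L * ncell, 4L)
  for (t in 1:6)
    tets[seq.int(t, by = 6L, length.out = ncell), ] <- crn[, kuhn[t, ]]
  cell_of_tet <- rep(seq_len(ncell), each = 6L)

  # region classification from the parametric cell centroid
  uc <- (ug[cells[, 1]] + ug[cells[, 1] + 1L]) / 2
  vc <- (ug[cells[, 2]] + ug[cells[, 2] + 1L]) / 2
  sc <- (sg[cells[, 3]] + sg[cells[, 3] + 1L]) / 2
  dc <- square_to_disc(uc, vc) * p$outer_radius
  rho <- sqrt(rowSums(dc^2))
  zc <- dc[, 2]

  tags <- region_tags()
  reg_cell <- rep(tags[["cancellous"]], ncell)
  reg_cell[rho >= p$outer_radius - p$cortical_thickness] <- tags[["cortical"]]

  # implant: vertical cylinder in the bent frame at arc fraction implant_pos
  r_imp <- p$implant_diameter / 2
  dl <- (sc - p$implant_pos) * arc_len
  in_imp <- sqrt(dl^2 + dc[, 1]^2) <= r_imp &
    zc >= p$outer_radius - p$implant_length
  reg_cell[in_imp] <- tags[["implant"]]

  # alveolar notch -> virtual fill, in an arc window around notch_center
  if (p$notch_depth > 0 && p$notch_extent > 0) {
    half <- (p$notch_extent * pi / 180) / 2 / theta   # fraction of arc
    in_notch <- abs(sc - p$notch_center) <= half &
      zc >= p$outer_radius - p$notch_depth & !in_imp
    reg_cell[in_notch] <- tags[["virtual"]]
  }
  region <- reg_cell[cell_of_tet]

  # node sets -------------------------------------------------------------
  iu_all <- rep(rep(seq_len(ncs + 1L), ncs + 1L), ns + 1L)
  iv_all <- rep(rep(seq_len(ncs + 1L), each = ncs + 1L), ns + 1L)
  k_all <- rep(seq_len(ns + 1L), each = npc)
  on_ring <- iu_all %in% c(1L, ncs + 1L) | iv_all %in% c(1L, ncs + 1L)

  nodes_of <- function(tag) {
    ids <- which(region == tag)
    if (!length(ids)) integer() else unique(as.vector(tets[ids, ]))
  }
  n_cort <- nodes_of(tags[["cortical"]])
  n_canc <- nodes_of(tags[["cancellous"]])
  n_imp <- nodes_of(tags[["implant"]])
  imp_zmax <- if (length(n_imp)) max(nodes[n_imp, 3]) else NA_real_
  node_sets <- list(
    end_cap_A = which(k_all == 1L),
    end_cap_B = which(k_all == ns + 1L),
    outer_surface = which(on_ring),
    inner_interface = intersect(n_cort, n_canc),
    implant_surface = intersect(n_imp, union(n_cort, n_canc)),
    crest_ring = intersect(n_imp, n_cort),
    implant_top = if (length(n_imp))
      n_imp[nodes[n_imp, 3] > imp_zmax - 0.75 * p$edge_length] else integer()
  )

  # deterministic interior jitter: only nodes whose incident elements all
  # share one region tag, and which are on no boundary or named set
  if (p$jitter > 0) {
    protected <- on_ring | k_all %in% c(1L, ns + 1L)
    n_tags_touching <- integer(nrow(nodes))
    for (tag in unique(region)) {
      ids <- nodes_of(tag)
      n_tags_touching[ids] <- n_tags_touching[ids] + 1L
    }
    free <- which(!protected & n_tags_touching == 1L)
    set.seed(p$seed)
    amp <- p$jitter * p$edge_length
    nodes[free, ] <- nodes[free, ] +
      matrix(stats::runif(3L * length(free), -amp, amp), ncol = 3L)
  }

  mesh <- tet_mesh(nodes, tets, region = region, node_sets = node_sets,
                   fix_orientation = TRUE)
  attr(mesh, "proxy_params") <- p
  mesh
}

#' Analytic centerline tangent of the proxy
#'
#' Unit tangent of the circular centerline at the arc parameter nearest to
#' each query point; the analytic reference for the longitudinal material
#' direction, used to score frame quality.
#'
#' @param params a [proxy_params()].
#' @param points numeric 3-vector or n x 3 matrix of query points (mm).
#' @return n x 3 matrix of unit tangents.
#' @export
centerline_tangent <- function(params, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  theta <- params$arc_angle * pi / 180
  a <- atan2(points[, 2], points[, 1])
  a <- pmin(pmax(a, -theta / 2), theta / 2)
  cbind(-sin(a), cos(a), 0)
}

#' Generate a structured box mesh
#'
#' Axis-aligned box split into 6 tets per grid cell (Kuhn subdivision),
#' with face sets `x0, x1, y0, y1, z0, z1` covering the six faces.
#'
#' @param nx,ny,nz cell subdivisions per axis (>= 1).
#' @param lengths box edge lengths (mm), length-3.
#' @param region uniform region tag.
#' @return A [tet_mesh()].
#' @export
generate_box <- function(nx = 1L, ny = 1L, nz = 1L, lengths = c(1, 1, 1),
                         region = 1L) {
  stopifnot(nx >= 1L, ny >= 1L, nz >= 1L, length(lengths) == 3L)
  xs <- seq(0, lengths[1], length.out = nx + 1L)
  ys <- seq(0, lengths[2], length.out = ny + 1L)
  zs <- seq(0, lengths[3], length.out = nz + 1L)
  g <- expand.grid(x = xs, y = ys, z = zs)
  nodes <- as.matrix(g)
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L) +
    (nx + 1L) * (ny + 1L) * (k - 1L)
  cells <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(ny),
                                 k = seq_len(nz)))
  corner <- function(di, dj, dk)
    nid(cells[, 1] + di, cells[, 2] + dj, cells[, 3] + dk)
  crn <- cbind(corner(0L, 0L, 0L), corner(1L, 0L, 0L),
               corner(0L, 1L, 0L), corner(1L, 1L, 0L),
               corner(0L, 0L, 1L), corner(1L, 0L, 1L),
               corner(0L, 1L, 1L), corner(1L, 1L, 1L))
  kuhn <- rbind(c(1L, 2L, 4L, 8L), c(1L, 4L, 3L, 8L), c(1L, 3L, 7L, 8L),
                c(1L, 7L, 5L, 8L), c(1L, 5L, 6L, 8L), c(1L, 6L, 2L, 8L))
  ncell <- nrow(cells)
  tets <- matrix(0L, 6L * ncell, 4L)
  for (t in 1:6)
    tets[seq.int(t, by = 6L, length.out = ncell), ] <- crn[, kuhn[t, ]]
  mesh <- tet_mesh(nodes, tets, region = region, fix_orientation = TRUE)

  bf <- boundary_faces(mesh)
  cen <- (mesh$nodes[bf[, 1], , drop = FALSE] +
          mesh$nodes[bf[, 2], , drop = FALSE] +
          mesh$nodes[bf[, 3], , drop = FALSE]) / 3
  eps <- 1e-9 * max(lengths)
  face_sets <- list(
    x0 = bf[cen[, 1] < eps, , drop = FALSE],
    x1 = bf[cen[, 1] > lengths[1] - eps, , drop = FALSE],
    y0 = bf[cen[, 2] < eps, , drop = FALSE],
    y1 = bf[cen[, 2] > lengths[2] - eps, , drop = FALSE],
    z0 = bf[cen[, 3] < eps, , drop = FALSE],
    z1 = bf[cen[, 3] > lengths[3] - eps, , drop = FALSE])
  mesh$face_sets <- face_sets
  mesh$node_sets <- lapply(face_sets, function(f) sort(unique(as.vector(f))))
  mesh
}
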