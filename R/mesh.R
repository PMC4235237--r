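# Tetrahedral mesh data model and P1 element geometry.
#
# A tet_mesh is the substrate for everything downstream: harmonic fields,
# material frames, and the elasticity solve all operate on its nodes,
# connectivity and region tags.  Coordinates are millimetres; connectivity
# is 1-based (the R-native convention; external formats are converted on
# read/write).

#' Standard region tags
#'
#' Integer labels used for mesh regions throughout the package: cortical
#' bone (1), cancellous bone (2), implant (3), tooth (4) and virtual fill
#' elements (9).  Additional integers may be used freely; these are the
#' names the generator and the pipeline agree on.
#'
#' @return Named integer vector of the standard region tags.
#' @export
region_tags <- function() {
  c(cortical = 1L, cancellous = 2L, implant = 3L, tooth = 4L, virtual = 9L)
}

#' Construct a tetrahedral mesh
#'
#' @param nodes numeric n x 3 matrix of node coordinates (mm).
#' @param tets integer m x 4 matrix of 1-based node indices.
#' @param region integer vector of length m with one region tag per element
#'   (see [region_tags()]); a single value is recycled.
#' @param node_sets named list of integer vectors indexing `nodes`.
#' @param face_sets named list of k x 3 integer matrices of boundary
#'   triangles (1-based node indices).
#' @param fix_orientation reorder tets with negative signed volume (swap of
#'   the last two nodes) so all Jacobians are positive. Default `TRUE`.
#'
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, region = 1L, node_sets = list(),
                     face_sets = list(), fix_orientation = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("'nodes' must be an n x 3 matrix")
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(tets) != 4L) stop("'tets' must be an m x 4 matrix")
  if (any(tets < 1L) || any(tets > nrow(nodes)))
    stop("tet connectivity indexes nodes outside [1, n_nodes]")
  region <- as.integer(region)
  if (length(region) == 1L) region <- rep(region, nrow(tets))
  if (length(region) != nrow(tets))
    stop("'region' must have one tag per element")
  if (fix_orientation) {
    v <- signed_volumes(nodes, tets)
    neg <- which(v < 0)
    if (length(neg)) tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
  }
  m <- structure(list(nodes = nodes, tets = tets, region = region,
                      node_sets = node_sets, face_sets = face_sets),
                 class = "tet_mesh")
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  tags <- sort(unique(x$region))
  cat(sprintf("tet_mesh: %d nodes, %d tets, regions {%s}\n",
              nrow(x$nodes), nrow(x$tets), paste(tags, collapse = ", ")))
  if (length(x$node_sets))
    cat("  node_sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  if (length(x$face_sets))
    cat("  face_sets:", paste(names(x$face_sets), collapse = ", "), "\n")
  invisible(x)
}

n_nodes <- function(mesh) nrow(mesh$nodes)
n_elems <- function(mesh) nrow(mesh$tets)

# Signed volume of each tet: det([b-a, c-a, d-a]) / 6.
signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  u <- nodes[tets[, 2L], , drop = FALSE] - a
  v <- nodes[tets[, 3L], , drop = FALSE] - a
  w <- nodes[tets[, 4L], , drop = FALSE] - a
  # triple product u . (v x w), fully vectorised
  cx <- v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]
  cy <- v[, 3L] * w[, 1L] - v[, 1L] * w[, 3L]
  cz <- v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L]
  (u[, 1L] * cx + u[, 2L] * cy + u[, 3L] * cz) / 6
}

#' P1 element geometry: volumes and shape-function gradients
#'
#' For every tetrahedron returns its volume and the (constant) gradients of
#' the four linear shape functions.  The gradients satisfy the partition of
#' unity `sum_a grad N_a = 0` and are exact for linear fields; they are the
#' building block of both the Laplace and the elasticity assembly.
#'
#' @param mesh a [tet_mesh()].
#' @return List with `volume` (length-m vector, mm^3) and `grads`
#'   (m x 4 x 3 array, 1/mm; `grads[e, a, ]` is grad N_a on element e).
#' @export
element_geometry <- function(mesh) {
  vol <- signed_volumes(mesh$nodes, mesh$tets)
  if (any(vol <= 0))
    stop("degenerate element(s) with non-positive volume: ",
         paste(utils::head(which(vol <= 0), 10L), collapse = ", "))
  m <- n_elems(mesh)
  grads <- array(0, dim = c(m, 4L, 3L))
  X <- mesh$nodes
  T1 <- mesh$tets
  # grad N_a = (opposite face normal) * area / (3 V); computed as cross
  # products of edge vectors, vectorised over elements.
  p <- lapply(1:4, function(a) X[T1[, a], , drop = FALSE])
  cross3 <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  # For vertex ordering (1,2,3,4) with positive volume:
  # grad N1 = (p4-p2) x (p3-p2) / 6V, and cyclic analogues.
  g1 <- cross3(p[[4]] - p[[2]], p[[3]] - p[[2]])
  g2 <- cross3(p[[3]] - p[[1]], p[[4]] - p[[1]])
  g3 <- cross3(p[[4]] - p[[1]], p[[2]] - p[[1]])
  g4 <- cross3(p[[2]] - p[[1]], p[[3]] - p[[1]])
  s <- 1 / (6 * vol)
  grads[, 1L, ] <- g1 * s
  grads[, 2L, ] <- g2 * s
  grads[, 3L, ] <- g3 * s
  grads[, 4L, ] <- g4 * s
  list(volume = vol, grads = grads)
}

#' Element centroids
#' @param mesh a [tet_mesh()].
#' @return m x 3 matrix of centroid coordinates (mm).
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4
}

#' Validate a mesh and report defects
#'
#' Non-destructive check of the `tet_mesh` invariants: index ranges,
#' inverted (non-positively oriented) elements, unreferenced nodes, and
#' set consistency.  The mesh itself is never modified.
#'
#' @param mesh a [tet_mesh()].
#' @return List of class `mesh_validation` with counts, volume range,
#'   `inverted` element ids, `orphan_nodes`, `set_errors`, and a logical
#'   `ok`.
#' @export
validate_mesh <- function(mesh) {
  vol <- signed_volumes(mesh$nodes, mesh$tets)
  inverted <- which(vol <= 0)
  referenced <- unique(as.vector(mesh$tets))
  orphan <- setdiff(seq_len(n_nodes(mesh)), referenced)
  set_errors <- character()
  for (nm in names(mesh$node_sets)) {
    s <- mesh$node_sets[[nm]]
    if (length(s) && (min(s) < 1L || max(s) > n_nodes(mesh)))
      set_errors <- c(set_errors, sprintf("node_set '%s' out of range", nm))
  }
  for (nm in names(mesh$face_sets)) {
    f <- mesh$face_sets[[nm]]
    if (length(f) && (min(f) < 1L || max(f) > n_nodes(mesh)))
      set_errors <- c(set_errors, sprintf("face_set '%s' out of range", nm))
  }
  rep <- list(n_nodes = n_nodes(mesh), n_elems = n_elems(mesh),
              min_volume = min(abs(vol)), max_volume = max(abs(vol)),
              inverted = inverted, orphan_nodes = orphan,
              set_errors = set_errors,
              ok = length(inverted) == 0L && length(orphan) == 0L &&
                   length(set_errors) == 0L)
  class(rep) <- "mesh_validation"
  rep
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf("mesh validation: %d nodes, %d tets, volumes [%.4g, %.4g] mm^3\n",
              x$n_nodes, x$n_elems, x$min_volume, x$max_volume))
  if (x$ok) cat("  no violations\n") else {
    if (length(x$inverted))
      cat("  inverted elements:", paste(utils::head(x$inverted, 10),
                                        collapse = ", "), "\n")
    if (length(x$orphan_nodes))
      cat("  orphan nodes:", paste(utils::head(x$orphan_nodes, 10),
                                   collapse = ", "), "\n")
    for (e in x$set_errors) cat(" ", e, "\n")
  }
  invisible(x)
}

#' Extract the submesh of selected regions
#'
#' Returns the elements whose tag is in `regions` together with the node
#' subset they reference; used to restrict the Laplace and elasticity
#' solves (e.g. bone only, or bone plus virtual fill).
#'
#' @param mesh a [tet_mesh()].
#' @param regions integer vector of region tags to keep.
#' @return List with `elem_ids` (indices into the parent mesh), `node_ids`
#'   (parent node indices present in the submesh), and `local_index`
#'   (length n_nodes map from parent node id to local id, NA outside).
#' @export
region_submesh <- function(mesh, regions) {
  elem_ids <- which(mesh$region %in% regions)
  if (!length(elem_ids))
    stop("no elements carry region tag(s) ", paste(regions, collapse = ", "))
  node_ids <- sort(unique(as.vector(mesh$tets[elem_ids, , drop = FALSE])))
  local_index <- rep(NA_integer_, n_nodes(mesh))
  local_index[node_ids] <- seq_along(node_ids)
  list(elem_ids = elem_ids, node_ids = node_ids, local_index = local_index)
}

# Boundary faces of an element subset: triangles appearing in exactly one
# tet of the subset. Returns a k x 3 matrix of node ids.
boundary_faces <- function(mesh, elem_ids = seq_len(n_elems(mesh))) {
  T1 <- mesh$tets[elem_ids, , drop = FALSE]
  faces <- rbind(T1[, c(1L, 2L, 3L)], T1[, c(1L, 2L, 4L)],
                 T1[, c(1L, 3L, 4L)], T1[, c(2L, 3L, 4L)])
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "_"))
  tab <- table(key)
  keep <- names(tab)[tab == 1L]
  faces[match(keep, key), , drop = FALSE]
}

# Connected components of the element subset (by shared nodes).
# Returns an integer component id per element of the subset.
element_components <- function(mesh, elem_ids) {
  sub <- mesh$tets[elem_ids, , drop = FALSE]
  nn <- max(sub)
  # union-find over nodes
  parent <- seq_len(nn)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(sub))) {
    r <- find(sub[e, 1L])
    for (a in 2:4) {
      s <- find(sub[e, a])
      if (s != r) parent[s] <- r
    }
  }
  roots <- vapply(sub[, 1L], find, integer(1))
  match(roots, unique(roots))
}
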