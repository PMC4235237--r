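# Volumetric harmonic fields: P1 finite-element solution of Laplace's
# equation with Dirichlet seeds on a region subset of the mesh, and
# per-element gradient extraction.
#
# The two fields of interest are the longitudinal field (end cap to end
# cap, optionally flowing through the virtual fill so its level sets do
# not bend around the alveolar notch) and the radial field (cortical-
# cancellous interface to periosteal surface).  Their gradients define the
# local material axes.

#' Dirichlet seed specification
#'
#' @param ... named numeric scalars: `set_name = value` pairs prescribing
#'   the field value on each named node set.
#' @return List of class `dirichlet_spec`.
#' @export
dirichlet_spec <- function(...) {
  v <- c(...)
  if (!length(v) || is.null(names(v)) || any(!nzchar(names(v))))
    stop("dirichlet_spec() needs named 'set = value' arguments")
  structure(as.list(v), class = "dirichlet_spec")
}

# P1 Laplace stiffness over a set of elements: K_ab = sum_e V_e gN_a.gN_b,
# assembled as a sparse matrix over local node numbering.
laplace_stiffness <- function(mesh, geo, sub) {
  el <- sub$elem_ids
  T1 <- mesh$tets[el, , drop = FALSE]
  Tl <- matrix(sub$local_index[T1], ncol = 4L)
  V <- geo$volume[el]
  G <- geo$grads[el, , , drop = FALSE]
  nn <- length(sub$node_ids)
  ii <- jj <- xx <- vector("list", 16L)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1L
    ii[[k]] <- Tl[, a]
    jj[[k]] <- Tl[, b]
    xx[[k]] <- V * (G[, a, 1] * G[, b, 1] + G[, a, 2] * G[, b, 2] +
                    G[, a, 3] * G[, b, 3])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nn, nn))
}

#' Solve Laplace's equation with Dirichlet seeds
#'
#' Minimises the discrete Dirichlet energy over P1 fields on the submesh
#' of `include_regions`, with prescribed values imposed exactly by
#' row/column elimination.  Seed nodes outside the included submesh are
#' dropped (with a warning).  Nodes outside the submesh carry `NA`.
#'
#' @param mesh a [tet_mesh()].
#' @param spec a [dirichlet_spec()].
#' @param include_regions region tags forming the solve domain; default
#'   all regions.
#' @return Numeric vector of length `n_nodes`: the harmonic field, `NA`
#'   outside the included regions.
#' @export
solve_harmonic <- function(mesh, spec, include_regions = NULL) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  if (is.null(include_regions)) include_regions <- unique(mesh$region)
  sub <- region_submesh(mesh, include_regions)

  comp <- element_components(mesh, sub$elem_ids)
  if (max(comp) > 1L)
    stop(sprintf("included submesh is disconnected (%d components of sizes %s)",
                 max(comp), paste(tabulate(comp), collapse = ", ")))

  fixed_global <- integer(); fixed_val <- numeric()
  for (nm in names(spec)) {
    s <- mesh$node_sets[[nm]]
    if (is.null(s)) stop("unknown node set in Dirichlet spec: ", nm)
    inside <- s[!is.na(sub$local_index[s])]
    if (length(inside) < length(s))
      message(sprintf("note: %d seed node(s) of '%s' lie outside the solve domain and were dropped",
                      length(s) - length(inside), nm))
    fixed_global <- c(fixed_global, inside)
    fixed_val <- c(fixed_val, rep(as.numeric(spec[[nm]]), length(inside)))
  }
  if (!length(fixed_global))
    stop("no Dirichlet seeds inside the solve domain; system is underdetermined")
  keep <- !duplicated(fixed_global)
  fixed_global <- fixed_global[keep]; fixed_val <- fixed_val[keep]

  geo <- element_geometry(mesh)
  K <- laplace_stiffness(mesh, geo, sub)
  nn <- length(sub$node_ids)
  fixed_local <- sub$local_index[fixed_global]
  free <- setdiff(seq_len(nn), fixed_local)

  u <- numeric(nn)
  u[fixed_local] <- fixed_val
  if (length(free)) {
    rhs <- -K[free, fixed_local, drop = FALSE] %*% fixed_val
    u[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE], rhs))
  }
  out <- rep(NA_real_, n_nodes(mesh))
  out[sub$node_ids] <- u
  out
}

#' Solve the longitudinal/radial harmonic field pair
#'
#' The longitudinal field runs between the two end caps and, when
#' `use_virtual` is set, is solved on bone plus the virtual fill so that
#' it flows through the alveolar notch instead of bending around it.  The
#' radial field runs from the cortical-cancellous interface (0) to the
#' periosteal surface (1) and is solved on bone only.
#'
#' @param mesh a [tet_mesh()] with the proxy's standard node sets.
#' @param long_spec,rad_spec [dirichlet_spec()] overrides; defaults are
#'   `end_cap_A = 0, end_cap_B = 1` and `inner_interface = 0,
#'   outer_surface = 1`.
#' @param use_virtual include virtual-tagged elements in the longitudinal
#'   solve.
#' @param bone_regions region tags treated as bone (default cortical and
#'   cancellous).
#' @return List with `phi_long` and `phi_rad` node fields (`NA` outside
#'   their domains).
#' @export
solve_field_pair <- function(mesh,
                             long_spec = dirichlet_spec(end_cap_A = 0,
                                                        end_cap_B = 1),
                             rad_spec = dirichlet_spec(inner_interface = 0,
                                                       outer_surface = 1),
                             use_virtual = TRUE,
                             bone_regions = c(1L, 2L)) {
  tags <- region_tags()
  has_virtual <- any(mesh$region == tags[["virtual"]])
  if (use_virtual && !has_virtual)
    stop("use_virtual = TRUE but the mesh has no virtual-tagged elements")
  long_regions <- if (use_virtual) c(bone_regions, tags[["virtual"]])
                  else bone_regions
  phi_long <- solve_harmonic(mesh, long_spec, include_regions = long_regions)
  phi_rad <- solve_harmonic(mesh, rad_spec, include_regions = bone_regions)
  list(phi_long = phi_long, phi_rad = phi_rad)
}

#' Per-element gradients of a node field
#'
#' The P1 gradient is constant on each tet: `sum_a phi_a grad N_a`; exact
#' for linear fields.
#'
#' @param mesh a [tet_mesh()].
#' @param field numeric node field (may be `NA` outside the regions of
#'   interest).
#' @param include_regions region tags of the elements to differentiate
#'   over; default all.
#' @return n_elems x 3 matrix of gradients (1/mm); rows of excluded
#'   elements are `NA`.
#' @export
element_gradients <- function(mesh, field, include_regions = NULL) {
  if (length(field) != n_nodes(mesh))
    stop("field length does not match the mesh")
  if (is.null(include_regions)) include_regions <- unique(mesh$region)
  el <- which(mesh$region %in% include_regions)
  vals <- matrix(field[mesh$tets[el, , drop = FALSE]], ncol = 4L)
  if (anyNA(vals)) {
    bad <- el[which(rowSums(is.na(vals)) > 0)]
    stop("field undefined on node(s) of element(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  geo <- element_geometry(mesh)
  G <- geo$grads[el, , , drop = FALSE]
  out <- matrix(NA_real_, n_elems(mesh), 3L)
  for (d in 1:3)
    out[el, d] <- rowSums(vals * G[, , d])
  out
}

# Discrete Dirichlet energy of a node field over a region subset.
dirichlet_energy <- function(mesh, field, include_regions = NULL) {
  if (is.null(include_regions)) include_regions <- unique(mesh$region)
  g <- element_gradients(mesh, field, include_regions)
  geo <- element_geometry(mesh)
  el <- which(mesh$region %in% include_regions)
  sum(geo$volume[el] * rowSums(g[el, , drop = FALSE]^2)) / 2
}
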