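# Linear-elastic constant-strain tetrahedron (tet4) solver with
# per-element (possibly rotated orthotropic) stiffness, plus stress/strain
# recovery and the scalar measures used in the peri-implant reports.
#
# Units: coordinates mm, stiffness GPa, applied forces N and tractions
# MPa.  Internally forces are carried in kN (1 GPa mm^2 = 1 kN) so the
# system K u = f is consistent in GPa/mm; recovered stresses are reported
# in MPa.

#' Boundary-condition specification
#'
#' @param fixed named list: `node_set = axes`, where axes is a character
#'   subset of `c("x","y","z")` or `"all"`.
#' @param forces named list: `node_set = c(Fx, Fy, Fz)` total force in N,
#'   split equally over the set's nodes.
#' @param tractions named list: `face_set = c(tx, ty, tz)` traction in
#'   MPa, integrated over the face areas.
#' @return List of class `bc_spec`.
#' @export
bc_spec <- function(fixed = list(), forces = list(), tractions = list()) {
  structure(list(fixed = fixed, forces = forces, tractions = tractions),
            class = "bc_spec")
}

axis_ids <- function(axes) {
  if (identical(axes, "all")) return(1:3)
  m <- match(axes, c("x", "y", "z"))
  if (anyNA(m)) stop("axes must be a subset of x, y, z or 'all'")
  m
}

#' Solve the linear elastostatic problem
#'
#' Assembles `K = sum_e V_e B_e^T C_e B_e` over the included elements
#' (constant-strain tets, one 6x6 stiffness per element) and solves
#' `K u = f` with homogeneous Dirichlet restraints imposed by elimination.
#' Bonded interfaces (implant-bone) are realised by the shared-node mesh,
#' so no contact machinery is involved.
#'
#' @param mesh a [tet_mesh()].
#' @param elem_stiffness n_elems x 6 x 6 array of stiffness matrices
#'   (GPa); elements with an `NA` stiffness are excluded from the solve.
#' @param bcs a [bc_spec()].
#' @param exclude_regions region tags dropped from the solve (default:
#'   virtual fill, tag 9).
#' @return List with `u` (n_nodes x 3 displacements, mm; `NA` outside the
#'   solved submesh), `reactions` (n_nodes x 3, N, nonzero on restrained
#'   nodes), `residual` (relative), and `elem_ids` of solved elements.
#' @export
solve_elasticity <- function(mesh, elem_stiffness, bcs,
                             exclude_regions = region_tags()[["virtual"]]) {
  stopifnot(inherits(bcs, "bc_spec"))
  include <- setdiff(unique(mesh$region), exclude_regions)
  sub <- region_submesh(mesh, include)
  el <- sub$elem_ids
  has_C <- !is.na(elem_stiffness[el, 1L, 1L])
  if (!all(has_C))
    stop("stiffness undefined for solved element(s): ",
         paste(utils::head(el[!has_C], 10L), collapse = ", "))
  geo <- element_geometry(mesh)
  nn <- length(sub$node_ids)
  ndof <- 3L * nn
  ldof <- function(local_nodes)  # local node ids -> dof ids (x,y,z blocks)
    as.vector(rbind(3L * local_nodes - 2L, 3L * local_nodes - 1L,
                    3L * local_nodes))

  nel <- length(el)
  ii <- matrix(0L, 144L, nel); jj <- matrix(0L, 144L, nel)
  xx <- matrix(0, 144L, nel)
  idx12 <- rep(1:12, times = 12L)
  jdx12 <- rep(1:12, each = 12L)
  for (q in seq_len(nel)) {
    e <- el[q]
    G <- geo$grads[e, , ]                 # 4 x 3
    B <- matrix(0, 6L, 12L)
    cx <- seq(1L, 12L, by = 3L); cy <- cx + 1L; cz <- cx + 2L
    B[1, cx] <- G[, 1]
    B[2, cy] <- G[, 2]
    B[3, cz] <- G[, 3]
    B[4, cy] <- G[, 3]; B[4, cz] <- G[, 2]
    B[5, cx] <- G[, 3]; B[5, cz] <- G[, 1]
    B[6, cx] <- G[, 2]; B[6, cy] <- G[, 1]
    C <- matrix(elem_stiffness[e, , ], 6L, 6L)
    Ke <- geo$volume[e] * crossprod(B, C %*% B)
    dofs <- ldof(sub$local_index[mesh$tets[e, ]])
    ii[, q] <- dofs[idx12]
    jj[, q] <- dofs[jdx12]
    xx[, q] <- Ke
  }
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(xx), dims = c(ndof, ndof))

  # loads (internal unit kN)
  f <- numeric(ndof)
  for (nm in names(bcs$forces)) {
    s <- mesh$node_sets[[nm]]
    if (is.null(s)) stop("unknown node set in forces: ", nm)
    s <- s[!is.na(sub$local_index[s])]
    if (!length(s)) stop("force set '", nm, "' has no nodes in the solved domain")
    Fv <- bcs$forces[[nm]] / 1000 / length(s)
    loc <- sub$local_index[s]
    for (d in 1:3) f[3L * loc - 3L + d] <- f[3L * loc - 3L + d] + Fv[d]
  }
  for (nm in names(bcs$tractions)) {
    fc <- mesh$face_sets[[nm]]
    if (is.null(fc)) stop("unknown face set in tractions: ", nm)
    tv <- bcs$tractions[[nm]] / 1000    # MPa -> GPa
    for (r in seq_len(nrow(fc))) {
      tri <- fc[r, ]
      a <- mesh$nodes[tri[2], ] - mesh$nodes[tri[1], ]
      b <- mesh$nodes[tri[3], ] - mesh$nodes[tri[1], ]
      area <- sqrt(sum(c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])^2)) / 2
      loc <- sub$local_index[tri]
      if (anyNA(loc)) stop("traction face outside the solved domain")
      for (d in 1:3)
        f[3L * loc - 3L + d] <- f[3L * loc - 3L + d] + tv[d] * area / 3
    }
  }

  # restraints
  fixed_dofs <- integer()
  for (nm in names(bcs$fixed)) {
    s <- mesh$node_sets[[nm]]
    if (is.null(s)) stop("unknown node set in fixed: ", nm)
    s <- s[!is.na(sub$local_index[s])]
    loc <- sub$local_index[s]
    for (d in axis_ids(bcs$fixed[[nm]]))
      fixed_dofs <- c(fixed_dofs, 3L * loc - 3L + d)
  }
  fixed_dofs <- sort(unique(fixed_dofs))
  if (length(fixed_dofs) < 6L)
    stop("insufficient restraints: rigid-body modes remain")
  free <- setdiff(seq_len(ndof), fixed_dofs)

  u <- numeric(ndof)
  Kff <- K[free, free, drop = FALSE]
  sol <- tryCatch(Matrix::solve(Kff, f[free]),
                  error = function(e)
                    stop("stiffness system is singular; check restraints (",
                         conditionMessage(e), ")"))
  u[free] <- as.numeric(sol)
  res <- sqrt(sum((as.numeric(Kff %*% u[free]) - f[free])^2))
  fn <- sqrt(sum(f[free]^2))
  residual <- if (fn > 0) res / fn else res
  reactions_l <- as.numeric(K %*% u) - f   # kN; nonzero only on fixed dofs

  U <- matrix(NA_real_, n_nodes(mesh), 3L)
  Rn <- matrix(0, n_nodes(mesh), 3L)
  for (d in 1:3) {
    U[sub$node_ids, d] <- u[seq.int(d, ndof, by = 3L)]
    Rn[sub$node_ids, d] <- reactions_l[seq.int(d, ndof, by = 3L)] * 1000
  }
  Rn[abs(Rn) < 1e-12] <- 0
  list(u = U, reactions = Rn, residual = residual, elem_ids = el)
}

#' Recover element strains and stresses
#'
#' Constant per-element strain `eps = sym(grad u)` and stress
#' `sigma = C eps` (with the global-frame stiffness used in the solve).
#'
#' @param mesh a [tet_mesh()].
#' @param u n_nodes x 3 displacement field (mm).
#' @param elem_stiffness the stiffness array passed to
#'   [solve_elasticity()] (GPa).
#' @param elem_ids elements to recover (default: those with finite
#'   displacements on all nodes).
#' @return List with `strain` and `stress`: n_elems x 6 Voigt matrices
#'   (order 11,22,33,23,13,12; strain uses engineering shear, stress in
#'   MPa); `NA` rows outside `elem_ids`.
#' @export
recover_fields <- function(mesh, u, elem_stiffness, elem_ids = NULL) {
  if (is.null(elem_ids)) {
    ok <- !is.na(u[, 1])
    elem_ids <- which(rowSums(matrix(ok[mesh$tets], ncol = 4L)) == 4L)
  }
  geo <- element_geometry(mesh)
  m <- n_elems(mesh)
  strain <- matrix(NA_real_, m, 6L)
  stress <- matrix(NA_real_, m, 6L)
  for (e in elem_ids) {
    G <- geo$grads[e, , ]               # 4 x 3
    ue <- u[mesh$tets[e, ], ]           # 4 x 3
    H <- crossprod(G, ue)               # displacement gradient (du_j/dx_i)^T
    # H[i, j] = sum_a G[a,i] ue[a,j] = du_j / dx_i
    eps <- (H + t(H)) / 2
    ev <- c(eps[1, 1], eps[2, 2], eps[3, 3],
            2 * eps[2, 3], 2 * eps[1, 3], 2 * eps[1, 2])
    strain[e, ] <- ev
    C <- matrix(elem_stiffness[e, , ], 6L, 6L)
    stress[e, ] <- as.numeric(C %*% ev) * 1000   # GPa -> MPa
  }
  list(strain = strain, stress = stress)
}

#' Scalar stress/strain measures per element
#'
#' Principal values by symmetric eigendecomposition (sorted descending:
#' first = most tensile, third = most compressive, signed) and the
#' equivalent (von Mises) measure.  For strain the equivalent value is
#' normalised by `1 / (1 + nu_eff)` with an effective Poisson ratio, the
#' usual postprocessing convention.
#'
#' @param voigt n_elems x 6 Voigt matrix from [recover_fields()] (strain
#'   rows use engineering shear).
#' @param kind `"stress"` or `"strain"`.
#' @param nu_eff effective Poisson ratio for the equivalent strain
#'   (default 0.3).
#' @return Data frame with `equivalent`, `first_principal`,
#'   `third_principal` per element (`NA` where input is `NA`).
#' @export
scalar_measures <- function(voigt, kind = c("stress", "strain"),
                            nu_eff = 0.3) {
  kind <- match.arg(kind)
  m <- nrow(voigt)
  eq <- p1 <- p3 <- rep(NA_real_, m)
  half <- if (kind == "strain") 0.5 else 1
  for (e in seq_len(m)) {
    v <- voigt[e, ]
    if (anyNA(v)) next
    Tm <- matrix(c(v[1], half * v[6], half * v[5],
                   half * v[6], v[2], half * v[4],
                   half * v[5], half * v[4], v[3]), 3L, 3L)
    pv <- sort(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    p1[e] <- pv[1]; p3[e] <- pv[3]
    vm <- sqrt(0.5 * ((pv[1] - pv[2])^2 + (pv[2] - pv[3])^2 +
                      (pv[3] - pv[1])^2))
    eq[e] <- if (kind == "strain") vm / (1 + nu_eff) else vm
  }
  data.frame(equivalent = eq, first_principal = p1, third_principal = p3)
}

#' Build the per-element stiffness array for a material model
#'
#' Maps region tags to materials and, for orthotropic materials, rotates
#' the local stiffness into global coordinates with the element's frame.
#'
#' @param mesh a [tet_mesh()].
#' @param materials named list mapping region names (as in
#'   [region_tags()]) to [iso_constants()] / [ortho_constants()] objects.
#' @param frames a `frame_field` (required when any material is
#'   orthotropic).
#' @return n_elems x 6 x 6 array (GPa); `NA` for untagged/unassigned
#'   elements (e.g. virtual).
#' @export
element_stiffness <- function(mesh, materials, frames = NULL) {
  tags <- region_tags()
  m <- n_elems(mesh)
  arr <- array(NA_real_, c(m, 6L, 6L))
  for (nm in names(materials)) {
    tag <- tags[[nm]]
    if (is.null(tag)) stop("unknown region name: ", nm)
    el <- which(mesh$region == tag)
    if (!length(el)) next
    mat <- materials[[nm]]
    C_local <- stiffness_from_compliance(compliance_from_constants(mat))
    if (inherits(mat, "iso_constants")) {
      for (e in el) arr[e, , ] <- C_local
    } else {
      if (is.null(frames))
        stop("orthotropic material for region '", nm,
             "' needs a frame field")
      for (e in el) {
        R <- frame_matrix(frames, e)
        if (anyNA(R))
          stop("no frame available for orthotropic element ", e)
        arr[e, , ] <- rotate_stiffness(C_local, R)
      }
    }
  }
  arr
}
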