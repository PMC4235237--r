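# Orthotropic elasticity machinery: nine-constant compliance/stiffness in
# Voigt notation, Bond rotation into global coordinates, the
# Voigt-Reuss-Hill effective isotropic reduction, and the material
# database used by the comparison models.
#
# Voigt component order is (11, 22, 33, 23, 13, 12) with engineering
# (doubled) shear strains, so that S44 pairs with G23, S55 with G13 and
# S66 with G12 under the radial/tangential/axial direction naming.
# Poisson convention: S_ij = -nu_ij / E_i (nu_ij = -eps_j/eps_i under
# uniaxial stress along i), the dominant engineering convention.

#' Nine orthotropic engineering constants
#'
#' @param E1,E2,E3 Young's moduli along the radial (1), tangential (2) and
#'   axial (3) material directions (GPa).
#' @param G12,G13,G23 shear moduli (GPa).
#' @param nu12,nu13,nu23 Poisson's ratios (`nu_ij = -eps_j/eps_i` under
#'   uniaxial stress along i).
#' @return List of class `ortho_constants`.
#' @export
ortho_constants <- function(E1, E2, E3, G12, G13, G23, nu12, nu13, nu23) {
  p <- list(E1 = E1, E2 = E2, E3 = E3, G12 = G12, G13 = G13, G23 = G23,
            nu12 = nu12, nu13 = nu13, nu23 = nu23)
  if (any(unlist(p[1:6]) <= 0)) stop("all moduli must be positive")
  class(p) <- "ortho_constants"
  p
}

#' Isotropic elastic constants
#'
#' @param E Young's modulus (GPa).
#' @param nu Poisson's ratio.
#' @return List of class `iso_constants`.
#' @export
iso_constants <- function(E, nu) {
  if (E <= 0) stop("E must be positive")
  if (nu <= -1 || nu >= 0.5) stop("nu must lie in (-1, 0.5)")
  structure(list(E = E, nu = nu), class = "iso_constants")
}

#' Orthotropic compliance matrix from nine constants
#'
#' @param c an [ortho_constants()] or [iso_constants()] object (the latter
#'   is expanded with `G = E / (2 (1 + nu))`).
#' @param check verify positive definiteness (thermodynamic
#'   admissibility); default `TRUE`.
#' @return 6 x 6 compliance matrix (1/GPa), Voigt order
#'   (11, 22, 33, 23, 13, 12), engineering shear.
#' @export
compliance_from_constants <- function(c, check = TRUE) {
  if (inherits(c, "iso_constants"))
    c <- ortho_constants(c$E, c$E, c$E,
                         G12 = c$E / (2 * (1 + c$nu)),
                         G13 = c$E / (2 * (1 + c$nu)),
                         G23 = c$E / (2 * (1 + c$nu)),
                         nu12 = c$nu, nu13 = c$nu, nu23 = c$nu)
  stopifnot(inherits(c, "ortho_constants"))
  S <- matrix(0, 6L, 6L)
  S[1, 1] <- 1 / c$E1; S[2, 2] <- 1 / c$E2; S[3, 3] <- 1 / c$E3
  S[4, 4] <- 1 / c$G23; S[5, 5] <- 1 / c$G13; S[6, 6] <- 1 / c$G12
  S[1, 2] <- S[2, 1] <- -c$nu12 / c$E1
  S[1, 3] <- S[3, 1] <- -c$nu13 / c$E1
  S[2, 3] <- S[3, 2] <- -c$nu23 / c$E2
  if (check) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop(sprintf("constants are thermodynamically inadmissible: compliance has a non-positive eigenvalue (%.3g)",
                   min(ev)))
  }
  S
}

#' Stiffness from compliance (and vice versa)
#'
#' @param S positive-definite 6 x 6 matrix.
#' @return Its inverse, symmetrised.
#' @export
stiffness_from_compliance <- function(S) {
  C <- tryCatch(solve(S), error = function(e)
    stop("compliance matrix is singular"))
  (C + t(C)) / 2
}

# Bond stress-transformation matrix for Voigt order (11,22,33,23,13,12):
# sigma'_voigt = M sigma_voigt for sigma' = R sigma R^T.  For stiffness in
# engineering-shear convention, C' = M C M^T.
bond_matrix <- function(R) {
  pr <- rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(2L, 3L), c(1L, 3L),
              c(1L, 2L))
  M <- matrix(0, 6L, 6L)
  for (a in 1:6) for (b in 1:6) {
    i <- pr[a, 1]; j <- pr[a, 2]; k <- pr[b, 1]; l <- pr[b, 2]
    M[a, b] <- if (k == l) R[i, k] * R[j, k]
               else R[i, k] * R[j, l] + R[i, l] * R[j, k]
  }
  M
}

#' Rotate a stiffness matrix into global coordinates
#'
#' Applies the Bond congruence `C_global = M(R) C_local M(R)^T`, the Voigt
#' form of the fourth-order rotation
#' `C'_ijkl = R_ip R_jq R_kr R_ls C_pqrs`, for a frame `R` whose columns
#' are the local material axes expressed in global coordinates.
#'
#' @param C_local 6 x 6 stiffness (GPa), engineering-shear Voigt form.
#' @param frame 3 x 3 orthonormal matrix with determinant +1 (columns e1,
#'   e2, e3).
#' @return Rotated 6 x 6 stiffness.
#' @export
rotate_stiffness <- function(C_local, frame) {
  R <- as.matrix(frame)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("frame must be orthonormal with determinant +1")
  M <- bond_matrix(R)
  Cg <- M %*% C_local %*% t(M)
  (Cg + t(Cg)) / 2
}

#' Voigt-Reuss-Hill effective isotropic moduli
#'
#' Reduces an orthotropic material to isotropic bounds: the Voigt
#' (uniform-strain, stiffness-average) and Reuss (uniform-stress,
#' compliance-average) bulk and shear moduli, their Hill arithmetic means,
#' and the corresponding Young's moduli and Poisson's ratios.
#'
#' @param c an [ortho_constants()] (or [iso_constants()], for which all
#'   three estimates coincide with the input).
#' @return List of class `effective_isotropic` with `K_V, G_V, K_R, G_R,
#'   K_H, G_H` and derived `E_V, nu_V, E_R, nu_R, E_H, nu_H` (GPa where
#'   dimensional).
#' @export
voigt_reuss_hill <- function(c) {
  S <- compliance_from_constants(c)
  C <- stiffness_from_compliance(S)
  K_V <- (C[1, 1] + C[2, 2] + C[3, 3] +
          2 * (C[1, 2] + C[1, 3] + C[2, 3])) / 9
  G_V <- (C[1, 1] + C[2, 2] + C[3, 3] - C[1, 2] - C[1, 3] - C[2, 3] +
          3 * (C[4, 4] + C[5, 5] + C[6, 6])) / 15
  K_R <- 1 / (S[1, 1] + S[2, 2] + S[3, 3] +
              2 * (S[1, 2] + S[1, 3] + S[2, 3]))
  G_R <- 15 / (4 * (S[1, 1] + S[2, 2] + S[3, 3]) -
               4 * (S[1, 2] + S[1, 3] + S[2, 3]) +
               3 * (S[4, 4] + S[5, 5] + S[6, 6]))
  K_H <- (K_V + K_R) / 2
  G_H <- (G_V + G_R) / 2
  En <- function(K, G) c(E = 9 * K * G / (3 * K + G),
                         nu = (3 * K - 2 * G) / (2 * (3 * K + G)))
  v <- En(K_V, G_V); r <- En(K_R, G_R); h <- En(K_H, G_H)
  structure(list(K_V = K_V, G_V = G_V, K_R = K_R, G_R = G_R,
                 K_H = K_H, G_H = G_H,
                 E_V = v[["E"]], nu_V = v[["nu"]],
                 E_R = r[["E"]], nu_R = r[["nu"]],
                 E_H = h[["E"]], nu_H = h[["nu"]]),
            class = "effective_isotropic")
}

#' @export
print.effective_isotropic <- function(x, ...) {
  cat(sprintf("effective isotropic moduli (GPa):\n"))
  cat(sprintf("  Voigt: E = %.4g, nu = %.4g\n", x$E_V, x$nu_V))
  cat(sprintf("  Reuss: E = %.4g, nu = %.4g\n", x$E_R, x$nu_R))
  cat(sprintf("  Hill : E = %.4g, nu = %.4g\n", x$E_H, x$nu_H))
  invisible(x)
}

#' Material database
#'
#' Elastic constants of the tissues and components of the implant-mandible
#' complex: isotropic enamel, dentin, articular cartilage, titanium
#' implant and zirconia crown; the effective isotropic bone values used by
#' the isotropic comparison model; and the nine-constant orthotropic rows
#' for mandibular cortical and cancellous bone (radial, tangential, axial
#' direction order).
#'
#' @param name optional material name; omitted returns the full named
#'   list.
#' @return An [iso_constants()] / [ortho_constants()] object, or the full
#'   list.
#' @export
material_db <- function(name = NULL) {
  db <- list(
    enamel = iso_constants(84.1, 0.33),
    dentin = iso_constants(18.6, 0.31),
    cartilage = iso_constants(0.8, 0.35),
    titanium = iso_constants(103.4, 0.35),
    zirconia = iso_constants(200, 0.31),
    bone_cortical_iso = iso_constants(16.42, 0.32),
    bone_cancellous_iso = iso_constants(0.482, 0.26),
    bone_cortical_ortho = ortho_constants(
      E1 = 12.7, E2 = 17.9, E3 = 22.8,
      G12 = 5.0, G13 = 5.5, G23 = 7.4,
      nu12 = 0.18, nu13 = 0.31, nu23 = 0.28),
    bone_cancellous_ortho = ortho_constants(
      E1 = 0.511, E2 = 0.114, E3 = 0.907,
      G12 = 0.078, G13 = 0.434, G23 = 0.081,
      nu12 = 0.22, nu13 = 0.31, nu23 = 0.30))
  if (is.null(name)) return(db)
  if (!name %in% names(db))
    stop("unknown material '", name, "'; available: ",
         paste(names(db), collapse = ", "))
  db[[name]]
}

# Brute-force fourth-order tensor rotation; the independent oracle for
# rotate_stiffness and handy for cross-checks.  Converts the
# engineering-shear Voigt stiffness to the full C_ijkl tensor, rotates
# component-wise, and converts back.
rotate_stiffness_tensor <- function(C_local, R) {
  pr <- rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(2L, 3L), c(1L, 3L),
              c(1L, 2L))
  vi <- matrix(0L, 3L, 3L)
  for (a in 1:6) {
    vi[pr[a, 1], pr[a, 2]] <- a
    vi[pr[a, 2], pr[a, 1]] <- a
  }
  C4 <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    C4[i, j, k, l] <- C_local[vi[i, j], vi[k, l]]
  C4r <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (p in 1:3) for (q in 1:3) for (r in 1:3) for (t in 1:3)
      s <- s + R[i, p] * R[j, q] * R[k, r] * R[l, t] * C4[p, q, r, t]
    C4r[i, j, k, l] <- s
  }
  out <- matrix(0, 6L, 6L)
  for (a in 1:6) for (b in 1:6)
    out[a, b] <- C4r[pr[a, 1], pr[a, 2], pr[b, 1], pr[b, 2]]
  out
}
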