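#' @include constructors.R
NULL

#' Isotropic linear-elasticity stiffness tensor (Voigt 6x6)
#'
#' Engineering-strain Voigt convention, units MPa when E is given in MPa.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 6x6 numeric matrix.
#' @export
elasticityTensor <- function(E, nu) {
  if (nu >= 0.5 - 1e-9)
    stop("Poisson's ratio at the incompressible limit (nu -> 0.5) is not ",
         "supported by the displacement formulation")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

# Trilinear shape-function derivative matrix dN/d(xi,eta,zeta) at a natural
# point; corner signs in standard hexahedron (VTK) order.
.hexSigns <- cbind(
  xi   = c(-1,  1,  1, -1, -1,  1,  1, -1),
  eta  = c(-1, -1,  1,  1, -1, -1,  1,  1),
  zeta = c(-1, -1, -1, -1,  1,  1,  1,  1))

.hexShapeDeriv <- function(xi, eta, zeta) {
  s <- .hexSigns
  dN <- matrix(0, 8, 3)
  dN[, 1] <- s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta) / 8
  dN[, 2] <- s[, 2] * (1 + s[, 1] * xi) * (1 + s[, 3] * zeta) / 8
  dN[, 3] <- s[, 3] * (1 + s[, 1] * xi) * (1 + s[, 2] * eta) / 8
  dN
}

#' Hexahedral (hex8) element stiffness matrix for a cubic voxel
#'
#' Standard trilinear displacement element with full 2x2x2 Gauss
#' integration on a cube of edge `edgeUm`.  Dof ordering is node-major
#' (ux, uy, uz for node 1, then node 2, ...), nodes in standard hexahedron
#' corner order.  The matrix is symmetric positive semidefinite with
#' exactly six zero-energy rigid-body modes, scales linearly in E and
#' linearly in the edge length.  Units: N/mm on mm displacements when E is
#' in GPa (internally converted to MPa = N/mm^2).
#'
#' @param material a [Material-class].
#' @param edgeUm cube edge length in micrometres.
#' @return 24x24 symmetric numeric matrix.
#' @examples
#' Ke <- hex8ElementMatrix(material(10, 0.3), 50)
#' range(rowSums(Ke[, seq(1, 24, by = 3)]))  # x-translation: zero force
#' @export
hex8ElementMatrix <- function(material, edgeUm) {
  stopifnot(is(material, "Material"))
  validObject(material)
  h <- edgeUm / 1000                      # mm
  E <- material@youngsModulusGPa * 1000   # MPa = N/mm^2
  C <- elasticityTensor(E, material@poissonRatio)
  gp <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(c(-gp, gp), c(-gp, gp), c(-gp, gp)))
  Ke <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  for (q in seq_len(nrow(pts))) {
    dN <- .hexShapeDeriv(pts[q, 1], pts[q, 2], pts[q, 3]) * (2 / h)
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      cix <- 3 * (a - 1)
      B[1, cix + 1] <- dN[a, 1]
      B[2, cix + 2] <- dN[a, 2]
      B[3, cix + 3] <- dN[a, 3]
      B[4, cix + 1] <- dN[a, 2]; B[4, cix + 2] <- dN[a, 1]
      B[5, cix + 2] <- dN[a, 3]; B[5, cix + 3] <- dN[a, 2]
      B[6, cix + 1] <- dN[a, 3]; B[6, cix + 3] <- dN[a, 1]
    }
    Ke <- Ke + t(B) %*% C %*% B * detJ
  }
  (Ke + t(Ke)) / 2
}

#' Timoshenko three-point-bending stiffness closed forms
#'
#' Midspan stiffness of a simply supported beam loaded at midspan,
#' including shear deformation:
#' `k = 1 / (L^3 / (48 E I) + L / (4 kappa G A))`.
#' For a rectangular section the shear correction factor is `kappa = 5/6`;
#' for a hollow circular section Cowper's expression
#' `kappa = 6 (1+nu) (1+m^2)^2 / ((7+6nu)(1+m^2)^2 + (20+12nu) m^2)` with
#' `m = rInner/rOuter` is used.  These closed forms are the independent
#' oracles for the voxel FE solver.
#'
#' @param spanMm support span L (mm).
#' @param material a [Material-class].
#' @param widthMm,heightMm rectangle width (axis 2) and height (axis 3).
#' @return stiffness in N/mm.
#' @export
timoshenkoRectStiffness <- function(spanMm, material, widthMm, heightMm) {
  E <- material@youngsModulusGPa * 1000
  G <- E / (2 * (1 + material@poissonRatio))
  I <- widthMm * heightMm^3 / 12
  A <- widthMm * heightMm
  kappa <- 5 / 6
  1 / (spanMm^3 / (48 * E * I) + spanMm / (4 * kappa * G * A))
}

#' @rdname timoshenkoRectStiffness
#' @param rOuterMm,rInnerMm annulus outer and inner radii (mm).
#' @export
timoshenkoAnnulusStiffness <- function(spanMm, material, rOuterMm,
                                       rInnerMm) {
  E <- material@youngsModulusGPa * 1000
  nu <- material@poissonRatio
  G <- E / (2 * (1 + nu))
  I <- pi / 4 * (rOuterMm^4 - rInnerMm^4)
  A <- pi * (rOuterMm^2 - rInnerMm^2)
  m <- rInnerMm / rOuterMm
  kappa <- 6 * (1 + nu) * (1 + m^2)^2 /
    ((7 + 6 * nu) * (1 + m^2)^2 + (20 + 12 * nu) * m^2)
  1 / (spanMm^3 / (48 * E * I) + spanMm / (4 * kappa * G * A))
}
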