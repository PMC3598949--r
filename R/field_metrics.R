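#' Volume of a tetrahedron
#'
#' `|det([p2-p1, p3-p1, p4-p1])| / 6`.
#'
#' @param coords 4 x 3 matrix of vertex coordinates (mm).
#' @return Volume in mm^3 (> 0).
#' @export
element_volume <- function(coords) {
  stopifnot(is.matrix(coords), nrow(coords) == 4, ncol(coords) == 3)
  m <- rbind(coords[2, ] - coords[1, ],
             coords[3, ] - coords[1, ],
             coords[4, ] - coords[1, ])
  v <- abs(det(m)) / 6
  if (v <= 1e-12) {
    stop("degenerate tetrahedron: vertices are coplanar (volume <= 1e-12 mm^3)")
  }
  v
}

# 3x3 symmetric tensor from a 6-vector (xx, yy, zz, xy, yz, zx) of *tensor*
# components (shear NOT engineering)
tensor_from_vec <- function(v) {
  matrix(c(v[1], v[4], v[6],
           v[4], v[2], v[5],
           v[6], v[5], v[3]), 3, 3)
}

#' Principal strains of a symmetric strain tensor
#'
#' Eigenvalues of the 3 x 3 symmetric strain tensor, sorted descending
#' (S1 >= S2 >= S3). Shear inputs are tensor components; engineering shear
#' must be halved first (see [tensor_field_records()] which does this for
#' solver output).
#'
#' @param tensor 3 x 3 symmetric matrix (asymmetry beyond 1e-8 is an error).
#' @return Numeric length-3 vector `c(S1, S2, S3)`.
#' @export
principal_strains <- function(tensor) {
  stopifnot(is.matrix(tensor), all(dim(tensor) == c(3, 3)))
  scale <- max(abs(tensor), 1)
  if (max(abs(tensor - t(tensor))) > 1e-8 * scale) {
    stop("strain tensor is not symmetric (asymmetry beyond 1e-8)")
  }
  sort(eigen((tensor + t(tensor)) / 2, symmetric = TRUE,
             only.values = TRUE)$values, decreasing = TRUE)
}

#' Equivalent strain from principal strains
#'
#' Scalar deformation measure built from the principal strains:
#' `S_e = 1/(1 + nu_eff) * sqrt(((S1-S2)^2 + (S2-S3)^2 + (S3-S1)^2) / 2)`.
#' It is non-negative, vanishes exactly for purely volumetric strain
#' (S1 = S2 = S3), and is homogeneous of degree one in the strains.
#'
#' Note the governing equation is a von-Mises-type deviatoric norm; the
#' effective Poisson's ratio `nu_eff` defaults to the material's ratio for
#' the element under analysis.
#'
#' @param p Length-3 principal strains (any order).
#' @param nu_eff Effective Poisson's ratio in (-1, 0.5].
#' @return Equivalent strain (unitless, >= 0).
#' @export
equivalent_strain <- function(p, nu_eff) {
  stopifnot(length(p) == 3)
  if (!is.finite(nu_eff) || nu_eff <= -1 || nu_eff > 0.5) {
    stop("nu_eff must lie in (-1, 0.5]")
  }
  sqrt(((p[1] - p[2])^2 + (p[2] - p[3])^2 + (p[3] - p[1])^2) / 2) / (1 + nu_eff)
}

#' Hydrostatic stress of a stress tensor
#'
#' The average of the three normal stress components,
#' `(sxx + syy + szz) / 3`; negative values mark net compression, positive
#' net tension. Invariant under coordinate rotation.
#'
#' @param tensor 3 x 3 symmetric stress tensor (MPa), or a length-6 vector
#'   (sxx, syy, szz, sxy, syz, szx).
#' @return Hydrostatic stress in MPa.
#' @export
hydrostatic_stress <- function(tensor) {
  if (is.matrix(tensor)) {
    stopifnot(all(dim(tensor) == c(3, 3)))
    scale <- max(abs(tensor), 1)
    if (max(abs(tensor - t(tensor))) > 1e-8 * scale) {
      stop("stress tensor is not symmetric")
    }
    (tensor[1, 1] + tensor[2, 2] + tensor[3, 3]) / 3
  } else {
    stopifnot(length(tensor) == 6)
    unname((tensor[1] + tensor[2] + tensor[3]) / 3)
  }
}

#' Biological response unit (BRU)
#'
#' The product of an element's hydrostatic stress (MPa) and its volume
#' (mm^3), in N mm. Increasingly negative values correspond to increasingly
#' strong biological responses to compression; increasingly positive values
#' to tension.
#'
#' @param sigma_h Hydrostatic stress, MPa.
#' @param volume Element volume, mm^3 (> 0).
#' @return BRU in N mm (vectorized).
#' @export
bru <- function(sigma_h, volume) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("BRU requires strictly positive element volumes")
  }
  sigma_h * volume
}

#' Per-element scalar records from a solved tensor field
#'
#' Reduces an `element_tensor_field` to the per-element scalars the cap
#' analysis consumes: volume, hydrostatic stress, equivalent strain and
#' BRU. Engineering shear strains are converted to tensor components before
#' the principal-strain computation; equivalent strain is evaluated with
#' each element's own material Poisson's ratio (vectorized through the
#' invariant identity `sum_(i<j) (Si-Sj)^2 = 3 tr(e^2) - tr(e)^2`).
#'
#' @param mesh A `tet_mesh`.
#' @param field An `element_tensor_field` from [recover_strain_stress()].
#' @param materials A [material_table()] (for `nu_eff` per element).
#' @return Data frame of class `element_records` with columns `element`,
#'   `region`, `volume` (mm^3), `sigma_h` (MPa), `s_e` (unitless),
#'   `bru` (N mm).
#' @export
tensor_field_records <- function(mesh, field, materials) {
  stopifnot(inherits(field, "element_tensor_field"))
  st <- field$strain
  exy <- st[, "gxy"] / 2; eyz <- st[, "gyz"] / 2; ezx <- st[, "gzx"] / 2
  tr1 <- st[, "exx"] + st[, "eyy"] + st[, "ezz"]
  tr2 <- st[, "exx"]^2 + st[, "eyy"]^2 + st[, "ezz"]^2 +
    2 * (exy^2 + eyz^2 + ezx^2)
  dev <- pmax(3 * tr2 - tr1^2, 0)
  nu <- material_for_elements(mesh$region, materials)$nu
  s_e <- sqrt(dev / 2) / (1 + nu)
  sigma_h <- (field$stress[, "sxx"] + field$stress[, "syy"] +
              field$stress[, "szz"]) / 3
  vol <- element_volumes(mesh)
  rec <- data.frame(element = seq_len(nrow(mesh$elements)),
                    region = mesh$region, volume = vol,
                    sigma_h = sigma_h, s_e = s_e,
                    bru = bru(sigma_h, vol))
  class(rec) <- c("element_records", "data.frame")
  rec
}
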