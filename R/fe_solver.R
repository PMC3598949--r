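#' Stiffness matrix of a single 4-node tetrahedron
#'
#' Standard constant-strain tetrahedron (tet4) stiffness for a homogeneous
#' isotropic linear-elastic material, `K = V * B' D B`. The result is a
#' symmetric positive semi-definite 12 x 12 matrix with exactly six zero
#' eigenvalues (the rigid-body modes).
#'
#' @param coords 4 x 3 matrix of node coordinates (mm), positively oriented.
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @return 12 x 12 numeric matrix; DOF ordering is (node1 x,y,z, node2 x,y,z, ...).
#'   Units N/mm.
#' @export
element_stiffness <- function(coords, E, nu) {
  stopifnot(is.matrix(coords), nrow(coords) == 4, ncol(coords) == 3)
  if (!is.finite(E) || E <= 0) stop("Young's modulus must be finite and > 0")
  if (!is.finite(nu) || nu <= -1 || nu >= 0.5) {
    stop("Poisson's ratio must lie in (-1, 0.5)")
  }
  .tet_stiffness_one(coords, E, nu)
}

#' Construct a load case
#'
#' A load case couples Dirichlet constraints (fixed degrees of freedom,
#' with optional prescribed nonzero values) with nodal forces.
#'
#' @param n_nodes Number of mesh nodes.
#' @param fixed Data frame with columns `node`, `axis` (1 = x, 2 = y, 3 = z)
#'   and optionally `value` (prescribed displacement, mm; default 0).
#' @param forces n x 3 matrix of nodal forces (N), or NULL for none.
#' @return A `load_case` list.
#' @export
load_case <- function(n_nodes, fixed, forces = NULL) {
  stopifnot(is.data.frame(fixed), all(c("node", "axis") %in% names(fixed)))
  if (nrow(fixed) == 0) stop("load case invalid: empty fixity set")
  if (is.null(fixed$value)) fixed$value <- 0
  stopifnot(all(fixed$node >= 1), all(fixed$node <= n_nodes),
            all(fixed$axis %in% 1:3))
  fixed <- fixed[!duplicated(fixed[, c("node", "axis")]), , drop = FALSE]
  if (is.null(forces)) {
    forces <- matrix(0, n_nodes, 3)
  }
  stopifnot(is.matrix(forces), nrow(forces) == n_nodes, ncol(forces) == 3)
  structure(list(fixed = fixed, forces = forces, n_nodes = n_nodes),
            class = "load_case")
}

# global DOF indices (1-based) of the constrained entries
fixed_dof_index <- function(load) {
  3L * (as.integer(load$fixed$node) - 1L) + as.integer(load$fixed$axis)
}

#' Assemble the global sparse stiffness matrix
#'
#' @param mesh A `tet_mesh`.
#' @param materials A [material_table()].
#' @return List with `K` (sparse symmetric 3n x 3n, N/mm) and `volume`
#'   (per-element volumes, mm^3).
#' @export
assemble_stiffness <- function(mesh, materials) {
  mat <- material_for_elements(mesh$region, materials)
  tr <- .assemble_triplets(mesh$nodes, mesh$elements, mat$E, mat$nu)
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(ndof, ndof), index1 = TRUE)
  list(K = Matrix::forceSymmetric(K), volume = tr$volume)
}

#' Solve the linear elastostatic problem
#'
#' Assembles the tet4 stiffness, imposes Dirichlet constraints by
#' row/column elimination (prescribed values are exact in the solution),
#' and solves the reduced symmetric system with a direct sparse Cholesky
#' factorization.
#'
#' @param mesh A `tet_mesh`.
#' @param materials A [material_table()].
#' @param load A [load_case()]. The constraints must remove all six
#'   rigid-body modes.
#' @return An `fe_solution`: list with `u` (n x 3 displacements, mm),
#'   `load`, and cached `K` and `f` for reaction recovery. The global
#'   equilibrium residual is stored as `residual`.
#' @export
solve_elasticity <- function(mesh, materials, load) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(load, "load_case"))
  if (load$n_nodes != nrow(mesh$nodes)) {
    stop("load case node count does not match the mesh")
  }
  asm <- assemble_stiffness(mesh, materials)
  K <- asm$K
  ndof <- nrow(K)
  f <- as.numeric(t(load$forces))

  fixed <- fixed_dof_index(load)
  if (length(fixed) < 6) {
    stop("singular system: fewer than six constrained degrees of freedom; ",
         "rigid-body modes are not removed")
  }
  uc <- load$fixed$value
  free <- setdiff(seq_len(ndof), fixed)

  u <- numeric(ndof)
  u[fixed] <- uc
  rhs <- f[free]
  if (any(uc != 0)) {
    rhs <- rhs - as.numeric(K[free, fixed, drop = FALSE] %*% uc)
  }
  uf <- tryCatch(
    as.numeric(Matrix::solve(K[free, free, drop = FALSE], rhs)),
    error = function(e) {
      stop("singular system: the constrained stiffness could not be ",
           "factorized (insufficient constraints to remove rigid-body ",
           "modes?): ", conditionMessage(e))
    })
  if (any(!is.finite(uf))) {
    stop("singular system: non-finite displacements returned; constraints ",
         "insufficient")
  }
  u[free] <- uf

  umat <- matrix(u, ncol = 3, byrow = TRUE)
  colnames(umat) <- c("ux", "uy", "uz")

  r <- as.numeric(K %*% u) - f
  applied <- f
  applied[fixed] <- 0
  denom <- max(sum(abs(applied)), sum(abs(r[fixed])), .Machine$double.eps)
  residual <- sum(abs(r[free])) / denom

  structure(list(u = umat, load = load, K = K, f = f,
                 volume = asm$volume, residual = residual),
            class = "fe_solution")
}

#' Recover per-element strain and stress tensors
#'
#' Element-wise constant strain from the tet4 shape-function gradients
#' (engineering shear components), and stress from isotropic Hooke's law
#' with each element's material.
#'
#' @param mesh A `tet_mesh`.
#' @param materials A [material_table()].
#' @param u Displacements: an `fe_solution` or an n x 3 matrix (mm).
#' @return An `element_tensor_field`: list with `strain` (ne x 6:
#'   exx, eyy, ezz, gxy, gyz, gzx; unitless, engineering shear) and
#'   `stress` (ne x 6: sxx, syy, szz, sxy, syz, szx; MPa).
#' @export
recover_strain_stress <- function(mesh, materials, u) {
  if (inherits(u, "fe_solution")) u <- u$u
  stopifnot(is.matrix(u), nrow(u) == nrow(mesh$nodes), ncol(u) == 3)
  strain <- .element_strains(mesh$nodes, mesh$elements, u)
  mat <- material_for_elements(mesh$region, materials)
  lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  mu <- mat$E / (2 * (1 + mat$nu))
  tr <- strain[, "exx"] + strain[, "eyy"] + strain[, "ezz"]
  stress <- cbind(
    sxx = lam * tr + 2 * mu * strain[, "exx"],
    syy = lam * tr + 2 * mu * strain[, "eyy"],
    szz = lam * tr + 2 * mu * strain[, "ezz"],
    sxy = mu * strain[, "gxy"],
    syz = mu * strain[, "gyz"],
    szx = mu * strain[, "gzx"]
  )
  structure(list(strain = strain, stress = stress),
            class = "element_tensor_field")
}

#' Reaction forces at constrained degrees of freedom
#'
#' `r = K u - f` evaluated at the fixed DOFs. Their vector sum balances the
#' applied loads (global equilibrium).
#'
#' @param solution An `fe_solution` from [solve_elasticity()], or an n x 3
#'   displacement matrix (in which case `mesh`, `materials` and `load` must
#'   be supplied for reassembly).
#' @param mesh,materials,load Only needed when `solution` is a bare matrix.
#' @return Data frame with columns `node`, `axis`, `force` (N).
#' @export
reaction_forces <- function(solution, mesh = NULL, materials = NULL,
                            load = NULL) {
  if (inherits(solution, "fe_solution")) {
    K <- solution$K
    f <- solution$f
    load <- solution$load
    u <- as.numeric(t(solution$u))
  } else {
    stopifnot(!is.null(mesh), !is.null(materials), !is.null(load))
    K <- assemble_stiffness(mesh, materials)$K
    f <- as.numeric(t(load$forces))
    u <- as.numeric(t(solution))
  }
  fixed <- fixed_dof_index(load)
  r <- as.numeric(K %*% u) - f
  data.frame(node = load$fixed$node, axis = load$fixed$axis,
             force = r[fixed])
}

#' Total applied force and total reaction, componentwise
#'
#' Convenience equilibrium check: returns the 3-vector sums of applied
#' nodal forces and of reactions; at convergence their sum is ~0.
#'
#' @param solution An `fe_solution`.
#' @return List with `applied`, `reaction` (3-vectors, N) and
#'   `relative_imbalance`.
#' @export
equilibrium_summary <- function(solution) {
  stopifnot(inherits(solution, "fe_solution"))
  applied <- colSums(solution$load$forces)
  rf <- reaction_forces(solution)
  reaction <- vapply(1:3, function(a) sum(rf$force[rf$axis == a]), 0)
  denom <- max(sqrt(sum(applied^2)), sqrt(sum(reaction^2)),
               .Machine$double.eps)
  list(applied = applied, reaction = reaction,
       relative_imbalance = sqrt(sum((applied + reaction)^2)) / denom)
}
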