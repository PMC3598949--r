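# shared fixtures: all meshes are generated in code at test time

# uniform single-region block of n voxels at the given pitch
box_mesh <- function(n = c(3, 3, 6), pitch = 1, region = "cancellous_bone") {
  voxels_to_tets(region_grid(array(match(region, region_labels()), dim = n),
                             pitch))
}

# a positively oriented reference tetrahedron
unit_tet <- matrix(c(0, 0, 0,
                     1, 0, 0,
                     0, 1, 0,
                     0, 0, 1), 4, 3, byrow = TRUE)

# small tooth-in-crypt scene that meshes quickly (19k elements)
small_geometry <- function(seed = 1L) {
  geometry_config(box = c(10, 5, 8), pitch = 0.5,
                  crown_centre = c(5, 2.5, 5.3), axis = c(0, 0, -1),
                  crown_radius = 1.1, root_length = 3,
                  follicle_thickness = 0.6, crypt_thickness = 0.5,
                  cortical_thickness = 0.5, pulp_radius = 0.4, seed = seed)
}

# random 3D rotation matrix (uniform via QR of Gaussian)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random symmetric 3x3 tensor
random_symmetric <- function(scale = 1) {
  a <- matrix(rnorm(9, sd = scale), 3, 3)
  (a + t(a)) / 2
}

# uniaxial bar problem: frictionless rollers on three faces, uniform
# axial traction on the top; closed form is uniform sigma_zz = F / A
uniaxial_bar <- function(n = c(3, 3, 6), pitch = 1, F_total = 90,
                         region = "cancellous_bone") {
  m <- box_mesh(n, pitch, region)
  tol <- 1e-9
  L <- n * pitch
  A <- L[1] * L[2]
  nd <- m$nodes
  fixed <- rbind(
    data.frame(node = which(nd[, 3] < tol), axis = 3, value = 0),
    data.frame(node = which(nd[, 1] < tol), axis = 1, value = 0),
    data.frame(node = which(nd[, 2] < tol), axis = 2, value = 0)
  )
  bf <- boundary_faces(m)
  top <- bf[apply(matrix(nd[bf, 3], ncol = 3), 1, min) > L[3] - tol, ,
            drop = FALSE]
  forces <- traction_loads(m, top, c(0, 0, F_total / A))
  list(mesh = m, load = load_case(nrow(nd), fixed, forces),
       F_total = F_total, A = A)
}

# Dirichlet patch test: affine displacement u = A x prescribed on every
# boundary node; interior strain must equal sym(A) exactly
patch_test_error <- function(mesh, materials, A) {
  bnodes <- sort(unique(as.integer(boundary_faces(mesh))))
  ub <- mesh$nodes[bnodes, , drop = FALSE] %*% t(A)
  fixed <- data.frame(node = rep(bnodes, each = 3),
                      axis = rep(1:3, times = length(bnodes)),
                      value = as.numeric(t(ub)))
  sol <- solve_elasticity(mesh, materials, load_case(nrow(mesh$nodes), fixed))
  fld <- recover_strain_stress(mesh, materials, sol)
  S <- (A + t(A)) / 2
  expected <- c(S[1, 1], S[2, 2], S[3, 3], 2 * S[1, 2], 2 * S[2, 3],
                2 * S[1, 3])
  max(abs(sweep(fld$strain, 2, expected))) / max(abs(expected))
}

# default-scene solve + cap analysis for one mode
solve_default_mode <- function(cfg, scene, mode) {
  lc <- make_load_case(scene$mesh, scene$muscles_for_mode(mode), mode = mode,
                       support_nodes = scene$support_nodes,
                       incisal_nodes = scene$incisal_nodes,
                       occlusal_nodes = scene$occlusal_nodes)
  sol <- solve_elasticity(scene$mesh, cfg$materials, lc)
  list(solution = sol,
       caps = analyze_solution(scene$mesh, cfg$materials, sol, mode,
                               cap_depth = cfg$cap_depth))
}
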