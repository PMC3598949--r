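#' Masticatory muscle specification
#'
#' A muscle acting on the model is described by its cross-sectional area,
#' the skeletal-muscle force constant, an activation scaling, a unit force
#' direction (direction cosines) and an attachment node set on the mesh
#' surface.
#'
#' @param name Muscle name.
#' @param X_MI Cross-sectional area, cm^2 (> 0).
#' @param K Skeletal-muscle force constant, N/cm^2 (> 0).
#' @param EMG_MI Activation scaling relative to maximal contraction, in [0, 1].
#' @param direction Length-3 force direction; normalized internally, must be
#'   nonzero.
#' @param attachment Integer vector of attachment node indices (non-empty).
#' @return A `muscle_spec` list.
#' @export
muscle_spec <- function(name, X_MI, K, EMG_MI, direction, attachment) {
  if (!is.finite(X_MI) || X_MI <= 0) stop("muscle ", name, ": X_MI must be > 0")
  if (!is.finite(K) || K <= 0) stop("muscle ", name, ": K must be > 0")
  if (!is.finite(EMG_MI) || EMG_MI < 0 || EMG_MI > 1) {
    stop("muscle ", name, ": EMG_MI must lie in [0, 1]")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("muscle ", name, ": direction must be nonzero")
  if (length(attachment) == 0) {
    stop("muscle ", name, ": attachment node set is empty")
  }
  structure(list(name = name, X_MI = X_MI, K = K, EMG_MI = EMG_MI,
                 direction = direction / nrm,
                 attachment = as.integer(attachment)),
            class = "muscle_spec")
}

#' Masticatory muscle force magnitude
#'
#' The force of a muscle is the product of its cross-sectional area, the
#' skeletal-muscle force constant and the activation scaling:
#' `M = X_MI * K * EMG_MI` (N).
#'
#' @param X_MI Cross-sectional area, cm^2 (> 0).
#' @param K Skeletal-muscle force constant, N/cm^2 (> 0).
#' @param EMG_MI Activation scaling in [0, 1].
#' @return Force magnitude in N.
#' @examples
#' muscle_force(5, 40, 0.5)  # 100 N
#' @export
muscle_force <- function(X_MI, K, EMG_MI) {
  if (!is.finite(X_MI) || X_MI <= 0) stop("X_MI must be finite and > 0")
  if (!is.finite(K) || K <= 0) stop("K must be finite and > 0")
  if (!is.finite(EMG_MI) || EMG_MI < 0 || EMG_MI > 1) {
    stop("EMG_MI must lie in [0, 1]")
  }
  X_MI * K * EMG_MI
}

#' Build the load case for a bite-force setting
#'
#' Distributes each muscle's total force equally over its attachment nodes
#' along its direction cosines, and assembles the mode's fixities: the
#' support corner nodes are fixed in all three axes, while the bite point
#' is restrained vertically -- at the incisal node set in `incisive` mode,
#' at the occlusal node set in `unilateral_molar` mode.
#'
#' @param mesh A `tet_mesh`.
#' @param muscles List of [muscle_spec()] objects.
#' @param mode `"incisive"` or `"unilateral_molar"`.
#' @param support_nodes Nodes fixed in all three axes (non-empty).
#' @param incisal_nodes Nodes restrained vertically in incisive mode.
#' @param occlusal_nodes Nodes restrained vertically in molar mode.
#' @param vertical_axis Which axis is "vertical" (default 3 = z).
#' @return A [load_case()].
#' @export
make_load_case <- function(mesh, muscles,
                           mode = c("incisive", "unilateral_molar"),
                           support_nodes, incisal_nodes = integer(),
                           occlusal_nodes = integer(), vertical_axis = 3L) {
  mode <- match.arg(mode)
  n <- nrow(mesh$nodes)
  if (length(support_nodes) == 0) {
    stop("load case invalid: empty support fixity set")
  }
  bite_nodes <- switch(mode, incisive = incisal_nodes,
                       unilateral_molar = occlusal_nodes)
  if (length(bite_nodes) == 0) {
    stop("load case invalid: empty ", mode, " bite fixity set")
  }

  forces <- matrix(0, n, 3)
  for (m in muscles) {
    stopifnot(inherits(m, "muscle_spec"))
    if (any(m$attachment < 1 | m$attachment > n)) {
      stop("muscle ", m$name, ": attachment nodes outside the mesh")
    }
    total <- muscle_force(m$X_MI, m$K, m$EMG_MI)
    per_node <- total / length(m$attachment)
    forces[m$attachment, ] <- forces[m$attachment, , drop = FALSE] +
      matrix(per_node * m$direction, length(m$attachment), 3, byrow = TRUE)
  }

  fixed <- rbind(
    data.frame(node = rep(as.integer(support_nodes), each = 3),
               axis = rep(1:3, times = length(support_nodes)), value = 0),
    data.frame(node = as.integer(bite_nodes),
               axis = as.integer(vertical_axis), value = 0)
  )
  load_case(n, fixed, forces)
}

#' Apply a uniform traction over boundary triangles as consistent nodal loads
#'
#' For linear tetrahedra a uniform traction on a triangulated surface is
#' represented exactly by giving each face node one third of
#' `traction * face area`. Used to reproduce closed-form uniform-stress
#' states (e.g. a uniaxial bar).
#'
#' @param mesh A `tet_mesh`.
#' @param faces nf x 3 matrix of boundary triangles (node indices), e.g.
#'   a subset of [boundary_faces()].
#' @param traction Length-3 traction vector (MPa, i.e. N/mm^2).
#' @return n x 3 matrix of nodal forces (N).
#' @export
traction_loads <- function(mesh, faces, traction) {
  stopifnot(is.matrix(faces), ncol(faces) == 3, length(traction) == 3)
  forces <- matrix(0, nrow(mesh$nodes), 3)
  a <- mesh$nodes[faces[, 2], , drop = FALSE] - mesh$nodes[faces[, 1], , drop = FALSE]
  b <- mesh$nodes[faces[, 3], , drop = FALSE] - mesh$nodes[faces[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  for (k in 1:3) {
    s <- rowsum(area / 3, faces[, k])
    idx <- as.integer(rownames(s))
    for (ax in 1:3) {
      forces[idx, ax] <- forces[idx, ax] + s[, 1] * traction[ax]
    }
  }
  forces
}
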