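#' Geometry configuration for the synthetic tooth-in-crypt scene
#'
#' Describes an idealized capsule-shaped unerupted tooth embedded in a
#' rectangular bone block: the tooth (enamel cap over a dentine body with an
#' optional pulp core) is wrapped in a soft dental-follicle shell, which is
#' in turn enclosed by a cortical bony crypt inside cancellous bone, the
#' whole block bounded by an outer cortical shell. All lengths in mm.
#'
#' @param box Numeric length-3, domain extents (mm). The domain is
#'   `[0, box[1]] x [0, box[2]] x [0, box[3]]`.
#' @param pitch Voxel edge length (mm); must divide every box extent.
#' @param crown_centre Numeric length-3, centre of the spherical crown (mm).
#' @param axis Numeric length-3, tooth long-axis direction pointing
#'   crown -> apex (normalized internally).
#' @param crown_radius Tooth capsule radius (mm).
#' @param root_length Distance crown centre -> apex centre along `axis` (mm).
#' @param follicle_thickness Soft follicle shell thickness (mm); must be at
#'   least one voxel so the shell survives voxelization.
#' @param crypt_thickness Cortical crypt wall thickness around the follicle (mm).
#' @param cortical_thickness Outer cortical shell thickness of the block (mm).
#' @param pulp_radius Pulp core radius (mm); 0 disables the pulp.
#' @param seed Integer recorded for provenance and used by downstream stages.
#' @return A validated list of class `geometry_config`.
#' @export
geometry_config <- function(box = c(14, 7, 10),
                            pitch = 0.5,
                            crown_centre = c(7, 3.5, 6.5),
                            axis = c(0, 0, -1),
                            crown_radius = 1.5,
                            root_length = 3.5,
                            follicle_thickness = 0.6,
                            crypt_thickness = 0.5,
                            cortical_thickness = 0.5,
                            pulp_radius = 0.6,
                            seed = 1L) {
  cfg <- list(box = as.numeric(box), pitch = as.numeric(pitch),
              crown_centre = as.numeric(crown_centre),
              axis = as.numeric(axis),
              crown_radius = as.numeric(crown_radius),
              root_length = as.numeric(root_length),
              follicle_thickness = as.numeric(follicle_thickness),
              crypt_thickness = as.numeric(crypt_thickness),
              cortical_thickness = as.numeric(cortical_thickness),
              pulp_radius = as.numeric(pulp_radius),
              seed = as.integer(seed))
  validate_geometry_config(cfg)
  class(cfg) <- "geometry_config"
  cfg
}

validate_geometry_config <- function(cfg) {
  stopifnot(length(cfg$box) == 3, length(cfg$crown_centre) == 3,
            length(cfg$axis) == 3)
  if (any(cfg$box <= 0)) stop("geometry invalid: box extents must be > 0")
  if (cfg$pitch <= 0) stop("geometry invalid: voxel pitch must be > 0")
  n <- cfg$box / cfg$pitch
  if (any(abs(n - round(n)) > 1e-9)) {
    stop("geometry invalid: voxel pitch must divide every box extent")
  }
  if (cfg$crown_radius <= 0) {
    stop("geometry invalid: degenerate tooth (crown radius must be > 0)")
  }
  if (cfg$root_length < 0) stop("geometry invalid: root length must be >= 0")
  if (cfg$follicle_thickness <= 0) {
    stop("geometry invalid: follicle thickness must be > 0")
  }
  if (cfg$follicle_thickness < cfg$pitch) {
    stop("geometry invalid: follicle shell thinner than one voxel ",
         "(follicle_thickness < pitch); the shell would not survive voxelization")
  }
  nrm <- sqrt(sum(cfg$axis^2))
  if (nrm < 1e-12) stop("geometry invalid: tooth axis direction is zero")
  # tooth + follicle must sit strictly inside the domain with at least one
  # voxel of bone beyond the follicle
  ax <- cfg$axis / nrm
  apex <- cfg$crown_centre + cfg$root_length * ax
  reach <- cfg$crown_radius + cfg$follicle_thickness + cfg$pitch
  lo <- pmin(cfg$crown_centre, apex) - reach
  hi <- pmax(cfg$crown_centre, apex) + reach
  if (any(lo < 0) || any(hi > cfg$box)) {
    stop("geometry invalid: tooth capsule plus follicle shell must lie inside ",
         "the domain with at least one voxel of bone beyond the follicle")
  }
  invisible(cfg)
}

#' Build the labelled voxel grid of the synthetic scene
#'
#' Classifies every voxel centre of the domain into a tissue region: the
#' tooth capsule (enamel hemisphere on the crown side of the crown centre,
#' dentine body, optional pulp core), a follicle shell of at least the
#' requested thickness around the tooth, a cortical crypt wall around the
#' follicle, an outer cortical shell at the domain boundary, and cancellous
#' bone elsewhere. The construction is deterministic; the config seed is
#' carried along for provenance.
#'
#' @param config A [geometry_config()].
#' @return A `region_grid`: 3D integer array of region codes with attributes
#'   `levels` (region names), `pitch`, and `config`.
#' @export
build_labelled_grid <- function(config) {
  validate_geometry_config(config)
  nvox <- as.integer(round(config$box / config$pitch))
  p <- config$pitch
  ax <- config$axis / sqrt(sum(config$axis^2))

  # voxel centre coordinates
  cx <- (seq_len(nvox[1]) - 0.5) * p
  cy <- (seq_len(nvox[2]) - 0.5) * p
  cz <- (seq_len(nvox[3]) - 0.5) * p
  X <- array(rep(cx, times = nvox[2] * nvox[3]), dim = nvox)
  Y <- array(rep(rep(cy, each = nvox[1]), times = nvox[3]), dim = nvox)
  Z <- array(rep(cz, each = nvox[1] * nvox[2]), dim = nvox)

  # axial coordinate s along crown->apex from the crown centre, and radial
  # distance d to the axis segment [crown centre, apex centre]
  dx <- X - config$crown_centre[1]
  dy <- Y - config$crown_centre[2]
  dz <- Z - config$crown_centre[3]
  s <- dx * ax[1] + dy * ax[2] + dz * ax[3]
  sc <- pmin(pmax(s, 0), config$root_length)  # clamp to the segment
  d2 <- (dx - sc * ax[1])^2 + (dy - sc * ax[2])^2 + (dz - sc * ax[3])^2
  d <- sqrt(d2)

  lv <- region_labels()
  code <- function(nm) match(nm, lv)
  lab <- array(code("cancellous_bone"), dim = nvox)

  # outer cortical shell of the block
  shell <- (X < config$cortical_thickness) | (X > config$box[1] - config$cortical_thickness) |
           (Y < config$cortical_thickness) | (Y > config$box[2] - config$cortical_thickness) |
           (Z < config$cortical_thickness) | (Z > config$box[3] - config$cortical_thickness)
  lab[shell] <- code("cortical_bone")

  # morphological dilation by the 26-neighbourhood, `iter` shells deep
  dilate <- function(mask, iter) {
    dd <- dim(mask)
    for (it in seq_len(iter)) {
      out <- mask
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ia <- max(1, 1 + di):min(dd[1], dd[1] + di)
        ja <- max(1, 1 + dj):min(dd[2], dd[2] + dj)
        ka <- max(1, 1 + dk):min(dd[3], dd[3] + dk)
        out[ia, ja, ka] <- out[ia, ja, ka] | mask[ia - di, ja - dj, ka - dk]
      }
      mask <- out
    }
    mask
  }

  r <- config$crown_radius
  tooth <- d <= r
  # the follicle must survive voxelization as a full shell: combine the
  # Euclidean offset surface with a voxel dilation of the tooth mask
  n_shell <- ceiling(config$follicle_thickness / p - 1e-9)
  follicle <- (d <= r + config$follicle_thickness) | dilate(tooth, n_shell)
  n_crypt <- ceiling(config$crypt_thickness / p - 1e-9)
  crypt <- (d <= r + config$follicle_thickness + config$crypt_thickness) |
    (if (n_crypt > 0) dilate(follicle, n_crypt) else follicle)
  lab[crypt] <- code("cortical_bone")
  lab[follicle] <- code("follicle_pdl")
  lab[tooth] <- code("dentine")
  if (config$pulp_radius > 0) {
    pulp <- tooth & (d <= config$pulp_radius) & (s >= r / 2) & (s <= config$root_length)
    lab[pulp] <- code("pulp")
  }
  enamel <- tooth & (s <= 0)
  lab[enamel] <- code("enamel")

  structure(lab, levels = lv, pitch = p, config = config,
            class = "region_grid")
}

#' Construct a region grid from a label array
#'
#' Low-level constructor for externally defined voxel label fields (e.g.
#' uniform blocks for solver verification). Labels may be region names or
#' integer codes into [region_labels()].
#'
#' @param labels 3D array of region names or integer codes.
#' @param pitch Voxel edge length (mm).
#' @param config Optional `geometry_config` carried for provenance.
#' @return A `region_grid`.
#' @export
region_grid <- function(labels, pitch, config = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3, pitch > 0)
  lv <- region_labels()
  if (is.character(labels)) {
    codes <- match(labels, lv)
    if (anyNA(codes)) {
      stop("unknown region labels: ",
           paste(unique(labels[is.na(codes)]), collapse = ", "))
    }
    labels <- array(codes, dim = dim(labels))
  } else {
    if (any(labels < 1 | labels > length(lv))) {
      stop("region codes must index region_labels()")
    }
    labels <- array(as.integer(labels), dim = dim(labels))
  }
  structure(labels, levels = lv, pitch = pitch, config = config,
            class = "region_grid")
}

#' Convert a labelled voxel grid to a conforming tetrahedral mesh
#'
#' Splits each voxel cube into 6 tetrahedra along a globally consistent
#' main diagonal (Kuhn subdivision), so faces of adjacent cubes triangulate
#' identically and the mesh conforms. Element region labels are inherited
#' from the voxel. All tetrahedra are positively oriented with volume
#' `pitch^3 / 6`.
#'
#' @param grid A `region_grid` from [build_labelled_grid()].
#' @return A `tet_mesh`: list with `nodes` (n x 3 matrix, mm), `elements`
#'   (ne x 4 integer matrix, 1-based), `region` (character, length ne), and
#'   the generating `config`.
#' @export
voxels_to_tets <- function(grid) {
  stopifnot(inherits(grid, "region_grid"))
  nvox <- dim(grid)
  p <- attr(grid, "pitch")
  nx <- nvox[1]; ny <- nvox[2]; nz <- nvox[3]

  # lattice nodes
  gx <- 0:nx * p; gy <- 0:ny * p; gz <- 0:nz * p
  nodes <- cbind(
    x = rep(gx, times = (ny + 1) * (nz + 1)),
    y = rep(rep(gy, each = nx + 1), times = nz + 1),
    z = rep(gz, each = (nx + 1) * (ny + 1))
  )

  nid <- function(i, j, k) i + (nx + 1L) * (j + (ny + 1L) * k) + 1L
  vi <- rep(0:(nx - 1L), times = ny * nz)
  vj <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  vk <- rep(0:(nz - 1L), each = nx * ny)

  # cube corners c0..c7, bit order x + 2y + 4z
  c0 <- nid(vi,      vj,      vk)
  c1 <- nid(vi + 1L, vj,      vk)
  c2 <- nid(vi,      vj + 1L, vk)
  c3 <- nid(vi + 1L, vj + 1L, vk)
  c4 <- nid(vi,      vj,      vk + 1L)
  c5 <- nid(vi + 1L, vj,      vk + 1L)
  c6 <- nid(vi,      vj + 1L, vk + 1L)
  c7 <- nid(vi + 1L, vj + 1L, vk + 1L)

  # Kuhn subdivision along the c0-c7 diagonal, corrected to positive
  # orientation; every cube uses the same scheme so shared faces conform
  tets <- rbind(
    cbind(c0, c1, c3, c7),
    cbind(c0, c1, c7, c5),
    cbind(c0, c2, c7, c3),
    cbind(c0, c2, c6, c7),
    cbind(c0, c4, c5, c7),
    cbind(c0, c4, c7, c6)
  )
  dimnames(tets) <- NULL
  region <- rep(attr(grid, "levels")[as.integer(grid)], times = 6)

  mesh <- list(nodes = nodes, elements = tets, region = region,
               config = attr(grid, "config"))
  class(mesh) <- "tet_mesh"
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$elements), "elements\n")
  cat("regions:\n")
  print(table(x$region))
  invisible(x)
}

#' Element centroids
#' @param mesh A `tet_mesh`.
#' @return ne x 3 matrix of element centroids (mm).
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elements[, 1], , drop = FALSE] +
   mesh$nodes[mesh$elements[, 2], , drop = FALSE] +
   mesh$nodes[mesh$elements[, 3], , drop = FALSE] +
   mesh$nodes[mesh$elements[, 4], , drop = FALSE]) / 4
}

#' Signed and absolute tetrahedron volumes of a mesh
#' @param mesh A `tet_mesh`.
#' @param signed Return signed volumes (orientation check) instead of absolute.
#' @return Numeric vector of element volumes (mm^3).
#' @export
element_volumes <- function(mesh, signed = FALSE) {
  a <- mesh$nodes[mesh$elements[, 2], , drop = FALSE] - mesh$nodes[mesh$elements[, 1], , drop = FALSE]
  b <- mesh$nodes[mesh$elements[, 3], , drop = FALSE] - mesh$nodes[mesh$elements[, 1], , drop = FALSE]
  d <- mesh$nodes[mesh$elements[, 4], , drop = FALSE] - mesh$nodes[mesh$elements[, 1], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
         a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
         a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
  v <- det / 6
  if (signed) v else abs(v)
}

#' Boundary triangular faces of a tetrahedral mesh
#'
#' A face is on the boundary iff it belongs to exactly one tetrahedron.
#'
#' @param mesh A `tet_mesh`.
#' @return Integer matrix (nf x 3) of node indices of boundary triangles.
#' @export
boundary_faces <- function(mesh) {
  el <- mesh$elements
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
                 el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  cnt <- table(key)
  faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

#' Select mesh nodes by coordinate predicate
#'
#' Convenience selector used when defining attachments, supports and bite
#' fixities on generated meshes.
#'
#' @param mesh A `tet_mesh`.
#' @param predicate Function of (x, y, z) vectors returning a logical vector.
#' @return Integer vector of node indices.
#' @export
nodes_where <- function(mesh, predicate) {
  keep <- predicate(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3])
  which(keep)
}
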