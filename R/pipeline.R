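#' Default run configuration for the synthetic tooth-in-crypt study
#'
#' Bundles everything a pipeline run needs: the synthetic geometry, material
#' overrides, the muscle roster (with per-mode activation scalings), the
#' load modes, cap depth, histogram edges and exception margin, and the
#' seed. The default scene treats the bone block as a cut-out segment of
#' the mandibular corpus under functional bending: the elevator musculature
#' acts far from the crypt, and what the segment feels is the flexural
#' couple transmitted across its cut end faces. That couple is applied as
#' paired upper/lower force patches on each end face (axially transmitted
#' bite load), putting the occlusal-side fibres into compression and the
#' lower border into tension, with corner supports and a mode-specific
#' vertical bite-point restraint removing the rigid-body modes.
#'
#' @param seed Integer seed recorded in all outputs.
#' @param geometry A [geometry_config()].
#' @param material_overrides Passed to [material_table()].
#' @param modes Load modes to run.
#' @param cap_depth Cap depth in mm (default 3).
#' @param exception_margin Near-miss margin in percentage points (default 4).
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       geometry = geometry_config(seed = seed),
                       material_overrides = NULL,
                       modes = c("incisive", "unilateral_molar"),
                       cap_depth = 3,
                       exception_margin = 4) {
  materials <- material_table(material_overrides)  # validates early
  stopifnot(all(modes %in% c("incisive", "unilateral_molar")),
            length(modes) >= 1)
  if (!is.finite(cap_depth) || cap_depth <= 0) {
    stop("run config invalid: cap depth must be > 0")
  }
  emg <- c(incisive = 0.4, unilateral_molar = 1.0)
  cfg <- list(
    geometry = geometry,
    material_overrides = material_overrides,
    materials = materials,
    muscles = list(
      list(name = "flexure_anterior_upper", X_MI = 3.0, K = 40, emg = emg,
           direction = c(+1, 0, 0), attachment_set = "anterior_upper"),
      list(name = "flexure_anterior_lower", X_MI = 3.0, K = 40, emg = emg,
           direction = c(-1, 0, 0), attachment_set = "anterior_lower"),
      list(name = "flexure_posterior_upper", X_MI = 3.0, K = 40, emg = emg,
           direction = c(-1, 0, 0), attachment_set = "posterior_upper"),
      list(name = "flexure_posterior_lower", X_MI = 3.0, K = 40, emg = emg,
           direction = c(+1, 0, 0), attachment_set = "posterior_lower")
    ),
    modes = modes,
    cap_depth = cap_depth,
    exception_margin = exception_margin,
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `seed`, `modes`, `cap_depth`, `exception_margin`,
#' `geometry` (fields of [geometry_config()]) and `materials` (per-region
#' `E` / `nu` overrides). Missing keys fall back to the defaults of
#' [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  geo_args <- y$geometry %||% list()
  geo_args$seed <- seed
  geometry <- do.call(geometry_config, geo_args)
  run_config(
    seed = seed,
    geometry = geometry,
    material_overrides = y$materials,
    modes = y$modes %||% c("incisive", "unilateral_molar"),
    cap_depth = y$cap_depth %||% 3,
    exception_margin = y$exception_margin %||% 4
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the synthetic scene: mesh, node sets, and muscle roster per mode
#'
#' Generates the labelled grid and conforming tet mesh, and derives the
#' node sets of the default scene from the geometry: corner support strips
#' on the lower border at both ends (fixed in all axes), incisal and
#' occlusal bite patches on the occlusal (top) surface at the anterior and
#' molar ends (restrained vertically per mode), and the paired elevator
#' muscle attachments in bands flanking the crypt with mirrored lateral
#' components.
#'
#' @param config A [run_config()].
#' @return List with `grid`, `mesh`, `materials`, node sets
#'   (`support_nodes`, `incisal_nodes`, `occlusal_nodes`), and
#'   `muscles_for_mode(mode)` returning the instantiated [muscle_spec()]s.
#' @export
build_scene <- function(config) {
  stopifnot(inherits(config, "run_config"))
  geo <- config$geometry
  grid <- build_labelled_grid(geo)
  mesh <- voxels_to_tets(grid)
  box <- geo$box; p <- geo$pitch
  tol <- 1e-9

  # corner supports: the four bottom corners of the block, all three axes
  support_nodes <- nodes_where(mesh, function(x, y, z)
    z < tol & (x < tol | x > box[1] - tol) & (y < tol | y > box[2] - tol))
  incisal_nodes <- nodes_where(mesh, function(x, y, z)
    z > box[3] - tol & x <= p + tol)
  occlusal_nodes <- nodes_where(mesh, function(x, y, z)
    z > box[3] - tol & x >= box[1] - p - tol)

  # flexural-couple patches on the cut end faces: upper and lower thirds
  upper <- function(z) z >= 0.7 * box[3] - tol
  lower <- function(z) z <= 0.3 * box[3] + tol
  attachments <- list(
    anterior_upper = nodes_where(mesh, function(x, y, z) x < tol & upper(z)),
    anterior_lower = nodes_where(mesh, function(x, y, z) x < tol & lower(z)),
    posterior_upper = nodes_where(mesh, function(x, y, z)
      x > box[1] - tol & upper(z)),
    posterior_lower = nodes_where(mesh, function(x, y, z)
      x > box[1] - tol & lower(z))
  )

  muscles_for_mode <- function(mode) {
    lapply(config$muscles, function(m) {
      muscle_spec(name = m$name, X_MI = m$X_MI, K = m$K,
                  EMG_MI = unname(m$emg[[mode]]),
                  direction = m$direction,
                  attachment = attachments[[m$attachment_set]])
    })
  }

  list(grid = grid, mesh = mesh, materials = config$materials,
       support_nodes = support_nodes, incisal_nodes = incisal_nodes,
       occlusal_nodes = occlusal_nodes, attachments = attachments,
       muscles_for_mode = muscles_for_mode)
}

#' Cap analysis of one solved load case
#'
#' Recovers tensors and scalar records, determines the tooth axis from the
#' tooth elements, selects the coronal and apical follicle caps, and
#' summarizes each.
#'
#' @param mesh A `tet_mesh`.
#' @param materials A [material_table()].
#' @param solution An `fe_solution`.
#' @param load_mode Load-mode label carried into the summaries.
#' @param cap_depth Cap depth, mm.
#' @param tooth,side Identifiers carried into the summaries.
#' @return List of two `cap_summary` objects (`coronal`, `apical`).
#' @export
analyze_solution <- function(mesh, materials, solution, load_mode,
                             cap_depth = 3, tooth = "synthetic",
                             side = "left") {
  field <- recover_strain_stress(mesh, materials, solution)
  records <- tensor_field_records(mesh, field, materials)
  tooth_el <- which(mesh$region %in% c("enamel", "dentine", "pulp"))
  follicle_el <- which(mesh$region == "follicle_pdl")
  ax <- tooth_axis(mesh, tooth_el)
  out <- lapply(c(coronal = "coronal", apical = "apical"), function(kind) {
    cap <- cap_spec(tooth, side, kind, axis = ax, depth = cap_depth)
    idx <- select_cap_elements(mesh, follicle_el, cap)
    cap_summary(records[records$element %in% idx, , drop = FALSE],
                cap, load_mode)
  })
  out
}

summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(tooth = s$tooth, side = s$side, load = s$load, cap = s$cap,
               basis = c("volume", "bru"),
               percent = c(s$volume_compression_percent,
                           s$bru_compression_percent),
               total_volume = s$total_volume)
  }))
}

histogram_long <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    rows <- function(h, basis) {
      do.call(rbind, lapply(c("compression", "tension"), function(curve) {
        d <- h[[curve]]
        d$curve <- curve
        d$basis <- basis
        d
      }))
    }
    hs <- rows(s$histogram_stress, "sigma_h")
    hb <- rows(s$histogram_bru, "abs_bru")
    hs$bru_percent <- NA_real_
    names(hs)[names(hs) == "percent"] <- "volume_percent"
    hs$mass <- NULL
    common <- c("bin", "lower", "upper", "volume_percent", "bru_percent",
                "curve", "basis")
    d <- rbind(hs[, common], hb[, common])
    d$tooth <- s$tooth; d$side <- s$side; d$load <- s$load; d$cap <- s$cap
    d
  }))
}

#' Run the full generate -> solve -> analyze -> report pipeline
#'
#' Executes every stage for each configured load mode and writes a
#' self-describing output directory: the verbatim configuration, the
#' region-labelled mesh and per-mode field files (legacy VTK), the
#' compression-percentage table, pooled table, histogram curves and
#' exception report (CSV), and a JSON manifest listing stage timings and a
#' content hash of every output file. Deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly; the analysis objects are attached as
#'   attribute `results`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  clock <- function(stage, expr) {
    s <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
    })
    stages[[stage]] <<- proc.time()[["elapsed"]] - s
    val
  }

  yaml::write_yaml(list(
    seed = config$seed, modes = config$modes, cap_depth = config$cap_depth,
    exception_margin = config$exception_margin,
    geometry = unclass(config$geometry),
    materials = config$material_overrides
  ), file.path(out_dir, "run_config.yaml"))

  scene <- clock("generate", build_scene(config))
  mesh <- scene$mesh
  message("generate: ", nrow(mesh$nodes), " nodes, ", nrow(mesh$elements),
          " elements")
  write_vtk_mesh(mesh, file.path(out_dir, "mesh.vtk"))

  all_summaries <- list()
  for (mode in config$modes) {
    load <- make_load_case(mesh, scene$muscles_for_mode(mode), mode = mode,
                           support_nodes = scene$support_nodes,
                           incisal_nodes = scene$incisal_nodes,
                           occlusal_nodes = scene$occlusal_nodes)
    sol <- clock(paste0("solve_", mode),
                 solve_elasticity(mesh, config$materials, load))
    message("solve [", mode, "]: equilibrium residual ",
            format(sol$residual, digits = 3))
    caps <- clock(paste0("analyze_", mode),
                  analyze_solution(mesh, config$materials, sol, mode,
                                   cap_depth = config$cap_depth))
    field <- recover_strain_stress(mesh, config$materials, sol)
    rec <- tensor_field_records(mesh, field, config$materials)
    write_vtk_mesh(mesh, file.path(out_dir, paste0("fields_", mode, ".vtk")),
                   cell_data = list(volume = rec$volume,
                                    sigma_h = rec$sigma_h,
                                    s_e = rec$s_e, bru = rec$bru),
                   point_data = list(displacement = sol$u))
    all_summaries <- c(all_summaries, unname(caps))
  }

  clock("report", {
    tab <- summary_table(all_summaries)
    utils::write.csv(tab, file.path(out_dir, "compression_percentages.csv"),
                     row.names = FALSE)
    pooled <- pool_caps(all_summaries, exclude_teeth = "second_molar")
    utils::write.csv(pooled, file.path(out_dir, "pooled_percentages.csv"),
                     row.names = FALSE)
    utils::write.csv(histogram_long(all_summaries),
                     file.path(out_dir, "histograms.csv"), row.names = FALSE)
    exc <- classify_exceptions(tab, margin = config$exception_margin,
                               eruptive_teeth = unique(tab$tooth))
    utils::write.csv(exc$table, file.path(out_dir, "exceptions.csv"),
                     row.names = FALSE)
    message("report: ", sum(exc$table$is_exception), " exception(s) in ",
            nrow(exc$table), " instances")
    invisible(NULL)
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "eruptsim",
    version = as.character(utils::packageVersion("eruptsim")),
    seed = config$seed,
    n_nodes = nrow(mesh$nodes),
    n_elements = nrow(mesh$elements),
    total_seconds = proc.time()[["elapsed"]] - t0,
    stages = stages,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "results") <- all_summaries
  invisible(manifest)
}
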