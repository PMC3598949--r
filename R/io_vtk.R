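#' Write a tetrahedral mesh (and optional fields) as legacy VTK
#'
#' ASCII legacy unstructured-grid format with tetrahedral cells (VTK cell
#' type 10). Region labels are written as integer cell data `region`
#' (codes index [region_labels()]); additional per-element scalar fields go
#' out as named cell data and per-node vectors (e.g. displacement) as point
#' data. Coordinates are printed with 17 significant digits so a
#' write/read round-trip reproduces them to better than 1e-12.
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file path.
#' @param cell_data Named list of numeric per-element vectors.
#' @param point_data Named list of n x 3 matrices (per-node vectors).
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, cell_data = list(),
                           point_data = list()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  con <- file(path, open = "wt")
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 17)

  writeLines(c("# vtk DataFile Version 2.0",
               "eruptsim tetrahedral mesh",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(paste(num(mesh$nodes[, 1]), num(mesh$nodes[, 2]),
                   num(mesh$nodes[, 3])), con)
  writeLines(paste("CELLS", ne, 5L * ne), con)
  writeLines(paste(4L, mesh$elements[, 1] - 1L, mesh$elements[, 2] - 1L,
                   mesh$elements[, 3] - 1L, mesh$elements[, 4] - 1L), con)
  writeLines(paste("CELL_TYPES", ne), con)
  writeLines(as.character(rep(10L, ne)), con)

  writeLines(paste("CELL_DATA", ne), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$region, region_labels())), con)
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    stopifnot(length(v) == ne)
    writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"),
               con)
    writeLines(num(v), con)
  }
  if (length(point_data) > 0) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(point_data)) {
      m <- point_data[[nm]]
      stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == 3)
      writeLines(paste("VECTORS", nm, "double"), con)
      writeLines(paste(num(m[, 1]), num(m[, 2]), num(m[, 3])), con)
    }
  }
  invisible(path)
}

#' Read a tetrahedral mesh (and fields) from legacy VTK
#'
#' Parses an ASCII legacy unstructured-grid file. Only tetrahedral cells
#' (VTK type 10) are accepted; any other cell type is an error naming the
#' offending type. Integer cell data `region` is mapped back to region
#' labels; other cell data and point-data vectors are returned alongside.
#'
#' @param path Input file path.
#' @return List with `mesh` (a `tet_mesh`), `cell_data` (named list) and
#'   `point_data` (named list of n x 3 matrices).
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  i <- 1L
  find_section <- function(word) {
    while (i <= length(toks)) {
      if (length(toks[[i]]) > 0 && toks[[i]][1] == word) return(i)
      i <<- i + 1L
    }
    stop("malformed VTK file: section ", word, " not found in ", path)
  }
  numbers_after <- function(start, count) {
    vals <- numeric(0)
    j <- start
    while (length(vals) < count && j <= length(toks)) {
      vals <- c(vals, as.numeric(toks[[j]]))
      j <- j + 1L
    }
    if (length(vals) < count) stop("malformed VTK file: truncated block")
    list(vals = vals[seq_len(count)], next_line = j)
  }

  ln <- find_section("POINTS")
  n <- as.integer(toks[[ln]][2])
  pts <- numbers_after(ln + 1L, 3L * n)
  nodes <- matrix(pts$vals, ncol = 3, byrow = TRUE)
  colnames(nodes) <- c("x", "y", "z")

  i <- pts$next_line
  ln <- find_section("CELLS")
  ne <- as.integer(toks[[ln]][2])
  total <- as.integer(toks[[ln]][3])
  cl <- numbers_after(ln + 1L, total)
  i <- cl$next_line
  ln <- find_section("CELL_TYPES")
  ct <- numbers_after(ln + 1L, ne)
  types <- as.integer(ct$vals)
  if (any(types != 10L)) {
    bad <- unique(types[types != 10L])
    vtk_names <- c(`1` = "vertex", `3` = "line", `5` = "triangle",
                   `9` = "quad", `10` = "tetra", `12` = "hexahedron",
                   `13` = "wedge", `14` = "pyramid")
    nm <- ifelse(as.character(bad) %in% names(vtk_names),
                 vtk_names[as.character(bad)], paste("type", bad))
    stop("unsupported VTK cell type(s): ", paste(nm, collapse = ", "),
         "; only tetrahedra (type 10) are supported")
  }
  cells <- matrix(as.integer(cl$vals), ncol = 5, byrow = TRUE)
  if (any(cells[, 1] != 4L)) {
    stop("malformed VTK file: tetrahedral cells must list 4 points")
  }
  elements <- cells[, 2:5, drop = FALSE] + 1L

  i <- ct$next_line
  cell_data <- list()
  point_data <- list()
  region <- NULL
  mode <- NULL
  count <- 0L
  while (i <= length(toks)) {
    tk <- toks[[i]]
    if (length(tk) == 0) { i <- i + 1L; next }
    if (tk[1] == "CELL_DATA") { mode <- "cell"; count <- ne; i <- i + 1L; next }
    if (tk[1] == "POINT_DATA") { mode <- "point"; count <- n; i <- i + 1L; next }
    if (tk[1] == "SCALARS") {
      nm <- tk[2]
      i <- i + 2L  # skip LOOKUP_TABLE line
      blk <- numbers_after(i, count)
      i <- blk$next_line
      if (identical(mode, "cell") && nm == "region") {
        region <- as.integer(blk$vals)
      } else if (identical(mode, "cell")) {
        cell_data[[nm]] <- blk$vals
      } else {
        point_data[[nm]] <- blk$vals
      }
      next
    }
    if (tk[1] == "VECTORS") {
      nm <- tk[2]
      blk <- numbers_after(i + 1L, 3L * count)
      i <- blk$next_line
      m <- matrix(blk$vals, ncol = 3, byrow = TRUE)
      if (identical(mode, "point")) point_data[[nm]] <- m
      else cell_data[[nm]] <- m
      next
    }
    i <- i + 1L
  }

  if (is.null(region)) {
    stop("VTK file carries no integer cell data 'region'")
  }
  lv <- region_labels()
  if (any(region < 1L | region > length(lv))) {
    stop("region codes outside 1..", length(lv),
         " cannot be mapped to tissue labels")
  }
  mesh <- structure(list(nodes = nodes, elements = elements,
                         region = lv[region], config = NULL),
                    class = "tet_mesh")
  list(mesh = mesh, cell_data = cell_data, point_data = point_data)
}
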