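#' Region labels used in the tooth-in-crypt model
#'
#' The eight tissue regions a mesh element may belong to. `follicle_pdl`
#' covers both the dental follicle of an unerupted tooth and the periodontal
#' ligament, which are assigned identical elastic properties. The two
#' condylar support materials are kept for completeness; the default
#' synthetic scene replaces condylar anatomy with fixed corner supports and
#' does not use them.
#'
#' @return Character vector of the eight valid region names.
#' @export
region_labels <- function() {
  c("cortical_bone", "cancellous_bone", "enamel", "dentine", "pulp",
    "follicle_pdl", "condylar_support_anterior", "condylar_support_posterior")
}

#' Default material table
#'
#' Literature-derived isotropic linear-elastic properties for each tissue:
#' Young's modulus `E` in MPa and Poisson's ratio `nu` (unitless). All
#' tissues are treated as homogeneous, isotropic and linearly elastic.
#' Values can be overridden per region via `overrides`.
#'
#' @param overrides Named list; each entry a list/vector with elements `E`
#'   and/or `nu`, named by region label.
#' @return A data frame with columns `region`, `E` (MPa), `nu`, one row per
#'   region, of class `material_table`.
#' @examples
#' mt <- material_table()
#' mt[mt$region == "enamel", ]
#' @export
material_table <- function(overrides = NULL) {
  tab <- data.frame(
    region = region_labels(),
    E = c(15000, 1500, 84100, 18600, 2, 12, 44.1, 0.49),
    nu = c(0.30, 0.30, 0.20, 0.31, 0.45, 0.45, 0.40, 0.49),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    for (nm in names(overrides)) {
      if (!nm %in% tab$region) {
        stop("unknown region in material overrides: ", nm)
      }
      ov <- overrides[[nm]]
      if (!is.null(ov$E)) tab$E[tab$region == nm] <- ov$E
      if (!is.null(ov$nu)) tab$nu[tab$region == nm] <- ov$nu
    }
  }
  validate_material_table(tab)
  class(tab) <- c("material_table", "data.frame")
  tab
}

validate_material_table <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("region", "E", "nu") %in% names(tab)))
  if (any(!is.finite(tab$E)) || any(tab$E <= 0)) {
    stop("material table invalid: Young's modulus E must be finite and > 0")
  }
  if (any(!is.finite(tab$nu)) || any(tab$nu <= -1) || any(tab$nu >= 0.5)) {
    stop("material table invalid: Poisson's ratio nu must lie in (-1, 0.5)")
  }
  invisible(tab)
}

# E, nu vectors aligned with a per-element region factor
material_for_elements <- function(regions, materials) {
  idx <- match(regions, materials$region)
  if (anyNA(idx)) {
    stop("elements carry region labels absent from the material table: ",
         paste(unique(regions[is.na(idx)]), collapse = ", "))
  }
  list(E = materials$E[idx], nu = materials$nu[idx])
}
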