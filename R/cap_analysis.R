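#' Long axis of a tooth from its element cloud
#'
#' The dominant principal axis of the tooth-element centroids, oriented
#' crown -> apex using the enamel-region centroid as the crown end. Errors
#' when the centroid cloud has no dominant axis (top two principal spreads
#' within 1% of each other), in which case an explicit axis must be
#' configured.
#'
#' @param mesh A `tet_mesh`.
#' @param tooth_elements Integer indices of the tooth's elements
#'   (enamel + dentine + pulp).
#' @return Unit 3-vector pointing crown -> apex.
#' @export
tooth_axis <- function(mesh, tooth_elements) {
  stopifnot(length(tooth_elements) >= 4)
  cen <- element_centroids(mesh)[tooth_elements, , drop = FALSE]
  pc <- stats::prcomp(cen, center = TRUE, scale. = FALSE)
  sd1 <- pc$sdev[1]; sd2 <- pc$sdev[2]
  if (!is.finite(sd1) || sd1 <= 0 || (sd1 - sd2) / sd1 < 0.01) {
    stop("ambiguous tooth axis: the top two principal spreads of the ",
         "element cloud are within 1% of each other; supply an explicit ",
         "axis in the configuration")
  }
  ax <- pc$rotation[, 1]
  ax <- ax / sqrt(sum(ax^2))
  enamel <- tooth_elements[mesh$region[tooth_elements] == "enamel"]
  if (length(enamel) == 0) {
    stop("cannot orient the tooth axis: no enamel elements to mark the crown end")
  }
  crown <- colMeans(element_centroids(mesh)[enamel, , drop = FALSE])
  mid <- colMeans(cen)
  # crown lies at the negative end of the crown->apex axis
  if (sum((crown - mid) * ax) > 0) ax <- -ax
  ax
}

#' Cap specification
#'
#' Identifies one of the two soft-tissue caps analysed per unerupted tooth:
#' the coronal cap over the crown or the apical cap beneath the root ends,
#' each extending a fixed depth (default 3 mm) along the tooth's long axis
#' towards the mid-portion of the tooth.
#'
#' @param tooth Tooth identifier (e.g. `"canine"`).
#' @param side `"left"` or `"right"`.
#' @param kind `"coronal"` or `"apical"`.
#' @param axis Unit 3-vector, crown -> apex.
#' @param depth Cap depth along the axis, mm (> 0); default 3.
#' @return A `cap_spec` list.
#' @export
cap_spec <- function(tooth, side = c("left", "right"),
                     kind = c("coronal", "apical"), axis, depth = 3) {
  side <- match.arg(side); kind <- match.arg(kind)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6) stop("cap axis must be a unit vector")
  if (!is.finite(depth) || depth <= 0) stop("cap depth must be > 0")
  structure(list(tooth = tooth, side = side, kind = kind,
                 axis = axis / nrm, depth = depth),
            class = "cap_spec")
}

#' Select the follicle elements belonging to a cap
#'
#' Projects follicle-element centroids onto the tooth axis. The coronal cap
#' comprises elements whose axial coordinate lies within `depth` mm of the
#' crown-most follicle centroid (measured towards the mid-tooth); the apical
#' cap is mirrored from the apex-most centroid. Errors when the follicle is
#' so short that the two caps would partially overlap mid-tooth
#' (double-counting); a depth at or beyond the whole follicle span
#' degenerates cleanly to the entire follicle.
#'
#' @param mesh A `tet_mesh`.
#' @param follicle_elements Integer indices of follicle elements (non-empty).
#' @param cap A [cap_spec()].
#' @return Integer vector of element indices in the cap.
#' @export
select_cap_elements <- function(mesh, follicle_elements, cap) {
  stopifnot(inherits(cap, "cap_spec"))
  if (length(follicle_elements) == 0) stop("follicle element set is empty")
  cen <- element_centroids(mesh)[follicle_elements, , drop = FALSE]
  t_ax <- as.numeric(cen %*% cap$axis)  # increases crown -> apex
  t_crown <- min(t_ax)
  t_apex <- max(t_ax)
  span <- t_apex - t_crown
  # caps overlapping mid-tooth would double-count follicle; a depth that
  # reaches past the whole follicle unambiguously selects all of it
  if (span < 2 * cap$depth && cap$depth < span) {
    stop("tooth too short for disjoint caps: follicle axial span ",
         format(span, digits = 4), " mm < 2 x depth = ",
         format(2 * cap$depth, digits = 4), " mm")
  }
  keep <- switch(cap$kind,
                 coronal = t_ax <= t_crown + cap$depth,
                 apical = t_ax >= t_apex - cap$depth)
  follicle_elements[keep]
}

#' Relative percentage of cap volume in compression
#'
#' `100 * sum(volume | sigma_h < 0) / sum(volume)`. Elements with exactly
#' zero hydrostatic stress count towards neither compression nor tension
#' but remain in the denominator. Compression dominates the cap when the
#' value exceeds 50%.
#'
#' @param records An `element_records` data frame (needs `volume`, `sigma_h`).
#' @return Percentage in [0, 100].
#' @export
compression_volume_percent <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("cannot compute a compression percentage from an empty record set")
  }
  tot <- sum(records$volume)
  if (!is.finite(tot) || tot <= 0) stop("total cap volume must be > 0")
  100 * sum(records$volume[records$sigma_h < 0]) / tot
}

#' Relative percentage of summated |BRU| in compression
#'
#' `100 * sum(|bru| | sigma_h < 0) / sum(|bru|)`: the compressive share of
#' the total absolute biological response.
#'
#' @param records An `element_records` data frame (needs `sigma_h`, `bru`).
#' @return Percentage in [0, 100].
#' @export
compression_bru_percent <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("cannot compute a BRU percentage from an empty record set")
  }
  tot <- sum(abs(records$bru))
  if (tot <= 0) {
    stop("total |BRU| is zero: no stress signal to apportion")
  }
  100 * sum(abs(records$bru)[records$sigma_h < 0]) / tot
}

#' Default hydrostatic-stress bin edges
#'
#' Rising increments of 0.005 MPa between 0.005 and 0.07 MPa; volumes
#' beyond either extreme are summated into underflow/overflow bins.
#'
#' @return Numeric vector of interior bin edges (MPa).
#' @export
stress_bin_edges <- function() seq(0.005, 0.07, by = 0.005)

#' Default |BRU| bin edges per tissue cap
#'
#' Coronal follicle: increments of 0.00017 N mm between 0.00029 and
#' 0.00250 N mm. Apical follicle: increments of 0.000045 N mm between
#' 0.000050 and 0.000630 N mm (the stated range is not an exact multiple of
#' the increment, so the last interior bin is closed off at the stated
#' maximum).
#'
#' @param tissue `"coronal"` or `"apical"`.
#' @return Numeric vector of interior bin edges (N mm).
#' @export
bru_bin_edges <- function(tissue = c("coronal", "apical")) {
  tissue <- match.arg(tissue)
  if (tissue == "coronal") {
    seq(0.00029, 0.00250, by = 0.00017)
  } else {
    e <- seq(0.000050, 0.000630, by = 0.000045)
    if (max(e) < 0.000630 - 1e-12) e <- c(e, 0.000630)
    e
  }
}

# shared binning core: values into [edge_i, edge_{i+1}) plus underflow
# (< first edge) and overflow (>= last edge); weights apportioned per bin
# and normalized to 100% of the curve's own mass
bin_curve <- function(values, weights, edges) {
  k <- length(edges)
  labels <- c("underflow",
              paste0("[", format(edges[-k], trim = TRUE), ",",
                     format(edges[-1], trim = TRUE), ")"),
              "overflow")
  idx <- findInterval(values, edges) + 1L  # 1 = underflow, k+1 = overflow
  out <- numeric(k + 1)
  if (length(values) > 0) {
    s <- rowsum(weights, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  tot <- sum(out)
  pct <- if (tot > 0) 100 * out / tot else out
  data.frame(bin = labels,
             lower = c(-Inf, edges[-k], edges[k]),
             upper = c(edges[1], edges[-1], Inf),
             mass = out, percent = pct)
}

#' Binned relative volume distribution over |hydrostatic stress|
#'
#' Splits the cap records into compressive (`sigma_h < 0`) and tensile
#' (`sigma_h > 0`) subsets and bins each on the absolute hydrostatic
#' stress, with volumes beyond the extreme edges summated into
#' underflow/overflow bins. Each curve's per-bin percentages are relative
#' to that curve's own total and sum to 100; each curve's share of the
#' total cap volume is reported alongside.
#'
#' @param records An `element_records` data frame.
#' @param edges Interior bin edges (MPa); default [stress_bin_edges()].
#' @return A `cap_histogram` list with `compression` and `tension` curve
#'   data frames (`bin`, `lower`, `upper`, `mass`, `percent`) and
#'   `share_of_total` (named length-2 vector, % of cap volume per curve).
#' @export
histogram_volume <- function(records, edges = stress_bin_edges()) {
  if (is.null(records) || nrow(records) == 0) {
    stop("cannot histogram an empty record set")
  }
  comp <- records$sigma_h < 0
  tens <- records$sigma_h > 0
  tot <- sum(records$volume)
  structure(list(
    basis = "volume", variable = "sigma_h", edges = edges,
    compression = bin_curve(abs(records$sigma_h[comp]),
                            records$volume[comp], edges),
    tension = bin_curve(records$sigma_h[tens], records$volume[tens], edges),
    share_of_total = c(compression = 100 * sum(records$volume[comp]) / tot,
                       tension = 100 * sum(records$volume[tens]) / tot)
  ), class = "cap_histogram")
}

#' Binned distributions over |BRU|
#'
#' Bins the compressive and tensile subsets on the absolute BRU value, with
#' the tissue-specific default edges, reporting per bin both the relative
#' percentage of volume occupied and the relative percentage of summated
#' |BRU|. Each curve is normalized to 100% of its own mass.
#'
#' @param records An `element_records` data frame.
#' @param tissue `"coronal"` or `"apical"` (selects the default edges).
#' @param edges Interior bin edges (N mm); default [bru_bin_edges()].
#' @return A `cap_histogram` list: `compression` and `tension` data frames
#'   with columns `bin`, `lower`, `upper`, `volume_percent`,
#'   `bru_percent`, plus `share_of_total` on the |BRU| basis.
#' @export
histogram_bru <- function(records, tissue = c("coronal", "apical"),
                          edges = NULL) {
  tissue <- match.arg(tissue)
  if (is.null(edges)) edges <- bru_bin_edges(tissue)
  if (is.null(records) || nrow(records) == 0) {
    stop("cannot histogram an empty record set")
  }
  one_curve <- function(sub) {
    v <- bin_curve(abs(sub$bru), sub$volume, edges)
    b <- bin_curve(abs(sub$bru), abs(sub$bru), edges)
    data.frame(bin = v$bin, lower = v$lower, upper = v$upper,
               volume_percent = v$percent, bru_percent = b$percent)
  }
  comp <- records[records$sigma_h < 0, , drop = FALSE]
  tens <- records[records$sigma_h > 0, , drop = FALSE]
  tot <- sum(abs(records$bru))
  structure(list(
    basis = "bru", variable = "abs_bru", tissue = tissue, edges = edges,
    compression = one_curve(comp),
    tension = one_curve(tens),
    share_of_total = c(compression = 100 * sum(abs(comp$bru)) / tot,
                       tension = 100 * sum(abs(tens$bru)) / tot)
  ), class = "cap_histogram")
}

#' Summarize one cap of one tooth under one load mode
#'
#' @param records `element_records` of the cap's elements.
#' @param cap A [cap_spec()].
#' @param load_mode `"incisive"` or `"unilateral_molar"`.
#' @return A `cap_summary` list: the spec, total volume, compression
#'   percentages on both bases, and the volume and BRU histograms.
#' @export
cap_summary <- function(records, cap, load_mode) {
  stopifnot(inherits(cap, "cap_spec"))
  structure(list(
    tooth = cap$tooth, side = cap$side, cap = cap$kind, load = load_mode,
    total_volume = sum(records$volume),
    volume_compression_percent = compression_volume_percent(records),
    bru_compression_percent = compression_bru_percent(records),
    histogram_stress = histogram_volume(records),
    histogram_bru = histogram_bru(records, tissue = cap$kind),
    records = records
  ), class = "cap_summary")
}

#' Pool cap summaries across teeth
#'
#' Pools element records cap-kind-wise across teeth and recomputes the
#' compression percentages over the concatenated records (pooling the bare
#' percentages would lose the volume weighting and is rejected). Second
#' molars are excluded by rule: they are not actively eruptive at the
#' developmental stage modelled.
#'
#' @param summaries List of `cap_summary` objects carrying their `records`.
#' @param exclude_teeth Teeth dropped from the pool (default second molars).
#' @return Data frame with one row per (cap kind, load mode):
#'   pooled volume- and BRU-basis compression percentages, pooled volume,
#'   and the teeth pooled; excluded teeth are listed in the
#'   `excluded` attribute.
#' @export
pool_caps <- function(summaries, exclude_teeth = "second_molar") {
  stopifnot(length(summaries) > 0)
  for (s in summaries) {
    if (!inherits(s, "cap_summary")) {
      stop("pooling requires full cap summaries with element records; ",
           "bare percentages cannot be pooled because the volume ",
           "weighting would be lost")
    }
    if (is.null(s$records)) {
      stop("cap summary for ", s$tooth, " (", s$side, ", ", s$cap,
           ") carries no element records; percentages alone cannot be pooled")
    }
  }
  keep <- summaries[!vapply(summaries, function(s) s$tooth %in% exclude_teeth,
                            logical(1))]
  dropped <- unique(vapply(summaries[vapply(summaries,
                                            function(s) s$tooth %in% exclude_teeth,
                                            logical(1))],
                           function(s) s$tooth, character(1)))
  if (length(dropped) > 0) {
    message("pool_caps: excluded from pooling: ",
            paste(dropped, collapse = ", "))
  }
  grp <- vapply(keep, function(s) paste(s$cap, s$load, sep = "|"), character(1))
  out <- do.call(rbind, lapply(split(keep, grp), function(grp_sums) {
    rec <- do.call(rbind, lapply(grp_sums, `[[`, "records"))
    data.frame(cap = grp_sums[[1]]$cap, load = grp_sums[[1]]$load,
               teeth = paste(sort(unique(vapply(grp_sums, `[[`, "",
                                                "tooth"))), collapse = ","),
               total_volume = sum(rec$volume),
               volume_compression_percent = compression_volume_percent(rec),
               bru_compression_percent = compression_bru_percent(rec))
  }))
  rownames(out) <- NULL
  attr(out, "excluded") <- dropped
  out
}

#' Classify exceptions to the coronal-compression / apical-tension pattern
#'
#' The expected pattern is compression-dominant coronal caps (compression
#' percentage > 50) and tension-dominant apical caps (compression
#' percentage < 50). A coronal entry is an exception iff its percentage is
#' below 50; an apical entry iff above 50; entries at exactly 50 are
#' exceptions for neither pattern. Second molars -- not actively eruptive at
#' this developmental stage -- are excluded from the canine/premolar counts
#' and reported separately. Exceptions within `margin` percentage points of
#' 50 are additionally flagged as near-misses (inclusive, `|x - 50| <=
#' margin`).
#'
#' @param table Data frame with columns `tooth`, `side`, `load`, `cap`,
#'   `basis`, `percent`. Teeth: `canine`, `first_premolar`,
#'   `second_premolar`, `second_molar`.
#' @param basis Restrict to one basis (`"volume"` or `"bru"`); default both.
#' @param margin Near-miss margin in percentage points (default 4).
#' @param eruptive_teeth Teeth included in the aggregate counts.
#' @return An `exception_report`: list with `table` (per-entry flags),
#'   `counts` (per basis: exceptions / instances among eruptive teeth,
#'   near-miss count), and `second_molars` (flags for the excluded teeth).
#' @export
classify_exceptions <- function(table, basis = c("volume", "bru"),
                                margin = 4,
                                eruptive_teeth = c("canine", "first_premolar",
                                                   "second_premolar")) {
  need <- c("tooth", "side", "load", "cap", "basis", "percent")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    stop("exception table is missing columns: ", paste(miss, collapse = ", "))
  }
  basis <- match.arg(basis, several.ok = TRUE)
  tab <- table[table$basis %in% basis, , drop = FALSE]

  # the full analysis grid must be present for every requested basis
  grid <- expand.grid(tooth = eruptive_teeth, side = unique(tab$side),
                      cap = c("coronal", "apical"),
                      load = unique(tab$load), basis = basis,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$tooth, d$side, d$cap, d$load, d$basis, sep = "|")
  missing_cells <- setdiff(key(grid), key(tab))
  if (length(missing_cells) > 0) {
    stop("exception table is missing cells: ",
         paste(utils::head(missing_cells, 10), collapse = "; "),
         if (length(missing_cells) > 10) " ...")
  }

  tab$expected <- ifelse(tab$cap == "coronal", "compression_dominant",
                         "tension_dominant")
  tab$is_exception <- ifelse(tab$cap == "coronal", tab$percent < 50,
                             tab$percent > 50)
  tab$near_miss <- tab$is_exception & abs(tab$percent - 50) <= margin

  eruptive <- tab[tab$tooth %in% eruptive_teeth, , drop = FALSE]
  counts <- do.call(rbind, lapply(split(eruptive, eruptive$basis), function(d) {
    data.frame(basis = d$basis[1], instances = nrow(d),
               exceptions = sum(d$is_exception),
               near_misses = sum(d$near_miss))
  }))
  rownames(counts) <- NULL

  structure(list(table = eruptive, counts = counts, margin = margin,
                 second_molars = tab[!tab$tooth %in% eruptive_teeth, ,
                                     drop = FALSE]),
            class = "exception_report")
}

#' @export
print.exception_report <- function(x, ...) {
  cat("Exception report (expected: coronal compression > 50%,",
      "apical compression < 50%)\n")
  print(x$counts, row.names = FALSE)
  nm <- x$table[x$table$near_miss, , drop = FALSE]
  if (nrow(nm) > 0) {
    cat("near-misses (within", x$margin, "points of 50%):\n")
    print(nm[, c("tooth", "side", "load", "cap", "basis", "percent")],
          row.names = FALSE)
  }
  invisible(x)
}
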