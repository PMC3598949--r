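make_records <- function(volume, sigma_h) {
  data.frame(element = seq_along(volume),
             region = rep("follicle_pdl", length(volume)),
             volume = volume, sigma_h = sigma_h,
             s_e = rep(NA_real_, length(volume)),
             bru = sigma_h * volume)
}

test_that("tooth axis recovers the constructed long axis, crown to apex", {
  mesh <- voxels_to_tets(build_labelled_grid(small_geometry()))
  tooth <- which(mesh$region %in% c("enamel", "dentine", "pulp"))
  ax <- tooth_axis(mesh, tooth)
  # constructed tooth: axis (0,0,-1), enamel (crown) at high z
  expect_gte(abs(sum(ax * c(0, 0, -1))), 0.999)
  expect_gt(-ax[3], 0)  # points crown -> apex, i.e. downward

  # equivariance under rotation of the whole mesh
  set.seed(8)
  R <- random_rotation()
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes %*% t(R)
  ax2 <- tooth_axis(mesh2, tooth)
  expect_gte(sum(ax2 * as.numeric(R %*% ax)), 0.999)
})

test_that("an isotropic tooth cloud demands an explicit axis", {
  # cubic dentine blob: all principal spreads equal
  lab <- array(match("cancellous_bone", region_labels()), dim = c(10, 10, 10))
  lab[3:8, 3:8, 3:8] <- match("dentine", region_labels())
  lab[3:8, 3:8, 8] <- match("enamel", region_labels())
  mesh <- voxels_to_tets(region_grid(lab, pitch = 1))
  tooth <- which(mesh$region %in% c("enamel", "dentine"))
  expect_error(tooth_axis(mesh, tooth), "ambiguous|explicit axis")
})

test_that("cap selection matches a brute-force axial filter", {
  mesh <- voxels_to_tets(build_labelled_grid(small_geometry()))
  follicle <- which(mesh$region == "follicle_pdl")
  ax <- c(0, 0, -1)
  for (kind in c("coronal", "apical")) {
    cap <- cap_spec("synthetic", "left", kind, axis = ax, depth = 3)
    got <- select_cap_elements(mesh, follicle, cap)
    # brute force: per-element centroid, axial coordinate filter
    t_ax <- vapply(follicle, function(e)
      sum(colMeans(mesh$nodes[mesh$elements[e, ], ]) * ax), 0)
    expected <- if (kind == "coronal") {
      follicle[t_ax <= min(t_ax) + 3]
    } else {
      follicle[t_ax >= max(t_ax) - 3]
    }
    expect_setequal(got, expected)
  }
  # disjoint caps at the default depth
  cor <- select_cap_elements(mesh, follicle,
                             cap_spec("s", "left", "coronal", ax, 3))
  api <- select_cap_elements(mesh, follicle,
                             cap_spec("s", "left", "apical", ax, 3))
  expect_length(intersect(cor, api), 0)
})

test_that("overlapping caps on a short tooth are rejected", {
  mesh <- voxels_to_tets(build_labelled_grid(small_geometry()))
  follicle <- which(mesh$region == "follicle_pdl")
  cap <- cap_spec("s", "left", "coronal", c(0, 0, -1), depth = 3.5)
  expect_error(select_cap_elements(mesh, follicle, cap), "too short")

  # limiting case: a depth beyond the whole span selects the entire follicle
  cap_all <- cap_spec("s", "left", "coronal", c(0, 0, -1), depth = 100)
  expect_setequal(select_cap_elements(mesh, follicle, cap_all), follicle)
})

test_that("compression volume percent weights by element volume", {
  expect_equal(compression_volume_percent(make_records(c(1, 1), c(-0.01, 0.01))), 50)
  expect_equal(compression_volume_percent(make_records(c(2, 5), c(-1, -2))), 100)
  expect_equal(compression_volume_percent(make_records(c(3, 1), c(-0.01, 0.02))), 75)
  # zero-stress elements stay in the denominator only
  expect_equal(compression_volume_percent(make_records(c(1, 1, 2), c(-1, 1, 0))), 25)
  expect_error(compression_volume_percent(make_records(numeric(), numeric())),
               "empty")
})

test_that("compression BRU percent apportions summated |BRU|", {
  expect_equal(compression_bru_percent(make_records(c(1, 1), c(-0.02, 0.01))),
               200 / 3, tolerance = 1e-12)
  expect_equal(compression_bru_percent(make_records(c(2, 1), c(-0.01, 0.02))), 50)
  expect_error(compression_bru_percent(make_records(c(1, 1), c(0, 0))),
               "zero")
  # oracle equivalence on 10,000 random records
  set.seed(7)
  rec <- make_records(rlnorm(10000, log(0.01), 0.5), rnorm(10000, 0, 0.02))
  num <- 0; den <- 0
  for (i in seq_len(nrow(rec))) {
    b <- abs(rec$sigma_h[i] * rec$volume[i])
    den <- den + b
    if (rec$sigma_h[i] < 0) num <- num + b
  }
  expect_equal(compression_bru_percent(rec), 100 * num / den,
               tolerance = 1e-9)
})

test_that("stress histograms conserve mass and match a brute-force binning", {
  # point mass: all records inside one bin
  rec <- make_records(rep(1, 5), rep(-0.012, 5))
  h <- histogram_volume(rec)
  expect_equal(sum(h$compression$percent), 100, tolerance = 1e-9)
  expect_equal(h$compression$percent[h$compression$lower == 0.010], 100)
  expect_true(all(h$compression$percent[h$compression$lower != 0.010] == 0))

  set.seed(9)
  rec <- make_records(rlnorm(2000, log(0.01), 0.5), rnorm(2000, 0, 0.03))
  h <- histogram_volume(rec)
  for (curve in c("compression", "tension")) {
    expect_equal(sum(h[[curve]]$percent), 100, tolerance = 1e-9)
  }
  # brute-force oracle for the compression curve
  edges <- stress_bin_edges()
  comp <- rec[rec$sigma_h < 0, ]
  v <- abs(comp$sigma_h)
  oracle <- numeric(length(edges) + 1)
  for (i in seq_along(v)) {
    b <- 1 + sum(v[i] >= edges)  # 1 = underflow
    oracle[b] <- oracle[b] + comp$volume[i]
  }
  oracle <- 100 * oracle / sum(oracle)
  expect_equal(h$compression$percent, oracle, tolerance = 1e-9)
  expect_equal(unname(h$share_of_total["compression"]),
               compression_volume_percent(rec), tolerance = 1e-9)
})

test_that("BRU histograms report volume and BRU weightings", {
  # uniform |bru|: the two weightings coincide
  rec <- make_records(rep(0.02, 50), rep(-0.03, 50))
  h <- histogram_bru(rec, tissue = "coronal")
  expect_equal(h$compression$volume_percent, h$compression$bru_percent,
               tolerance = 1e-9)
  expect_equal(sum(h$compression$volume_percent), 100, tolerance = 1e-9)

  # two-mass example: the BRU weighting shifts mass to the high-|bru| bin
  lo_bru <- 0.0004; hi_bru <- 0.002
  rec2 <- make_records(volume = rep(0.01, 10),
                       sigma_h = c(rep(-lo_bru / 0.01, 9), -hi_bru / 0.01))
  h2 <- histogram_bru(rec2, tissue = "coronal")
  hi_bin <- which(h2$compression$lower <= hi_bru &
                  h2$compression$upper > hi_bru)
  expect_gt(h2$compression$bru_percent[hi_bin],
            h2$compression$volume_percent[hi_bin])
  # cumulative BRU curve right-shifted vs volume curve
  expect_true(all(cumsum(h2$compression$bru_percent) <=
                  cumsum(h2$compression$volume_percent) + 1e-9))
})

test_that("default bin edges follow the stated increments", {
  expect_equal(stress_bin_edges(), seq(0.005, 0.07, by = 0.005))
  expect_equal(diff(bru_bin_edges("coronal")),
               rep(0.00017, 13), tolerance = 1e-12)
  expect_equal(range(bru_bin_edges("coronal")), c(0.00029, 0.00250))
  ea <- bru_bin_edges("apical")
  expect_equal(min(ea), 0.000050)
  expect_equal(max(ea), 0.000630)
  expect_true(all(diff(ea) > 0))
})

test_that("pooling recomputes over concatenated records, excluding second molars", {
  ax <- c(0, 0, -1)
  mk <- function(tooth, side, pct, total = 10) {
    # two-element record set with the requested compression percent by volume
    rec <- make_records(volume = c(total * pct / 100, total * (1 - pct / 100)),
                        sigma_h = c(-0.01, 0.01))
    cap_summary(rec, cap_spec(tooth, side, "coronal", ax, 3), "incisive")
  }
  s1 <- mk("canine", "left", 60)
  s2 <- mk("first_premolar", "left", 40)
  pooled <- suppressMessages(pool_caps(list(s1, s2)))
  expect_equal(pooled$volume_compression_percent, 50)

  # oracle: recomputation from the concatenated records
  s3 <- mk("second_premolar", "right", 85, total = 3)
  pooled2 <- suppressMessages(pool_caps(list(s1, s2, s3)))
  cat_rec <- rbind(s1$records, s2$records, s3$records)
  expect_equal(pooled2$volume_compression_percent,
               compression_volume_percent(cat_rec), tolerance = 1e-12)
  expect_equal(pooled2$bru_compression_percent,
               compression_bru_percent(cat_rec), tolerance = 1e-12)
  # pooled value lies between the constituent extremes
  expect_gte(pooled2$volume_compression_percent, 40)
  expect_lte(pooled2$volume_compression_percent, 85)

  # second molars are excluded and logged
  sm <- mk("second_molar", "left", 10)
  expect_message(p3 <- pool_caps(list(s1, s2, sm)), "second_molar")
  expect_equal(p3$volume_compression_percent, 50)
  expect_false(grepl("second_molar", p3$teeth))

  # pooling bare percentages is rejected
  expect_error(pool_caps(list(list(percent = 60))), "records|summaries")
})

test_that("exception classification applies the >50 / <50 rule", {
  # all-conforming synthetic table: no exceptions
  grid <- expand.grid(tooth = c("canine", "first_premolar", "second_premolar"),
                      side = c("left", "right"),
                      cap = c("coronal", "apical"),
                      load = c("incisive", "unilateral_molar"),
                      basis = "volume", stringsAsFactors = FALSE)
  grid$percent <- ifelse(grid$cap == "coronal", 80, 20)
  rep0 <- classify_exceptions(grid, basis = "volume")
  expect_equal(rep0$counts$exceptions, 0)
  expect_equal(rep0$counts$instances, 24)

  # flip three cells into exceptions, one a near-miss
  tab <- grid
  tab$percent[1] <- 40            # coronal below 50
  tab$percent[2] <- 48            # coronal near-miss (within 4)
  i_ap <- which(tab$cap == "apical")[1]
  tab$percent[i_ap] <- 72         # apical above 50
  rep1 <- classify_exceptions(tab, basis = "volume")
  expect_equal(rep1$counts$exceptions, 3)
  expect_equal(rep1$counts$near_misses, 1)

  # a cell at exactly 50 is an exception for neither pattern
  tab50 <- grid
  tab50$percent[1] <- 50
  tab50$percent[i_ap] <- 50
  rep50 <- classify_exceptions(tab50, basis = "volume")
  expect_equal(rep50$counts$exceptions, 0)

  # missing cells are reported by name
  expect_error(classify_exceptions(grid[-1, ], basis = "volume"),
               "missing cells")
  expect_error(classify_exceptions(grid[, -1]), "missing columns")
})
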