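test_that("muscle force is the area x constant x activation product", {
  expect_equal(muscle_force(5, 40, 0.5), 100)
  expect_equal(muscle_force(5, 40, 0), 0)
  expect_equal(muscle_force(7.3, 37, 1), 7.3 * 37)
  expect_error(muscle_force(5, 40, 1.2), "EMG")
  expect_error(muscle_force(5, 40, -0.1), "EMG")
  expect_error(muscle_force(0, 40, 0.5), "X_MI")
  expect_error(muscle_force(5, 0, 0.5), "K")
})

test_that("muscle specs validate direction, activation and attachment", {
  expect_error(muscle_spec("m", 5, 40, 0.5, c(0, 0, 0), 1L), "nonzero")
  expect_error(muscle_spec("m", 5, 40, 1.5, c(0, 0, 1), 1L), "EMG")
  expect_error(muscle_spec("m", 5, 40, 0.5, c(0, 0, 1), integer()), "empty")
  m <- muscle_spec("m", 5, 40, 0.5, c(0, 0, -2), 1:4)
  expect_equal(sqrt(sum(m$direction^2)), 1, tolerance = 1e-12)
})

test_that("muscle force splits equally over attachment nodes", {
  mesh <- box_mesh(c(2, 2, 2), pitch = 1)
  top <- nodes_where(mesh, function(x, y, z) z > 2 - 1e-9)
  att <- top[1:4]
  mus <- list(muscle_spec("pull", 5, 40, 0.5, c(0, 0, -1), att))  # 100 N
  lc <- make_load_case(mesh, mus, mode = "incisive",
                       support_nodes = nodes_where(mesh, function(x, y, z) z < 1e-9),
                       incisal_nodes = top)
  expect_equal(lc$forces[att, 3], rep(-25, 4))
  expect_equal(sqrt(sum(colSums(lc$forces)^2)), 100, tolerance = 1e-12)
})

test_that("mirrored left/right muscles cancel laterally", {
  mesh <- box_mesh(c(2, 2, 2), pitch = 1)
  top <- nodes_where(mesh, function(x, y, z) z > 2 - 1e-9)
  left <- muscle_spec("l", 4, 40, 0.8, c(0, +0.3, -1), top[1:3])
  right <- muscle_spec("r", 4, 40, 0.8, c(0, -0.3, -1), top[4:6])
  lc <- make_load_case(mesh, list(left, right), mode = "incisive",
                       support_nodes = 1:4, incisal_nodes = top)
  total <- colSums(lc$forces)
  expect_equal(total[2], 0, tolerance = 1e-9)
  expect_lt(total[3], 0)
})

test_that("incisive mode fixes exactly the incisal vertical DOFs plus supports", {
  mesh <- box_mesh(c(2, 2, 2), pitch = 1)
  support <- c(1L, 3L)
  incisal <- c(20L, 21L)
  occl <- 25L
  mus <- list(muscle_spec("m", 1, 10, 1, c(0, 0, -1), 10L))
  lc <- make_load_case(mesh, mus, mode = "incisive",
                       support_nodes = support, incisal_nodes = incisal,
                       occlusal_nodes = occl)
  expected <- rbind(expand.grid(node = support, axis = 1:3),
                    data.frame(node = incisal, axis = 3))
  got <- lc$fixed[, c("node", "axis")]
  key <- function(d) sort(paste(d$node, d$axis))
  expect_identical(key(got), key(expected))

  # molar mode swaps the bite fixity set
  lcm <- make_load_case(mesh, mus, mode = "unilateral_molar",
                        support_nodes = support, incisal_nodes = incisal,
                        occlusal_nodes = occl)
  expect_true(all(paste(occl, 3) %in% paste(lcm$fixed$node, lcm$fixed$axis)))
  expect_false(any(paste(incisal, 3) %in%
                   paste(lcm$fixed$node, lcm$fixed$axis)))
})

test_that("empty fixity or attachment sets are rejected", {
  mesh <- box_mesh(c(2, 2, 2), pitch = 1)
  mus <- list(muscle_spec("m", 1, 10, 1, c(0, 0, -1), 1L))
  expect_error(make_load_case(mesh, mus, mode = "incisive",
                              support_nodes = integer(), incisal_nodes = 1L),
               "support")
  expect_error(make_load_case(mesh, mus, mode = "incisive",
                              support_nodes = 1L, incisal_nodes = integer()),
               "bite fixity")
})

test_that("applied nodal force totals match the muscle force formula exactly", {
  mesh <- box_mesh(c(3, 3, 3), pitch = 1)
  top <- nodes_where(mesh, function(x, y, z) z > 3 - 1e-9)
  set.seed(42)
  for (k in 1:5) {
    X <- runif(1, 1, 10); K <- runif(1, 20, 60); emg <- runif(1)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    att <- sample(top, sample(2:8, 1))
    lc <- make_load_case(mesh, list(muscle_spec("m", X, K, emg, dir, att)),
                         mode = "incisive", support_nodes = 1:4,
                         incisal_nodes = top[1])
    expect_equal(colSums(lc$forces), muscle_force(X, K, emg) * dir,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})
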