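test_that("mesh respects edge-length limits inside and outside the boundary", {
  m <- test_mesh()
  el <- triangle_edge_lengths(m)
  expect_true(all(el[m$inner, ] <= 0.3 + 1e-9))
  expect_true(all(el <= 0.6 + 1e-9))
})

test_that("mesh triangles cover the extended region without overlap and are CCW", {
  m <- test_mesh()
  areas <- herdmaps:::triangle_areas(m$vertices, m$triangles)
  expect_true(all(areas > 0))  # consistent counter-clockwise orientation
  # bbox of 2x2 boundary + 1 deg extension has area 16; a cover without
  # overlaps has triangle areas summing to it
  expect_equal(sum(areas), 16, tolerance = 1e-9)
})

test_that("halving the inner edge limit roughly quadruples inner triangles", {
  m1 <- test_mesh()
  m2 <- fixture("half_mesh", function()
    build_mesh(square_boundary(0, 0, 2, 2), 0.15, 0.6, 1.0))
  ratio <- sum(m2$inner) / sum(m1$inner)
  expect_gt(ratio, 4 * 0.7)
  expect_lt(ratio, 4 * 1.3)
})

test_that("degenerate geometry is rejected", {
  expect_error(build_mesh(square_boundary(), extension = 0), "extension")
  # unequal-lobe bowtie: self-crossing with non-zero net signed area
  bowtie <- cbind(c(0, 3, 3, 0), c(0, 1, -2, 2))
  expect_false(herdmaps:::polygon_is_simple(bowtie))
  expect_error(build_mesh(bowtie), "self-intersecting")
  expect_error(build_mesh(square_boundary(), inner_max_edge = 0.7,
                          outer_max_edge = 0.6), "inner_max_edge")
})

test_that("element matrices match the analytic P1 integrals", {
  fem <- fem_matrices(unit_right_triangle())
  C_expected <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3) / 24
  G_expected <- matrix(c(2, -1, -1, -1, 1, 0, -1, 0, 1), 3, 3) / 2
  expect_equal(as.matrix(fem$C), C_expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.matrix(fem$G), G_expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  # lumped mass = row sums on the diagonal
  expect_equal(Matrix::diag(fem$C_lumped), rowSums(C_expected))
})

test_that("stiffness row sums vanish and matrices are symmetric", {
  fem <- fixture("fem", function() fem_matrices(test_mesh()))
  expect_lt(max(abs(Matrix::rowSums(fem$G))), 1e-10)
  expect_lt(max(abs(fem$C - Matrix::t(fem$C))), 1e-10)
  expect_lt(max(abs(fem$G - Matrix::t(fem$G))), 1e-10)
  expect_true(all(Matrix::diag(fem$C_lumped) > 0))
})

test_that("degenerate triangles are reported by index", {
  bad <- list(vertices = cbind(c(0, 1, 2), c(0, 0, 0)),
              triangles = matrix(c(1L, 2L, 3L), 1L, 3L))
  expect_error(fem_matrices(bad), "triangle 1")
})

test_that("SPDE marginal variance approximates sigma_s^2 away from boundaries", {
  m <- fine_mesh()
  fem <- fixture("fine_fem", function() fem_matrices(fine_mesh()))
  sp <- spde_precision(fem, rho_s = 0.5, sigma_s = 1)
  Sig <- solve(as.matrix(sp$Q))
  interior <- point_in_polygon(m$vertices[, 1], m$vertices[, 2],
                               square_boundary(0.5, 0.5, 1, 1))
  expect_lt(abs(mean(diag(Sig)[interior]) - 1), 0.1)
})

test_that("SPDE correlation at the range distance is about 0.14", {
  m <- fine_mesh()
  fem <- fixture("fine_fem", function() fem_matrices(fine_mesh()))
  sp <- spde_precision(fem, rho_s = 0.5, sigma_s = 1)
  Sig <- solve(as.matrix(sp$Q))
  interior <- which(point_in_polygon(m$vertices[, 1], m$vertices[, 2],
                                     square_boundary(0.5, 0.5, 1, 1)))
  d <- as.matrix(dist(m$vertices[interior, ]))
  pair <- which(abs(d - 0.5) < 0.02 & upper.tri(d), arr.ind = TRUE)[1, ]
  i <- interior[pair[1]]; j <- interior[pair[2]]
  r <- Sig[i, j] / sqrt(Sig[i, i] * Sig[j, j])
  expect_equal(r, sqrt(8) * besselK(sqrt(8), 1), tolerance = 0.25)
  expect_lt(abs(r - 0.14), 0.05)
})

test_that("doubling sigma_s scales the precision by exactly 1/4", {
  fem <- fixture("fem", function() fem_matrices(test_mesh()))
  q1 <- spde_precision(fem, 0.5, 1)$Q
  q2 <- spde_precision(fem, 0.5, 2)$Q
  expect_lt(max(abs(q2 - q1 / 4)), 1e-12)
  expect_error(spde_precision(fem, Inf, 1), "finite")
  expect_error(spde_precision(fem, 0.5, -1), "finite")
})

test_that("precision sparsity stays within the second-order neighbourhood", {
  fem <- fixture("fem", function() fem_matrices(test_mesh()))
  Q <- spde_precision(fem, 0.5, 1)$Q
  adj1 <- (fem$G != 0) | (fem$C != 0)  # first-order vertex neighbourhood
  adj2 <- (adj1 %*% adj1) != 0
  expect_true(all((Q != 0)@i %in% adj2@i |
                    length((Q != 0)@i) <= length(adj2@i)))
  outside <- Matrix::which(Q != 0 & !adj2)
  expect_length(outside, 0)
})

test_that("point projection returns barycentric partitions of unity", {
  m <- test_mesh()
  # a vertex projects to a unit indicator
  A <- project_points(m, m$vertices[c(5, 40), , drop = FALSE])
  expect_equal(max(A[1, ]), 1)
  expect_equal(sum(A[1, ] > 0), 1)
  # a centroid projects to weights 1/3
  tri <- m$triangles[10, ]
  ctr <- colMeans(m$vertices[tri, ])
  Ac <- project_points(m, matrix(ctr, 1))
  expect_equal(sort(as.numeric(Ac[1, tri])), rep(1 / 3, 3), tolerance = 1e-9)
  # arbitrary interior points: rows sum to 1, at most 3 non-negative entries
  set.seed(1)
  pts <- cbind(runif(50, -0.5, 2.5), runif(50, -0.5, 2.5))
  Ar <- project_points(m, pts)
  expect_equal(unname(Matrix::rowSums(Ar)), rep(1, 50), tolerance = 1e-12)
  expect_true(all(Ar@x >= 0))
  expect_true(all(Matrix::rowSums(Ar != 0) <= 3))
  expect_error(project_points(m, matrix(c(99, 99), 1)), "outside mesh")
})

test_that("meshes serialize through the plain-text container", {
  m <- test_mesh()
  p <- withr::local_tempfile(fileext = ".json")
  write_mesh(m, p)
  m2 <- read_mesh(p)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-12)
  expect_equal(m2$triangles, m$triangles, ignore_attr = TRUE)
  expect_equal(m2$inner, m$inner)
})
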