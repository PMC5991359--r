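# Surface evaluation, closest-point projection, serialization.

test_that("patch corners interpolate the corner nodes exactly", {
  m <- base_mesh()
  topo <- m$topology
  for (p in c(1L, 13L, 40L)) {
    corners <- evaluate_surface(m, p, c(0, 1, 0, 1), c(0, 0, 1, 1))
    ids <- topo$patches[p, c(1, 4, 13, 16)]
    expect_equal(corners, m$nodes[ids, ], tolerance = 1e-12)
  }
})

test_that("interpolation has linear precision (planar data stays planar)", {
  m <- base_mesh()
  nodes <- m$nodes
  nodes[, 3] <- 0.3 * nodes[, 1] - 0.2 * nodes[, 2] + 5
  flat <- new_mc3_mesh(nodes, m$topology, m$manifest)
  uv <- expand.grid(u = seq(0, 1, 0.2), v = seq(0, 1, 0.2))
  pts <- evaluate_surface(flat, 17L, uv$u, uv$v)
  expect_equal(pts[, 3], 0.3 * pts[, 1] - 0.2 * pts[, 2] + 5,
               tolerance = 1e-10)
})

test_that("evaluation matches an independent Lagrange basis product sum", {
  m <- base_mesh()
  lag <- function(u) {
    xs <- c(0, 1 / 3, 2 / 3, 1)
    vapply(1:4, function(i)
      prod((u - xs[-i]) / (xs[i] - xs[-i])), 0)
  }
  p <- 22L; u <- 0.5; v <- 0.5
  ids <- m$topology$patches[p, ]
  w <- as.vector(outer(lag(u), lag(v)))  # u fast within v-major id ordering
  expected <- colSums(m$nodes[ids, ] * w)
  expect_equal(as.vector(evaluate_surface(m, p, u, v)), expected,
               tolerance = 1e-12)
})

test_that("evaluate_surface rejects invalid patches and parameters", {
  m <- base_mesh()
  expect_error(evaluate_surface(m, 99L, 0.5, 0.5), "invalid patch")
  expect_error(evaluate_surface(m, 1L, 1.5, 0.5), "0,1")
})

test_that("closest_point is exact on and near the surface", {
  m <- base_mesh()
  set.seed(11)
  p <- sample.int(40, 400, replace = TRUE)
  q <- evaluate_surface(m, p, runif(400), runif(400))
  cp <- closest_point(m, q)
  expect_lt(max(cp$distance), 1e-9)
  nn <- node_normals(m)
  q2 <- m$nodes[50:80, ] + 2.5 * nn[50:80, ]
  cp2 <- closest_point(m, q2)
  expect_lt(max(abs(cp2$distance - 2.5)), 0.05)
})

test_that("closest_point agrees with a dense-grid brute-force oracle", {
  m <- base_mesh()
  set.seed(12)
  q <- surface_cloud(m, 60, seed = 12) + matrix(rnorm(180, 0, 4), 60, 3)
  cp <- closest_point(m, q, iters = 14L)
  eg <- expand.grid(th = seq(0, 2 * pi, length.out = 900),
                    t = seq(0, 1, length.out = 260))
  pts <- evaluate_surface(m, mc3ssm:::chart_to_patch(eg$th, eg$t)$patch,
                          mc3ssm:::chart_to_patch(eg$th, eg$t)$u,
                          mc3ssm:::chart_to_patch(eg$th, eg$t)$v)
  for (i in seq_len(nrow(q))) {
    oracle <- sqrt(min(rowSums(sweep(pts, 2, q[i, ])^2)))
    # the refined result may only beat the discrete oracle
    expect_lt(cp$distance[i] - oracle, 1e-3)
  }
})

test_that("node normals are unit length and point outward", {
  m <- base_mesh()
  nn <- node_normals(m)
  expect_equal(rowSums(nn^2), rep(1, nrow(nn)), tolerance = 1e-9)
  cen <- colMeans(m$nodes)
  d0 <- rowSums(sweep(m$nodes, 2, cen)^2)
  d1 <- rowSums(sweep(m$nodes + 0.3 * nn, 2, cen)^2)
  expect_true(all(d1 > d0))
})

test_that("meshes and point clouds round-trip through their file formats", {
  m <- base_mesh()
  tf <- tempfile(fileext = ".json")
  write_mesh_json(new_mc3_mesh(m$nodes, m$topology, m$manifest,
                               densities = runif(361)), tf)
  back <- read_mesh_json(tf)
  expect_equal(back$nodes, m$nodes, ignore_attr = TRUE)
  expect_length(back$densities, 361)

  pts <- m$nodes[1:50, ]
  for (bin in c(TRUE, FALSE)) {
    tp <- tempfile(fileext = ".ply")
    write_ply(pts, tp, scalar = seq_len(50), binary = bin)
    rb <- read_ply(tp)
    expect_equal(rb$points, pts, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(rb$scalar, seq_len(50), tolerance = 1e-6)
  }
  tc <- tempfile(fileext = ".csv")
  write_cloud_csv(pts, tc)
  expect_equal(read_cloud_csv(tc), pts, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("patch areas are additive over regions", {
  m <- base_mesh()
  total <- patch_area(m)
  parts <- sum(vapply(1:40, function(p) patch_area(m, p), 0))
  expect_equal(total, parts, tolerance = 1e-9)
})
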