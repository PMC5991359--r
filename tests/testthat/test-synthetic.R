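# Synthetic population generator: determinism, variance bookkeeping,
# exported artifacts.

test_that("the generator is deterministic under a fixed seed", {
  a <- sample_population(default_synthetic_spec(3, seed = 99))
  b <- sample_population(default_synthetic_spec(3, seed = 99))
  expect_identical(a$specimens[[2]]$node_coords, b$specimens[[2]]$node_coords)
  expect_identical(a$specimens[[3]]$node_density, b$specimens[[3]]$node_density)
  c <- sample_population(default_synthetic_spec(3, seed = 100))
  expect_false(identical(a$specimens[[1]]$node_coords,
                         c$specimens[[1]]$node_coords))
})

test_that("zero variance and zero noise reproduce the base up to pose", {
  spec <- default_synthetic_spec(2, seed = 5)
  spec$shape_rms_mm <- 0; spec$node_noise_sd <- 0
  spec$density_rms <- 0; spec$density_noise_sd <- 0
  pop <- sample_population(spec)
  expect_equal(pop$specimens[[1]]$node_coords_local, pop$base$nodes,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pop$specimens[[1]]$node_density, rep(spec$density_base, 361))
  # posed coordinates are a rigid motion of the base
  k <- kabsch(pop$base$nodes, pop$specimens[[1]]$node_coords)
  expect_lt(k$rms, 1e-9)
})

test_that("generative variance partitions across modes as specified", {
  spec <- default_synthetic_spec(300, seed = 31)
  pop <- sample_population(spec)
  X <- population_coord_matrix(pop)
  m <- ssm_train(X, "shape")
  expect_lt(max(abs(m$variance_fractions[1:3] - c(0.50, 0.30, 0.15))), 0.05)
})

test_that("mode scores behave as standard normal draws", {
  pop <- sample_population(default_synthetic_spec(300, seed = 32))
  sc <- do.call(rbind, lapply(pop$specimens, `[[`, "mode_scores"))
  expect_lt(max(abs(colMeans(sc))), 0.2)
  expect_lt(max(abs(apply(sc, 2, sd) - 1)), 0.15)
})

test_that("densities are clamped non-negative", {
  spec <- default_synthetic_spec(5, seed = 33)
  spec$density_base <- 0.02   # force frequent clamping
  pop <- sample_population(spec)
  for (s in pop$specimens) expect_true(all(s$node_density >= 0))
})

test_that("noiseless exported points lie on the specimen surface", {
  spec <- default_synthetic_spec(2, seed = 34)
  spec$node_noise_sd <- 0   # a smooth specimen; node jitter would wrinkle
                            # the degenerate pole and stall the projector
  pop <- sample_population(spec)
  s <- pop$specimens[[1]]
  cl <- export_point_cloud(s, density = 0.1, point_noise_sd = 0, seed = 34)
  d <- closest_point(mesh_from_specimen(s), cl)$distance
  expect_lt(max(d), 1e-7)
})

test_that("noisy cloud distances follow the half-normal of the jitter", {
  pop <- small_population()
  s <- pop$specimens[[2]]
  sdj <- 0.15
  cl <- export_point_cloud(s, density = 0.3, point_noise_sd = sdj, seed = 35)
  d <- closest_point(mesh_from_specimen(s), cl)$distance
  # distance to a locally flat surface = |normal component| of the isotropic
  # jitter: RMS = sd, mean = sd * sqrt(2/pi); curvature shrinks both a little
  expect_gt(sqrt(mean(d^2)) / sdj, 0.90)
  expect_lt(sqrt(mean(d^2)) / sdj, 1.05)
  expect_gt(mean(d) / (sdj * sqrt(2 / pi)), 0.88)
  expect_lt(mean(d) / (sdj * sqrt(2 / pi)), 1.08)
})

test_that("doubling the sampling density doubles the point count", {
  pop <- small_population()
  s <- pop$specimens[[3]]
  n1 <- nrow(export_point_cloud(s, density = 0.15, seed = 36))
  n2 <- nrow(export_point_cloud(s, density = 0.30, seed = 37))
  expect_gt(n2 / n1, 1.8)
  expect_lt(n2 / n1, 2.2)
})

test_that("ground-truth sidecars round-trip through JSON", {
  pop <- small_population()
  s <- pop$specimens[[4]]
  tf <- tempfile(fileext = ".json")
  write_specimen_json(s, tf)
  back <- read_specimen_json(tf)
  expect_equal(back$node_coords, s$node_coords, ignore_attr = TRUE)
  expect_equal(back$mode_scores, s$mode_scores)
  expect_equal(back$rigid_pose$R, s$rigid_pose$R, ignore_attr = TRUE)
})

test_that("invalid specifications are rejected", {
  spec <- default_synthetic_spec(2)
  spec$n_specimens <- 1L
  expect_error(sample_population(spec), ">= 2")
  spec <- default_synthetic_spec(2)
  spec$variance_fractions <- c(0.8, 0.4)
  expect_error(sample_population(spec), "sum")
  spec <- default_synthetic_spec(2)
  spec$voxel_spacing <- c(0.3, -1, 0.6)
  expect_error(sample_population(spec), "spacing")
})

test_that("export_point_cloud rejects non-positive density", {
  pop <- small_population()
  expect_error(export_point_cloud(pop$specimens[[1]], density = 0), "positive")
})
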