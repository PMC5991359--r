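# Generalized Procrustes alignment and the correspondence loop.

test_that("identical meshes in different poses align to coincidence", {
  m <- base_mesh()
  R <- euler_rotation(0.3, -0.2, 0.5)
  posed <- apply_rigid(m$nodes, R, c(12, -7, 4))
  al <- rigid_align(list(m$nodes, posed))
  expect_lt(max(abs(al$coords[[1]] - al$coords[[2]])), 1e-6)
})

test_that("N=2 alignment residual equals closed-form orthogonal Procrustes", {
  pop <- small_population()
  A <- pop$specimens[[1]]$node_coords
  B <- pop$specimens[[2]]$node_coords
  al <- rigid_align(list(A, B))
  gpa_dist <- sqrt(mean(rowSums((al$coords[[1]] - al$coords[[2]])^2)))
  expect_equal(gpa_dist, kabsch(A, B)$rms, tolerance = 1e-9)
})

test_that("a common extra rigid motion leaves pairwise distances unchanged", {
  pop <- small_population()
  Xs <- lapply(pop$specimens[1:4], `[[`, "node_coords")
  al1 <- rigid_align(Xs)
  R <- euler_rotation(-0.4, 0.1, 0.7)
  al2 <- rigid_align(lapply(Xs, function(x) apply_rigid(x, R, c(3, 9, -2))))
  pd <- function(al) sapply(2:4, function(i)
    sqrt(mean(rowSums((al$coords[[1]] - al$coords[[i]])^2))))
  expect_equal(pd(al1), pd(al2), tolerance = 1e-8)
})

test_that("re-aligning an aligned set is the identity", {
  pop <- small_population()
  al1 <- rigid_align(lapply(pop$specimens[1:4], `[[`, "node_coords"))
  al2 <- rigid_align(al1$coords)
  for (i in 1:4)
    expect_lt(max(abs(al1$coords[[i]] - al2$coords[[i]])), 1e-5)
})

test_that("alignment rejects mismatched topologies", {
  m <- base_mesh()
  expect_error(rigid_align(list(m$nodes, m$nodes[1:100, ])), "topology")
  expect_error(rigid_align(list(m$nodes)), "two meshes")
})

test_that("alignment never uses scaling (size survives)", {
  m <- base_mesh()
  big <- 1.3 * m$nodes
  al <- rigid_align(list(m$nodes, big))
  s1 <- sqrt(sum(sweep(al$coords[[1]], 2, colMeans(al$coords[[1]]))^2))
  s2 <- sqrt(sum(sweep(al$coords[[2]], 2, colMeans(al$coords[[2]]))^2))
  expect_equal(s2 / s1, 1.3, tolerance = 1e-9)
})

test_that("clouds already in correspondence terminate the loop in one round", {
  pop <- small_population()
  template <- pop$base
  sub <- pop$specimens[1:4]
  clouds <- lapply(seq_along(sub), function(i)
    export_point_cloud(sub[[i]], density = 0.2, point_noise_sd = 0,
                       seed = 600 + i))
  fits <- lapply(seq_along(sub), function(i)
    fine_fit(mesh_from_specimen(sub[[i]]), clouds[[i]]))
  # the truth meshes carry 0.22 mm node jitter, which wrinkles the
  # degenerate pole; the projector's accuracy floor there is ~0.01 mm
  expect_lt(max(vapply(fits, `[[`, 0, "rms")), 0.02)
  ts <- correspondence_loop(template, clouds, fits, rms_target = 0.05)
  expect_equal(ts$rounds, 1L)
  expect_true(ts$converged)
  expect_lt(ts$mean_rms, 0.05)
})

test_that("the loop keeps mean RMS non-increasing and recovers correspondence", {
  pop <- small_population()
  template <- pop$base
  clouds <- lapply(seq_along(pop$specimens), function(i)
    export_point_cloud(pop$specimens[[i]], density = 0.25, seed = 700 + i))
  fits <- fit_population(template, clouds)
  ts <- correspondence_loop(template, clouds, fits)
  expect_lt(ts$mean_rms, 0.3)
  mean_per_round <- rowMeans(ts$rms_history)
  expect_true(all(diff(mean_per_round) <= 1e-3))
  # specimen-frame ground-truth correspondence: limited by the rigid-pose
  # bias of surface-only registration (tangential position is unobservable);
  # the empirically supported bound is a few node spacings
  nerr <- vapply(seq_along(ts$fits), function(i)
    mean(sqrt(rowSums((ts$fits[[i]]$mesh$nodes -
                       pop$specimens[[i]]$node_coords)^2))), 0)
  expect_lt(mean(nerr), 3)
  # aligned-frame consequence: the fitted training set carries the
  # generator's variance structure
  m <- ssm_train(ts$aligned$matrix, "shape")
  expect_gt(m$variance_fractions[1], 0.25)
  expect_lt(m$n_retained, length(ts$fits))
})
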