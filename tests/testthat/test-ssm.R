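# Principal-component models: training, projection, reconstruction,
# leave-one-out, invariances.

test_that("two distinct specimens give exactly one mode with fraction 1", {
  pop <- small_population()
  X <- population_coord_matrix(pop)[1:2, ]
  m <- ssm_train(X, "shape")
  expect_length(m$sdev, 1L)
  expect_equal(m$variance_fractions, 1)
  expect_equal(m$n_retained, 1L)
})

test_that("variance fractions match an independent covariance eigendecomposition", {
  set.seed(51)
  X <- matrix(rnorm(300), 10, 30)
  m <- ssm_train(X, "shape")
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12 * ev[1]]
  expect_equal(m$variance_fractions, ev / sum(ev), tolerance = 1e-8)
  # components are orthonormal
  G <- crossprod(m$components)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_equal(sum(m$variance_fractions), 1, tolerance = 1e-9)
})

test_that("reconstruction and projection are mutually inverse", {
  pop <- small_population()
  X <- population_coord_matrix(pop)
  m <- ssm_train(X, "shape", variance_target = 1)
  expect_equal(ssm_reconstruct(m), m$mean)
  # full-rank round trip of a training member
  pr <- ssm_project(m, X[3, ], k = length(m$sdev))
  xr <- ssm_reconstruct(m, pr$weights, limit = FALSE)
  expect_equal(xr, X[3, ], tolerance = 1e-8, ignore_attr = TRUE)
  # projecting the mean gives zero weights
  expect_lt(max(abs(ssm_project(m, m$mean)$weights)), 1e-8)
  # projecting mean + 1.5 * mode2 recovers (0, 1.5, 0, ...)
  x2 <- m$mean + m$scales * (1.5 * m$sdev[2] * m$components[, 2])
  w <- ssm_project(m, x2, k = 4)$weights
  expect_equal(w, c(0, 1.5, 0, 0), tolerance = 1e-8)
})

test_that("projection residual equals the brute-force least-squares residual", {
  set.seed(52)
  X <- matrix(rnorm(192), 8, 24)
  m <- ssm_train(X, "shape", variance_target = 1)
  y <- rnorm(24)
  k <- 3
  pr <- ssm_project(m, y, k = k)
  # normal-equations oracle in the standardized, centered space
  Z <- (y - m$mean) / m$scales
  V <- m$components[, 1:k]
  beta <- solve(crossprod(V), crossprod(V, Z))
  expect_equal(pr$weights, as.vector(beta) / m$sdev[1:k], tolerance = 1e-8)
  expect_equal(pr$residual_norm, sqrt(sum((Z - V %*% beta)^2)),
               tolerance = 1e-8)
})

test_that("the generator's modes are recovered from a large population", {
  spec <- default_synthetic_spec(200, seed = 53)
  pop <- sample_population(spec)
  X <- population_coord_matrix(pop)
  m <- ssm_train(X, "shape")
  expect_lt(max(abs(m$variance_fractions[1:3] - c(0.50, 0.30, 0.15))), 0.05)
  G <- sapply(pop$modes, function(md) flatten_coords(md$shape_field))
  sv <- svd(crossprod(qr.Q(qr(G)), qr.Q(qr(m$components[, 1:3]))))$d
  expect_lt(max(acos(pmin(sv, 1))) * 180 / pi, 10)
})

test_that("mode signs follow the outward-radial convention", {
  pop <- small_population()
  X <- population_coord_matrix(pop)
  m <- ssm_train(X, "shape")
  ref <- mc3ssm:::sign_reference("shape", m$mean, ncol(X))
  for (j in seq_len(m$n_retained))
    expect_gte(sum(m$components[, j] * ref), 0)
})

test_that("errors are informative: NaN location, size limits, mismatches", {
  pop <- small_population()
  X <- population_coord_matrix(pop)
  X[4, 14] <- NaN
  expect_error(ssm_train(X, "shape"), "specimen 4.*node 5")
  expect_error(ssm_train(X[1, , drop = FALSE], "shape"), "two specimens")
  m <- ssm_train(population_coord_matrix(pop), "shape")
  expect_error(ssm_project(m, 1:5), "mismatch")
  expect_error(ssm_reconstruct(m, rep(0, length(m$sdev) + 3)), "exceeds")
})

test_that("the shape spectrum is invariant to a rigid motion of the frame", {
  pop <- small_population()
  X <- population_coord_matrix(pop)
  m1 <- ssm_train(X, "shape")
  R <- euler_rotation(0.2, 0.5, -0.4)
  Xr <- do.call(rbind, lapply(seq_len(nrow(X)), function(i)
    flatten_coords(apply_rigid(unflatten_coords(X[i, ]), R, c(10, -5, 3)))))
  m2 <- ssm_train(Xr, "shape")
  expect_lt(max(abs(m1$variance_fractions - m2$variance_fractions)), 1e-9)
})

test_that("the combined correlation model ignores density unit rescaling", {
  pop <- small_population()
  X <- population_coord_matrix(pop)
  D <- population_density_matrix(pop)
  m1 <- ssm_train(build_combined_matrix(X, D), "combined")
  m2 <- ssm_train(build_combined_matrix(X, 1000 * D), "combined")
  expect_lt(max(abs(m1$variance_fractions - m2$variance_fractions)), 1e-9)
})

test_that("leave-one-out curves behave: zero for clones, non-increasing", {
  pop <- small_population()
  X <- population_coord_matrix(pop)
  D <- population_density_matrix(pop)
  # identical population: zero error at every k
  Xc <- X[rep(1, 5), ] ; Dc <- D[rep(1, 5), ]
  curve0 <- loo_analysis(Xc, Dc, "combined", max_components = 2)
  expect_lt(max(curve0$geometric_rms), 1e-8)
  expect_lt(max(curve0$density_rms), 1e-10)
  # real population: curves non-increasing within 5% slack
  curve <- loo_analysis(X, D, "combined", max_components = 4)
  expect_true(all(diff(curve$geometric_rms) <= 0.05 * curve$geometric_rms[-nrow(curve)]))
  expect_true(all(diff(curve$density_rms) <= 0.05 * curve$density_rms[-nrow(curve)]))
  # truncation warning
  expect_warning(loo_analysis(X, flavor = "shape", max_components = 10),
                 "truncating")
  expect_error(loo_analysis(X[1:2, ], flavor = "shape"), "at least 3")
})

test_that("models round-trip through the JSON archive", {
  pop <- small_population()
  m <- ssm_train(population_coord_matrix(pop), "shape")
  tf <- tempfile(fileext = ".json")
  write_ssm_json(m, tf)
  back <- read_ssm_json(tf)
  expect_equal(back$mean, m$mean)
  expect_equal(back$components, m$components, ignore_attr = TRUE)
  expect_equal(back$variance_fractions, m$variance_fractions)
  expect_equal(back$n_retained, m$n_retained)
  # the archive is usable
  expect_equal(ssm_reconstruct(back, c(1, -0.5)),
               ssm_reconstruct(m, c(1, -0.5)))
})

test_that("variance tables mirror the per-flavor spectra", {
  pop <- small_population()
  X <- population_coord_matrix(pop)
  D <- population_density_matrix(pop)
  tab <- variance_table(shape = ssm_train(X, "shape"),
                        density = ssm_train(D, "density"),
                        combined = ssm_train(build_combined_matrix(X, D),
                                             "combined"))
  expect_setequal(unique(tab$flavor), c("shape", "density", "combined"))
  for (fl in unique(tab$flavor)) {
    sub <- tab[tab$flavor == fl, ]
    expect_equal(sub$cumulative_pct, cumsum(sub$variance_pct))
    expect_equal(max(sub$cumulative_pct), 100, tolerance = 1e-6)
  }
})
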