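# Phantom calibration, HU conversion, density-modulus law, subchondral
# sampling, and the voxelization round trip.

make_phantom_volume <- function(phantom_hu = 1200, water_hu = 0, noise = 0,
                                seed = 1) {
  dims <- c(40L, 40L, 30L)
  hu <- array(water_hu, dims)
  set.seed(seed)
  if (noise > 0) hu <- hu + array(rnorm(prod(dims), 0, noise), dims)
  vol <- new_mc3_volume(hu, c(1, 1, 1), c(0, 0, 0),
                        phantom_region = list(center = c(30, 20),
                                              radius = 6, zlim = c(5, 25)),
                        water_region = list(lo = c(1L, 1L, 1L),
                                            hi = c(10L, 10L, 10L)))
  m <- region_mask(vol, "phantom")
  vol$hu[m] <- phantom_hu + if (noise > 0)
    rnorm(sum(m), 0, noise) else 0
  vol
}

test_that("calibration recovers constructed phantom and water levels", {
  vol <- make_phantom_volume(1200, 0)
  cal <- estimate_calibration(vol, rho_phantom = 800)
  expect_equal(cal$ct_ha, 1200)
  expect_equal(cal$ct_h2o, 0)
  expect_equal(cal$rho_phantom, 800)
})

test_that("calibration is invariant to a constant HU offset", {
  vol <- make_phantom_volume(1200, 0)
  cal1 <- estimate_calibration(vol)
  vol$hu <- vol$hu + 137
  cal2 <- estimate_calibration(vol)
  expect_equal(cal2$ct_ha - cal1$ct_ha, 137)
  expect_equal(hu_to_rho_ha(900 + 137, cal2), hu_to_rho_ha(900, cal1),
               tolerance = 1e-12)
})

test_that("noisy phantom means concentrate like the CLT predicts", {
  vol <- make_phantom_volume(1200, 0, noise = 10, seed = 41)
  n_ph <- sum(region_mask(vol, "phantom"))
  expect_gt(n_ph, 1000)
  cal <- estimate_calibration(vol)
  expect_lt(abs(cal$ct_ha - 1200), 3 * 10 / sqrt(n_ph))
})

test_that("degenerate calibration is an error", {
  vol <- make_phantom_volume(0, 0)
  expect_error(estimate_calibration(vol), "degenerate")
})

test_that("the linear calibration maps its anchor points correctly", {
  cal <- structure(list(ct_ha = 1600, ct_h2o = 0, rho_phantom = 800),
                   class = "mc3_calibration")
  expect_equal(hu_to_rho_ha(1600, cal, "mg.cm3"), 800)
  expect_equal(hu_to_rho_ha(0, cal, "mg.cm3"), 0)
  expect_equal(hu_to_rho_ha(800, cal, "mg.cm3"), 400)
  expect_equal(hu_to_rho_ha(1600, cal), 0.8)
  # negative values are preserved, not clamped
  expect_lt(hu_to_rho_ha(-100, cal), 0)
})

test_that("the density-modulus power law matches its anchors and an oracle", {
  z <- rho_ha_to_modulus(0)
  expect_equal(z$rho_app, 0)
  expect_equal(z$modulus, 0)
  one <- rho_ha_to_modulus(0.626)
  expect_equal(one$rho_app, 1, tolerance = 1e-12)
  expect_equal(one$modulus, 2017.3, tolerance = 1e-12)
  # arbitrary-precision spot checks (mpmath, 30 digits)
  expect_equal(2017.3 * 2^2.46, 11099.5220389332201, tolerance = 1e-13)
  expect_equal(rho_ha_to_modulus(2 * 0.626)$modulus, 11099.5220389332201,
               tolerance = 1e-12)
  expect_equal(rho_ha_to_modulus(0.5 * 0.626)$modulus, 366.637344898782808,
               tolerance = 1e-12)
  # strict monotonicity
  rho <- seq(0, 2, 0.01)
  expect_true(all(diff(rho_ha_to_modulus(rho)$modulus) > 0))
  expect_error(rho_ha_to_modulus(-0.1), "negative")
})

test_that("a uniform volume gives every node the same mean HU", {
  m <- base_mesh()
  vol <- uniform_volume(m, hu = 777)
  ss <- sample_subchondral(m, vol)
  expect_false(any(ss$flagged))
  expect_equal(ss$mean_hu, rep(777, 361), tolerance = 1e-9)
})

test_that("a linear HU gradient averages to the mid-depth value", {
  m <- base_mesh()
  vol <- uniform_volume(m, hu = 0)
  dims <- dim(vol$hu)
  zs <- vol$origin[3] + (seq_len(dims[3]) - 1) * vol$spacing[3]
  a <- 100; b <- 7
  vol$hu <- array(rep(a + b * zs, each = dims[1] * dims[2]), dims)
  depth <- 5
  ss <- sample_subchondral(m, vol, depth = depth, step = 0.25)
  nrm <- node_normals(m)
  expected <- a + b * (m$nodes[, 3] - nrm[, 3] * depth / 2)
  expect_equal(ss$mean_hu, expected, tolerance = 1e-6)
})

test_that("rays leaving the volume are flagged and excluded", {
  m <- base_mesh()
  vol <- uniform_volume(m, hu = 500, margin = 8)
  # crop the volume in z so distal rays exit
  vol$hu <- vol$hu[, , 10:dim(vol$hu)[3]]
  vol$origin[3] <- vol$origin[3] + 9 * vol$spacing[3]
  expect_message(ss <- sample_subchondral(m, vol), "flagged")
  expect_true(any(ss$flagged))
  expect_true(all(is.na(ss$mean_hu[ss$flagged])))
  expect_lt(max(abs(ss$mean_hu[!ss$flagged] - 500)), 1e-9)
})

test_that("voxelize: phantom is uniform CT_HA, background is CT_H2O", {
  spec <- default_synthetic_spec(2, seed = 44)
  pop <- sample_population(spec)
  vol <- voxelize(pop$specimens[[1]], spec)
  expect_equal(unique(as.vector(vol$hu[region_mask(vol, "phantom")])),
               spec$ct_ha)
  expect_equal(unique(as.vector(vol$hu[region_mask(vol, "water")])),
               spec$ct_h2o)
})

test_that("a uniform-density specimen voxelizes to a uniform shell", {
  spec <- default_synthetic_spec(2, seed = 45)
  pop <- sample_population(spec)
  s <- pop$specimens[[1]]
  s$node_density <- rep(0.6, 361)
  vol <- voxelize(s, spec)
  fld <- node_density_field(mesh_from_specimen(s), vol)
  expect_lt(max(abs(fld$rho_ha - 0.6), na.rm = TRUE), 1e-3)
})

test_that("voxelize rejects a field of view that clips the specimen", {
  spec <- default_synthetic_spec(2, seed = 46)
  pop <- sample_population(spec)
  expect_error(voxelize(pop$specimens[[1]], spec,
                        fov = list(origin = c(0, 0, 0), dims = c(10, 10, 10))),
               "field of view")
})

test_that("the noiseless density round trip recovers node densities", {
  spec <- default_synthetic_spec(2, seed = 47)
  spec$density_noise_sd <- 0; spec$node_noise_sd <- 0; spec$point_noise_sd <- 0
  pop <- sample_population(spec)
  s <- pop$specimens[[2]]
  vol <- voxelize(s, spec)
  fld <- node_density_field(mesh_from_specimen(s), vol)
  rel <- abs(fld$rho_ha - s$node_density) / pmax(s$node_density, 1e-9)
  expect_lt(max(rel, na.rm = TRUE), 0.05)
})

test_that("volumes round-trip through NIfTI and raw formats", {
  vol <- make_phantom_volume(1200, 0)
  tn <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, tn)
  vn <- read_volume_nifti(tn)
  expect_equal(vn$hu, vol$hu, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(vn$spacing, vol$spacing)
  expect_equal(vn$origin, vol$origin)
  expect_equal(estimate_calibration(vn)$ct_ha, 1200)

  tr <- tempfile()
  write_volume_raw(vol, tr)
  vr <- read_volume_raw(tr)
  expect_equal(vr$hu, vol$hu, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(vr$phantom_region$radius, vol$phantom_region$radius)
})
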