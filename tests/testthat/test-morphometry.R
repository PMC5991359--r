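# Landmark morphometry and mode-effect interrogation.

test_that("uniform density gives equal palmar and dorsal BMD", {
  m <- base_mesh()
  mm <- measure_morphometry(m, densities = rep(0.7, 361))
  expect_equal(mm$palmar_condylar_bmd, mm$dorsal_condylar_bmd)
  expect_equal(mm$palmar_condylar_bmd, 0.7)
})

test_that("measurements scale with dimension and BMD does not", {
  m <- base_mesh()
  s <- 1.37
  big <- new_mc3_mesh(s * m$nodes, m$topology, m$manifest)
  a <- measure_morphometry(m, densities = rep(0.5, 361))
  b <- measure_morphometry(big, densities = rep(0.5, 361))
  for (nm in c("medio_lateral_width", "lateral_condylar_width",
               "medial_condylar_width", "sagittal_ridge_width",
               "metaphysis_circumference"))
    expect_equal(b[[nm]], s * a[[nm]], tolerance = 1e-9)
  for (nm in c("total_area", "lateral_condylar_area", "medial_condylar_area"))
    expect_equal(b[[nm]], s^2 * a[[nm]], tolerance = 1e-9)
  expect_equal(b$palmar_condylar_bmd, a$palmar_condylar_bmd)
})

test_that("all measurements are invariant to rigid motion", {
  pop <- small_population()
  s <- pop$specimens[[2]]
  m <- mesh_from_specimen(s, posed = FALSE)
  mp <- mesh_from_specimen(s, posed = TRUE)
  a <- unlist(measure_morphometry(m, densities = s$node_density))
  b <- unlist(measure_morphometry(mp, densities = s$node_density))
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("condylar widths never exceed the medio-lateral width", {
  pop <- small_population()
  for (s in pop$specimens) {
    mm <- measure_morphometry(mesh_from_specimen(s))
    expect_lt(mm$lateral_condylar_width + mm$medial_condylar_width,
              mm$medio_lateral_width)
    expect_gt(mm$total_area, 0)
  }
})

test_that("patch-area quadrature matches a dense triangulation oracle", {
  m <- base_mesh()
  tri_area <- function(patches, G = 48L) {
    total <- 0
    g <- seq(0, 1, length.out = G)
    for (p in patches) {
      pts <- evaluate_surface(m, p, rep(g, G), rep(g, each = G))
      for (i in seq_len(G - 1)) for (j in seq_len(G - 1)) {
        a <- pts[(j - 1) * G + i, ]; b <- pts[(j - 1) * G + i + 1, ]
        cc <- pts[j * G + i, ]; d <- pts[j * G + i + 1, ]
        cr1 <- crossprod_vec(b - a, cc - a)
        cr2 <- crossprod_vec(d - b, cc - b)
        total <- total + 0.5 * (sqrt(sum(cr1^2)) + sqrt(sum(cr2^2)))
      }
    }
    total
  }
  crossprod_vec <- function(u, v)
    c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
  lat <- m$manifest$patch_regions$lateral_condyle
  expect_equal(patch_area(m, lat), tri_area(lat), tolerance = 1e-3)
})

test_that("a zero SD range collapses the mode effect to the mean", {
  pop <- small_population()
  X <- population_coord_matrix(pop)
  D <- population_density_matrix(pop)
  model <- ssm_train(build_combined_matrix(X, D), "combined")
  eff <- mode_effect(model, 1, sd_range = 0)
  expect_equal(max(abs(eff$percent_change$pct_change)), 0, tolerance = 1e-9)
  expect_equal(unlist(eff$minus), unlist(eff$plus), tolerance = 1e-12)
})

test_that("the size mode couples larger area with higher density", {
  spec <- default_synthetic_spec(80, seed = 61)
  pop <- sample_population(spec)
  X <- population_coord_matrix(pop)
  D <- population_density_matrix(pop)
  model <- ssm_train(build_combined_matrix(X, D), "combined")
  eff <- mode_effect(model, 1, sd_range = 2)
  pc <- eff$percent_change
  expect_gt(pc$pct_change[pc$metric == "total_area"], 0)
  expect_gt(pc$pct_change[pc$metric == "dorsal_condylar_bmd"], 0)
  expect_gt(pc$pct_change[pc$metric == "palmar_condylar_bmd"], 0)
})

test_that("percent changes compose consistently", {
  pop <- small_population()
  X <- population_coord_matrix(pop)
  model <- ssm_train(X, "shape")
  eff <- mode_effect(model, 1, sd_range = 2)
  pc <- eff$percent_change
  expect_equal(pc$pct_change, pc$pct_plus_vs_mean - pc$pct_minus_vs_mean,
               tolerance = 1e-9)
})

test_that("missing landmarks are reported by name", {
  m <- base_mesh()
  m$manifest$landmarks <- m$manifest$landmarks[
    names(m$manifest$landmarks) != "lateral_edge"]
  expect_error(measure_morphometry(m), "lateral_edge")
})

test_that("mode-effect summaries export to CSV and JSON", {
  pop <- small_population()
  model <- ssm_train(population_coord_matrix(pop), "shape")
  eff <- mode_effect_summary(model, n_modes = 2)
  tc <- tempfile(fileext = ".csv"); tj <- tempfile(fileext = ".json")
  tab <- write_mode_effects(eff, tc, tj)
  expect_true(file.exists(tc) && file.exists(tj))
  expect_setequal(unique(utils::read.csv(tc)$mode), 1:2)
  parsed <- jsonlite::read_json(tj, simplifyVector = FALSE)
  expect_length(parsed, 2)
})
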